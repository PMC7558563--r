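# Synthetic "observed" physiological series: a model trajectory plus
# autocorrelated Gaussian measurement noise, emulating the statistical
# structure of chamber measurements (minute-wise, smooth, with an
# inter-subject SD of a few tenths of a degree for rectal temperature).

#' Measurement-noise specification
#'
#' @param sd Stationary standard deviation of the noise (degC for rectal
#'   series, g for water loss).
#' @param ar1 Lag-1 autocorrelation in `[0, 1)`; physiological minute-wise
#'   measurements are smooth, so the default is 0.8.
#' @param seed Integer RNG seed; output is reproducible given the seed.
#' @param offset Systematic measurement bias, same units as `sd`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd, ar1 = 0.8, seed = 1L, offset = 0) {
  stopifnot(is.finite(sd), sd >= 0, is.finite(ar1), ar1 >= 0, ar1 < 1,
            is.finite(offset))
  structure(list(sd = sd, ar1 = ar1, seed = as.integer(seed), offset = offset),
            class = "noise_spec")
}

#' Generate a synthetic observed series
#'
#' Adds `offset` plus stationary AR(1) Gaussian noise (marginal SD
#' `spec$sd`) to a model trajectory. The global RNG state is left untouched.
#' For cumulative quantities such as water loss set `monotone = TRUE`, which
#' clips the output to be non-decreasing (running maximum).
#'
#' @param truth Finite numeric series (a model trajectory).
#' @param spec A [noise_spec()].
#' @param monotone Enforce a non-decreasing output.
#' @return Numeric series of the same length as `truth`.
#' @export
synth_observed <- function(truth, spec, monotone = FALSE) {
  stopifnot(inherits(spec, "noise_spec"), is.numeric(truth),
            all(is.finite(truth)))
  n <- length(truth)
  e <- numeric(n)
  if (spec$sd > 0 && n > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed)
    e[1] <- stats::rnorm(1, 0, spec$sd)
    if (n > 1) {
      innov <- stats::rnorm(n - 1, 0, spec$sd * sqrt(1 - spec$ar1^2))
      for (i in 2:n) e[i] <- spec$ar1 * e[i - 1] + innov[i - 1]
    }
  }
  out <- truth + spec$offset + e
  if (monotone) out <- cummax(out)
  out
}
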