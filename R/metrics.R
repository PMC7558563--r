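# Goodness-of-fit metrics for predicted vs observed physiological series.

#' Root-mean-square deviation and bias
#'
#' Compares an observed with a predicted series after discarding a burn-in
#' period (the initial-state transient). The sign convention is measured
#' minus predicted, so a positive bias means the model under-predicts.
#' The fit is taken as acceptable when the rmsd is smaller than the standard
#' deviation of the observed data; by default that threshold is the SD of
#' the observed series after burn-in, and a measurement SD from replicate
#' subjects may be supplied instead.
#'
#' @param observed,predicted Equal-length numeric series.
#' @param burn_in Number of initial samples to drop (default 10).
#' @param sd_observed Acceptance threshold; defaults to `sd(observed)` after
#'   burn-in.
#' @return An object of class `eval_metrics`: `rmsd`, `bias`, `sd_observed`,
#'   `n_points` and the logical `accepted`.
#' @examples
#' rmsd_bias(c(38, 38), c(37, 39), burn_in = 0)  # rmsd 1, bias 0
#' @export
rmsd_bias <- function(observed, predicted, burn_in = 10, sd_observed = NULL) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  if (burn_in < 0 || burn_in >= length(observed)) {
    stop("`burn_in` must be smaller than the series length", call. = FALSE)
  }
  if (burn_in > 0) {
    observed <- observed[-seq_len(burn_in)]
    predicted <- predicted[-seq_len(burn_in)]
  }
  d <- observed - predicted
  rmsd <- sqrt(mean(d^2))
  bias <- mean(d)
  if (is.null(sd_observed)) sd_observed <- stats::sd(observed)
  structure(
    list(rmsd = rmsd, bias = bias, sd_observed = sd_observed,
         n_points = length(d),
         accepted = is.finite(sd_observed) && rmsd < sd_observed),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("rmsd = %.4f, bias = %+.4f (n = %d, SD of observed = %.4f): %s\n",
              x$rmsd, x$bias, x$n_points, x$sd_observed,
              if (x$accepted) "acceptable fit" else "fit not acceptable"))
  invisible(x)
}
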