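# Clothing thermophysical properties and their dynamic corrections.
#
# All insulation algebra is carried out in clo (1 clo = 0.155 m^2.K/W);
# conversion to SI happens only where the Lewis relation or the heat-balance
# core needs watts.

# Static boundary-air-layer insulation of a standing person, clo.
IA_STATIC_CLO <- 0.716
# clo -> m^2.K/W
CLO_TO_SI <- 0.155
# Lewis relation constant, K/kPa.
LEWIS <- 16.7

#' Clothing area factor
#'
#' Ratio of the outer surface area of the clothed body to the surface area of
#' the nude body, from the basic clothing insulation.
#'
#' @param icl Basic clothing insulation in clo (>= 0).
#' @return The dimensionless clothing area factor `1 + 0.3 * icl`.
#' @examples
#' fcl_ratio(1)    # 1.3
#' fcl_ratio(0)    # nude limit, 1
#' @export
fcl_ratio <- function(icl) {
  if (!is.numeric(icl) || any(!is.finite(icl)) || any(icl < 0)) {
    stop("`icl` must be finite and >= 0 (clo)", call. = FALSE)
  }
  1 + 0.3 * icl
}

#' Classify an ensemble by its basic insulation
#'
#' Light clothing (LC) below 0.6 clo, normal clothing (NC) from 0.6 to
#' 1.4 clo, and specialized insulating cold-weather clothing (SC) above
#' 1.4 clo. The boundary values 0.6 and 1.4 clo are assigned to NC.
#'
#' @param icl Basic clothing insulation, clo.
#' @return `"LC"`, `"NC"` or `"SC"`.
#' @export
clothing_category <- function(icl) {
  ifelse(icl < 0.6, "LC", ifelse(icl <= 1.4, "NC", "SC"))
}

#' Clothing ensemble
#'
#' Static thermophysical properties of a clothing ensemble.
#'
#' @param icl Basic clothing insulation, clo (> 0).
#' @param rt_static Static total evaporative resistance, m^2.kPa/W (> 0).
#' @param imt Static moisture permeability index, dimensionless in (0, 1].
#' @param pr Air permeability, L/m^2.s (>= 1); used only by the ISO 9920
#'   cold-weather correction. Defaults to 1, which makes the `pr^0.144`
#'   term unity.
#' @param category Clothing category `"LC"`, `"NC"` or `"SC"`; by default
#'   derived from `icl` via [clothing_category()]. A supplied category must
#'   agree with the cutpoints.
#' @return An object of class `clothing_ensemble`.
#' @examples
#' clothing_ensemble(icl = 1.08, rt_static = 0.0421, imt = 0.37)
#' @export
clothing_ensemble <- function(icl, rt_static, imt, pr = 1, category = NULL) {
  stopifnot(is.numeric(icl), length(icl) == 1L, is.finite(icl))
  if (icl <= 0) stop("`icl` must be > 0 clo", call. = FALSE)
  if (!is.finite(rt_static) || rt_static <= 0) {
    stop("`rt_static` must be > 0 m^2.kPa/W", call. = FALSE)
  }
  if (!is.finite(imt) || imt <= 0 || imt > 1) {
    stop("`imt` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(pr) || pr < 1) stop("`pr` must be >= 1 L/m^2.s", call. = FALSE)
  derived <- clothing_category(icl)
  if (is.null(category)) {
    category <- derived
  } else {
    category <- match.arg(category, c("LC", "NC", "SC"))
    if (category != derived) {
      stop(sprintf("category %s inconsistent with icl = %g clo (expected %s)",
                   category, icl, derived), call. = FALSE)
    }
  }
  structure(
    list(icl = icl, rt_static = rt_static, imt = imt, pr = pr,
         category = category),
    class = "clothing_ensemble"
  )
}

#' @export
print.clothing_ensemble <- function(x, ...) {
  cat(sprintf(
    "Clothing ensemble (%s): Icl = %.2f clo, Rt = %.4f m^2.kPa/W, imt = %.2f, pr = %g L/m^2.s\n",
    x$category, x$icl, x$rt_static, x$imt, x$pr))
  invisible(x)
}

#' Air and body kinematics
#'
#' Bundles the air velocity, the walking speed and the relative air velocity
#' experienced by the moving body. When `var` is not supplied it is computed
#' with [relative_air_velocity()] (omni-directional max rule, capped at
#' 3 m/s).
#'
#' @param va Air velocity, m/s (>= 0).
#' @param vw Walking speed, m/s (>= 0).
#' @param var Relative air velocity, m/s; computed from `va` and `vw` when
#'   `NULL`.
#' @return An object of class `kinematics`.
#' @export
kinematics <- function(va, vw, var = NULL) {
  stopifnot(is.numeric(va), is.numeric(vw), va >= 0, vw >= 0)
  if (is.null(var)) var <- relative_air_velocity(va, vw, walking_defined = TRUE)
  stopifnot(is.numeric(var), var >= 0)
  structure(list(va = va, vw = vw, var = var), class = "kinematics")
}

# Clamp x into [lo, hi]; flags when clamping actually happened.
clamp_range <- function(x, lo, hi) {
  clamped <- x < lo || x > hi
  list(value = min(max(x, lo), hi), clamped = clamped)
}

#' Dynamic-correction factors for total and boundary-layer insulation
#'
#' Exponential correction factors for the pumping effect of wind and body
#' movement, for normal clothing under the ISO 7933 and ISO 9920 coefficient
#' sets and for cold-weather clothing under ISO 9920. Inputs outside an
#' algorithm's stated validity range are clamped to the nearest bound and
#' flagged. ISO 9920 gives no cold-weather boundary-layer factor, so the
#' normal-clothing one is used there.
#'
#' The raw regression values are returned; the Annex-E cap at 1 is applied
#' later, in [dynamic_insulation()].
#'
#' @param algorithm One of `"ISO7933_NC"`, `"ISO9920_NC"`, `"ISO9920_SC"`.
#' @param kin A [kinematics()] object (its `var` and `vw` are used).
#' @param pr Air permeability, L/m^2.s; required for `"ISO9920_SC"`.
#' @return A list with `corr_tot`, `corr_a` and the logical `clamped`.
#' @examples
#' correction_factors("ISO9920_NC", kinematics(0.15, 0, var = 0.15))
#' @export
correction_factors <- function(algorithm = c("ISO7933_NC", "ISO9920_NC", "ISO9920_SC"),
                               kin, pr = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(kin, "kinematics"))
  var <- kin$var
  vw <- kin$vw
  if (algorithm == "ISO7933_NC") {
    cv <- clamp_range(var, 0, 3)
    cw <- clamp_range(vw, 0, 1.5)
    v <- cv$value; w <- cw$value
    corr_tot <- exp(0.043 - 0.398 * v + 0.066 * v^2 - 0.378 * w + 0.094 * w^2)
    corr_a <- exp(-0.472 * v + 0.047 * v^2 - 0.342 * w + 0.117 * w^2)
  } else if (algorithm == "ISO9920_NC") {
    cv <- clamp_range(var, 0.15, 3.5)
    cw <- clamp_range(vw, 0, 1.2)
    v <- cv$value - 0.15; w <- cw$value
    corr_tot <- exp(-0.281 * v + 0.044 * v^2 - 0.492 * w + 0.176 * w^2)
    corr_a <- exp(-0.533 * v + 0.069 * v^2 - 0.462 * w + 0.201 * w^2)
  } else {
    if (is.null(pr)) {
      stop("air permeability `pr` is required for the ISO 9920 cold-weather correction",
           call. = FALSE)
    }
    cv <- clamp_range(var, 0.4, 18)
    cw <- clamp_range(vw, 0, 1.2)
    cp <- clamp_range(pr, 1, 1000)
    v <- cv$value - 0.4; w <- cw$value
    corr_tot <- exp(-0.0512 * v + 0.000794 * v^2 - 0.0639 * w) * cp$value^0.144
    # no SC-specific boundary-layer factor exists; fall back on the NC one
    vn <- clamp_range(var, 0.15, 3.5)$value - 0.15
    corr_a <- exp(-0.533 * vn + 0.069 * vn^2 - 0.462 * w + 0.201 * w^2)
  }
  clamped <- cv$clamped || cw$clamped
  if (clamped) {
    message(sprintf("%s: kinematics clamped to validity range (var = %.3g, vw = %.3g)",
                    algorithm, var, vw))
  }
  list(corr_tot = corr_tot, corr_a = corr_a, clamped = clamped)
}

# Lu's regression for light clothing: a single factor on the total insulation.
lu_total_factor <- function(var, vw) {
  cv <- clamp_range(var, 0.15, 5.2)
  cw <- clamp_range(vw, 0, 1.2)
  v <- cv$value - 0.15; w <- cw$value
  list(corr_tot = exp(-0.393 * v + 0.0393 * v^2 - 0.0728 * w + 0.053 * w^2),
       clamped = cv$clamped || cw$clamped)
}

#' Dynamic clothing and boundary-layer insulation
#'
#' Builds the static total insulation `Itot = Icl + Ia/fcl` (with
#' `Ia = 0.716` clo) and corrects it for wind and body movement under one of
#' three algorithms:
#'
#' * `"ISO7933"`: the normal-clothing coefficients applied to every category;
#'   for light clothing (`Icl < 0.6` clo) the total factor is interpolated
#'   between the boundary-layer and the clothing factor in proportion to
#'   `Icl/0.6`.
#' * `"ISO9920"`: category dispatch; normal-clothing coefficients for NC,
#'   the cold-weather formula (with air permeability `pr`) for SC, and for LC
#'   an interpolation between the dynamic boundary layer and the
#'   NC-corrected ("dressed") total insulation.
#' * `"LU"`: Lu's single regression on the total insulation, valid for light
#'   clothing only; the boundary layer is corrected with the ISO 9920 factor
#'   so the clothing-only term can still be split out.
#'
#' Factors are capped at 1 so that movement never adds insulation. The
#' clothing-only dynamic insulation is `Icl,dyn = Itot,dyn - Ia,dyn/fcl`.
#'
#' @param ens A [clothing_ensemble()].
#' @param kin A [kinematics()] object.
#' @param algorithm `"ISO7933"`, `"ISO9920"` or `"LU"`.
#' @return An object of class `dynamic_clothing`: the effective factors
#'   `corr_tot` and `corr_a`, the static `itot`, the dynamic `itot_dyn`,
#'   `ia_dyn` and `icl_dyn` (all clo), `fcl`, the `algorithm` label and the
#'   `clamped` flag. Evaporative quantities are filled by
#'   [dynamic_evaporative_resistance()].
#' @seealso [dynamic_clothing()] for the one-call version.
#' @export
dynamic_insulation <- function(ens, kin, algorithm = c("ISO7933", "ISO9920", "LU")) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(ens, "clothing_ensemble"), inherits(kin, "kinematics"))
  icl <- ens$icl
  fcl <- fcl_ratio(icl)
  itot <- icl + IA_STATIC_CLO / fcl

  if (algorithm == "ISO7933") {
    cf <- correction_factors("ISO7933_NC", kin)
    ct <- min(cf$corr_tot, 1)
    ca <- min(cf$corr_a, 1)
    corr_tot <- if (ens$category == "LC") ((0.6 - icl) * ca + icl * ct) / 0.6 else ct
    corr_a <- ca
    clamped <- cf$clamped
  } else if (algorithm == "ISO9920") {
    cf <- correction_factors("ISO9920_NC", kin)
    corr_a <- min(cf$corr_a, 1)
    if (ens$category == "SC") {
      sc <- correction_factors("ISO9920_SC", kin, pr = ens$pr)
      corr_tot <- min(sc$corr_tot, 1)
      clamped <- sc$clamped
    } else if (ens$category == "LC") {
      ia_dyn <- corr_a * IA_STATIC_CLO
      itot_dress <- min(cf$corr_tot, 1) * itot
      corr_tot <- ((0.6 - icl) * ia_dyn + icl * itot_dress) / 0.6 / itot
      clamped <- cf$clamped
    } else {
      corr_tot <- min(cf$corr_tot, 1)
      clamped <- cf$clamped
    }
  } else {
    if (ens$category != "LC") {
      stop("Lu's correction is defined for light clothing (LC) only", call. = FALSE)
    }
    lu <- lu_total_factor(kin$var, kin$vw)
    corr_tot <- min(lu$corr_tot, 1)
    corr_a <- min(correction_factors("ISO9920_NC", kin)$corr_a, 1)
    clamped <- lu$clamped
  }

  itot_dyn <- corr_tot * itot
  ia_dyn <- corr_a * IA_STATIC_CLO
  structure(
    list(corr_tot = corr_tot, corr_a = corr_a,
         itot = itot, itot_dyn = itot_dyn, ia_dyn = ia_dyn,
         icl_dyn = itot_dyn - ia_dyn / fcl, fcl = fcl,
         rt_dyn = NA_real_, imt_dyn = NA_real_,
         algorithm = algorithm, clamped = clamped),
    class = "dynamic_clothing"
  )
}

#' Dynamic evaporative resistance
#'
#' Corrects the moisture path for wind and body movement. ISO 7933 is a
#' double correction: the permeability index is scaled by
#' `Corr_E = 2.6 corr_tot^2 - 6.5 corr_tot + 4.9` (the result capped at 0.9)
#' and the resistance recovered through the Lewis relation,
#' `Rt,dyn = Itot,dyn / (imt,dyn * 16.7)` with `Itot,dyn` in SI units.
#' ISO 9920 corrects the static total evaporative resistance with the single
#' factor `1.2 corr_tot^2 - 0.5 corr_tot + 0.3`; its permeability index is
#' then reported back through the same Lewis relation.
#'
#' @param ens A [clothing_ensemble()] (supplies `imt` and `rt_static`).
#' @param dyn A `dynamic_clothing` object from [dynamic_insulation()].
#' @param algorithm `"ISO7933"` or `"ISO9920"`. Defaults to the algorithm
#'   that produced `dyn`, with Lu's insulation falling back on the ISO 7933
#'   double correction.
#' @return A list with `rt_dyn` (m^2.kPa/W) and `imt_dyn` (dimensionless).
#' @export
dynamic_evaporative_resistance <- function(ens, dyn, algorithm = NULL) {
  stopifnot(inherits(ens, "clothing_ensemble"), inherits(dyn, "dynamic_clothing"))
  if (is.null(algorithm)) {
    algorithm <- if (dyn$algorithm == "ISO9920") "ISO9920" else "ISO7933"
  }
  algorithm <- match.arg(algorithm, c("ISO7933", "ISO9920"))
  ct <- dyn$corr_tot
  if (!is.finite(ct) || ct <= 0) stop("corr_tot must be > 0", call. = FALSE)
  itot_dyn_si <- dyn$itot_dyn * CLO_TO_SI
  if (algorithm == "ISO7933") {
    corr_e <- 2.6 * ct^2 - 6.5 * ct + 4.9
    imt_dyn <- min(ens$imt * corr_e, 0.9)
    rt_dyn <- itot_dyn_si / (imt_dyn * LEWIS)
  } else {
    rt_dyn <- (1.2 * ct^2 - 0.5 * ct + 0.3) * ens$rt_static
    imt_dyn <- itot_dyn_si / (LEWIS * rt_dyn)
  }
  list(rt_dyn = rt_dyn, imt_dyn = imt_dyn)
}

#' Full dynamic clothing state
#'
#' Convenience wrapper running [dynamic_insulation()] and
#' [dynamic_evaporative_resistance()] in one call.
#'
#' @inheritParams dynamic_insulation
#' @param evap_algorithm Evaporative-resistance algorithm; defaults to the
#'   insulation algorithm (Lu falls back on ISO 7933).
#' @return A complete `dynamic_clothing` object.
#' @export
dynamic_clothing <- function(ens, kin, algorithm = c("ISO7933", "ISO9920", "LU"),
                             evap_algorithm = NULL) {
  dyn <- dynamic_insulation(ens, kin, algorithm)
  ev <- dynamic_evaporative_resistance(ens, dyn, evap_algorithm)
  dyn$rt_dyn <- ev$rt_dyn
  dyn$imt_dyn <- ev$imt_dyn
  dyn
}

#' @export
print.dynamic_clothing <- function(x, ...) {
  cat(sprintf("Dynamic clothing (%s%s):\n", x$algorithm,
              if (x$clamped) ", inputs clamped" else ""))
  cat(sprintf("  corr_tot = %.4f, corr_a = %.4f\n", x$corr_tot, x$corr_a))
  cat(sprintf("  Itot,dyn = %.4f clo, Ia,dyn = %.4f clo, Icl,dyn = %.4f clo\n",
              x$itot_dyn, x$ia_dyn, x$icl_dyn))
  if (is.finite(x$rt_dyn)) {
    cat(sprintf("  Rt,dyn = %.5f m^2.kPa/W, imt,dyn = %.4f\n", x$rt_dyn, x$imt_dyn))
  }
  invisible(x)
}
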