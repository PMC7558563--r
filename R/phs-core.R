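# Minute-by-minute Predicted Heat Strain (PHS) simulation, following the
# ISO 7933:2004 computer-program structure (Malchaire's published model):
# exponentially averaged equilibrium core temperature, regression-predicted
# skin temperature, iterative clothing-surface temperature, wettedness-limited
# evaporation, exponentially averaged sweat rate, and duration limits from
# rectal temperature (38 degC) and dehydration (5 % / 7.5 % of body mass).

# Saturated water-vapour pressure over water, kPa (Antoine form used by the
# PHS program).
p_sat_kpa <- function(t_c) 0.6105 * exp(17.27 * t_c / (t_c + 237.3))

#' Subject anthropometry and status
#'
#' @param height Body height, m.
#' @param weight Body mass, kg.
#' @param acclimatized Logical; heat-acclimatized subject? Raises the maximum
#'   sweat rate by 25 % and the maximum skin wettedness from 0.85 to 1.
#' @param drink Logical; can the subject drink freely? When `FALSE` both
#'   dehydration limits drop to 3 % of body mass.
#' @return An object of class `phs_subject` including the DuBois body surface
#'   area `adu` (m^2).
#' @export
phs_subject <- function(height = 1.78, weight = 80, acclimatized = FALSE,
                        drink = TRUE) {
  stopifnot(height > 1.0, height < 2.5, weight > 30, weight < 200)
  adu <- 0.202 * weight^0.425 * height^0.725
  structure(list(height = height, weight = weight,
                 acclimatized = isTRUE(acclimatized), drink = isTRUE(drink),
                 adu = adu),
            class = "phs_subject")
}

#' Exposure scenario
#'
#' One combination of environment, work rate, clothing and exposure duration.
#'
#' @param label Scenario name.
#' @param ensemble A [clothing_ensemble()].
#' @param ta Air temperature, degC.
#' @param tr Mean radiant temperature, degC; defaults to `ta`
#'   (climate-chamber convention).
#' @param pw Partial water-vapour pressure, kPa; must be below saturation at
#'   `ta`.
#' @param va Air velocity, m/s.
#' @param vw_measured Measured walking speed, m/s, or `NULL` when walking is
#'   undefined and the speed is to be estimated from the metabolic rate.
#' @param met Metabolic rate, W/m^2 (>= 58, i.e. at least resting).
#' @param duration Exposure duration, minutes (>= 1).
#' @param subject A [phs_subject()].
#' @return An object of class `phs_scenario`.
#' @export
phs_scenario <- function(label, ensemble, ta, tr = ta, pw, va,
                         vw_measured = NULL, met, duration = 70,
                         subject = phs_subject()) {
  stopifnot(inherits(ensemble, "clothing_ensemble"),
            inherits(subject, "phs_subject"),
            is.finite(ta), is.finite(tr), is.finite(pw), is.finite(va),
            is.finite(met), va >= 0, pw >= 0)
  if (duration < 1) stop("`duration` must be >= 1 minute", call. = FALSE)
  duration <- as.integer(duration)
  if (met < 58) stop("`met` must be >= 58 W/m^2", call. = FALSE)
  if (pw >= p_sat_kpa(ta)) {
    stop(sprintf("`pw` = %.2f kPa is not below saturation at %.1f degC (%.2f kPa)",
                 pw, ta, p_sat_kpa(ta)), call. = FALSE)
  }
  if (!is.null(vw_measured)) stopifnot(is.finite(vw_measured), vw_measured >= 0)
  structure(list(label = label, ensemble = ensemble, ta = ta, tr = tr,
                 pw = pw, va = va, vw_measured = vw_measured, met = met,
                 duration = duration, subject = subject),
            class = "phs_scenario")
}

#' @export
print.phs_scenario <- function(x, ...) {
  cat(sprintf(
    "PHS scenario '%s' (%s): Ta = %g degC, Tr = %g degC, Pw = %g kPa, va = %g m/s, Met = %g W/m^2, %d min\n",
    x$label, x$ensemble$category, x$ta, x$tr, x$pw, x$va, x$met, x$duration))
  if (!is.null(x$vw_measured)) {
    cat(sprintf("  measured walking speed: %g m/s\n", x$vw_measured))
  }
  invisible(x)
}

#' Walking speed estimated from the metabolic rate
#'
#' The PHS convention for undefined walking: `0.0052 * (met - 58)` m/s,
#' capped at 0.7 m/s.
#'
#' @param met Metabolic rate, W/m^2.
#' @return Walking speed, m/s. Below resting metabolism (met < 58) the speed
#'   is 0, with a warning.
#' @examples
#' estimate_walking_speed(155)  # 0.5044
#' estimate_walking_speed(250)  # capped at 0.7
#' @export
estimate_walking_speed <- function(met) {
  if (any(met < 58)) {
    warning("metabolic rate below resting (58 W/m^2); walking speed set to 0")
  }
  pmin(pmax(0.0052 * (met - 58), 0), 0.7)
}

#' Relative air velocity
#'
#' For defined, omni-directional walking the body experiences
#' `max(va, vw)`; when walking is undefined the walking speed does not add to
#' the air movement and the relative velocity is the air velocity itself.
#' The result is capped at 3 m/s.
#'
#' @param va Air velocity, m/s.
#' @param vw Walking speed, m/s.
#' @param walking_defined Logical; is `vw` a supplied (measured) speed?
#' @return Relative air velocity, m/s.
#' @export
relative_air_velocity <- function(va, vw, walking_defined = TRUE) {
  stopifnot(va >= 0, vw >= 0)
  v <- if (walking_defined) pmax(va, vw) else va
  pmin(v, 3)
}

#' Simulate the PHS model for one scenario
#'
#' Runs the minute-stepping heat balance with initial rectal and core
#' temperature 36.8 degC, skin temperature 34.1 degC and zero sweat rate.
#' Clothing enters through the dynamic corrections of the chosen algorithm;
#' when `use_measured_vw` is `TRUE` the scenario's measured walking speed is
#' supplied to the corrections and (under `vw_mode = "max"`) to the relative
#' air velocity, otherwise the walking speed is estimated from the metabolic
#' rate and the relative velocity stays at the air velocity.
#'
#' Duration limits: `dlim_tre` is the first minute the rectal temperature
#' reaches 38 degC; `dlim_loss95` / `dlim_loss50` the first minute the
#' cumulative water loss reaches 5 % / 7.5 % of body mass (3 % for both when
#' drinking is restricted). Limits not reached within the horizon are
#' reported as the exposure duration.
#'
#' @param scenario A [phs_scenario()].
#' @param algorithm Clothing-dynamics algorithm: `"ISO7933"`, `"ISO9920"` or
#'   `"LU"` (light clothing only).
#' @param use_measured_vw Logical; use the scenario's measured walking speed
#'   instead of the metabolic-rate estimate.
#' @param vw_mode With a measured walking speed, `"max"` (default) also
#'   raises the relative air velocity to `max(va, vw)`; `"air"` feeds the
#'   walking speed to the clothing corrections only.
#' @return An object of class `phs_result`: the per-minute data frame
#'   `minutes` (temperatures, sweat rate, cumulative water loss and the
#'   heat-balance components, all W/m^2), the duration limits, the dynamic
#'   clothing state and the run settings.
#' @export
phs_simulate <- function(scenario, algorithm = c("ISO7933", "ISO9920", "LU"),
                         use_measured_vw = FALSE, vw_mode = c("max", "air")) {
  algorithm <- match.arg(algorithm)
  vw_mode <- match.arg(vw_mode)
  stopifnot(inherits(scenario, "phs_scenario"))
  sub <- scenario$subject
  ens <- scenario$ensemble
  ta <- scenario$ta; tr <- scenario$tr; pa <- scenario$pw; va <- scenario$va
  met <- scenario$met; duration <- scenario$duration

  if (use_measured_vw) {
    if (is.null(scenario$vw_measured)) {
      stop("scenario has no measured walking speed", call. = FALSE)
    }
    vw <- scenario$vw_measured
    var <- if (vw_mode == "max") relative_air_velocity(va, vw, TRUE) else min(va, 3)
  } else {
    vw <- estimate_walking_speed(met)
    var <- relative_air_velocity(va, vw, walking_defined = FALSE)
  }

  dyn <- dynamic_clothing(ens, kinematics(va, vw, var = var), algorithm)
  itot_dyn_si <- dyn$itot_dyn * CLO_TO_SI
  rt_dyn <- dyn$rt_dyn
  fcl <- dyn$fcl

  adu <- sub$adu
  sp_heat <- 57.83 * sub$weight / adu
  sw_max <- min(max((met - 32) * adu, 250), 400)
  if (sub$acclimatized) sw_max <- sw_max * 1.25
  w_max <- if (sub$acclimatized) 1 else 0.85
  if (sub$drink) {
    d_max_95 <- 0.05 * sub$weight * 1000
    d_max_50 <- 0.075 * sub$weight * 1000
  } else {
    d_max_95 <- d_max_50 <- 0.03 * sub$weight * 1000
  }
  # weight-loss conversion: 1 W/m^2 sustained for 1 min evaporates
  # 60 J / 2430 J/g per m^2 of body surface
  g_per_wm2min <- 2.67 * adu / 1.8 / 60

  # radiative exchange: standing posture, no reflective clothing
  ardu <- 0.77
  fcl_r <- 0.97
  wme <- 0  # external mechanical work

  const_teq <- exp(-1 / 10)
  const_tsk <- exp(-1 / 3)
  const_sw <- exp(-1 / 10)

  t_sk <- 34.1; t_cr <- 36.8; t_re <- 36.8; t_cr_eq <- 36.8
  wg <- 0.3  # skin/core weighting of body heat content
  sw <- 0; sw_tot <- 0
  t_cl <- tr + 0.1
  dlim_tre <- dlim95 <- dlim50 <- 0L

  n <- duration
  out <- data.frame(minute = seq_len(n), t_re = NA_real_, t_cr = NA_real_,
                    t_sk = NA_real_, sweat_rate_gh = NA_real_,
                    water_loss_g = NA_real_, conv = NA_real_, rad = NA_real_,
                    c_res = NA_real_, e_res = NA_real_, e_p = NA_real_,
                    storage = NA_real_)

  for (tm in seq_len(n)) {
    t_sk0 <- t_sk; t_re0 <- t_re; t_cr0 <- t_cr; t_cr_eq0 <- t_cr_eq; wg0 <- wg

    # equilibrium core temperature tied to the metabolic rate, approached
    # with a 10-min time constant; its drift is heat already stored
    t_cr_eq <- t_cr_eq0 * const_teq + (0.0036 * met + 36.6) * (1 - const_teq)
    d_stor_eq <- sp_heat * (t_cr_eq - t_cr_eq0) * (1 - wg0)

    # skin temperature: regression for the clothed and the nude body,
    # interpolated between 0.2 and 0.6 clo; 3-min time constant
    t_sk_cl <- 12.165 + 0.02017 * ta + 0.04361 * tr + 0.19354 * pa -
      0.25315 * va + 0.005346 * met + 0.51274 * t_re
    t_sk_nu <- 7.191 + 0.064 * ta + 0.061 * tr + 0.198 * pa - 0.348 * va +
      0.616 * t_re
    t_sk_eq <- if (ens$icl >= 0.6) t_sk_cl else if (ens$icl <= 0.2) t_sk_nu else
      t_sk_nu + 2.5 * (t_sk_cl - t_sk_nu) * (ens$icl - 0.2)
    t_sk <- t_sk0 * const_tsk + t_sk_eq * (1 - const_tsk)
    p_sk <- p_sat_kpa(t_sk)

    # respiratory heat losses
    t_exp <- 28.56 + 0.115 * ta + 0.641 * pa
    c_res <- 0.001516 * met * (t_exp - ta)
    e_res <- 0.00127 * met * (59.34 + 0.53 * ta - 11.63 * pa)

    # convective coefficient: forced vs natural, whichever is larger
    h_forced <- if (var > 1) 8.7 * var^0.6 else 3.5 + 5.2 * var
    hc_dyn <- max(2.38 * abs(t_sk - ta)^0.25, h_forced)

    # clothing-surface temperature by fixed-point iteration with the
    # linearized radiative coefficient
    aux_r <- 5.67e-8 * ardu
    h_r <- 0
    for (i in 1:30) {
      h_r <- fcl_r * aux_r * ((t_cl + 273)^4 - (tr + 273)^4) / (t_cl - tr)
      t_cl_new <- (fcl * (hc_dyn * ta + h_r * tr) + t_sk / itot_dyn_si) /
        (fcl * (hc_dyn + h_r) + 1 / itot_dyn_si)
      if (abs(t_cl - t_cl_new) <= 0.001) break
      t_cl <- (t_cl + t_cl_new) / 2
    }
    conv <- fcl * hc_dyn * (t_cl - ta)
    rad <- fcl * h_r * (t_cl - tr)

    # required and maximum evaporation, required sweat rate
    e_max <- (p_sk - pa) / rt_dyn
    e_req <- met - d_stor_eq - wme - c_res - e_res - conv - rad
    if (e_req <= 0) {
      e_req <- 0; sw_req <- 0
    } else if (e_max <= 0) {
      e_max <- 0; sw_req <- sw_max
    } else {
      w_req <- e_req / e_max
      if (w_req >= 1.7) {
        sw_req <- sw_max
      } else {
        ev_eff <- if (w_req > 1) (2 - w_req)^2 / 2 else 1 - w_req^2 / 2
        sw_req <- min(e_req / ev_eff, sw_max)
      }
    }
    sw <- sw * const_sw + sw_req * (1 - const_sw)
    if (sw <= 0) {
      e_p <- 0; sw <- 0
    } else {
      k <- e_max / sw
      wp <- if (k >= 0.5) -k + sqrt(k * k + 2) else 1
      wp <- min(wp, w_max)
      e_p <- wp * e_max
    }

    # heat storage and its split between core and skin compartments
    d_stor <- e_req - e_p + d_stor_eq
    t_cr_n <- t_cr0
    for (i in 1:30) {
      wg <- min(max(0.3 - 0.09 * (t_cr_n - 36.8), 0.1), 0.3)
      t_cr <- d_stor / sp_heat + t_sk0 * wg0 / 2 - t_sk * wg / 2
      t_cr <- (t_cr + t_cr0 * (1 - wg0 / 2)) / (1 - wg / 2)
      if (abs(t_cr - t_cr_n) <= 0.001) break
      t_cr_n <- (t_cr_n + t_cr) / 2
    }
    t_re <- t_re0 + (2 * t_cr - 1.962 * t_re0 - 1.31) / 9

    sw_tot <- sw_tot + sw + e_res
    sw_tot_g <- sw_tot * g_per_wm2min

    if (!all(is.finite(c(t_re, t_cr, t_sk, sw_tot_g)))) {
      stop(sprintf("simulation diverged at minute %d", tm), call. = FALSE)
    }
    if (dlim_tre == 0L && t_re >= 38) dlim_tre <- tm
    if (dlim95 == 0L && sw_tot_g >= d_max_95) dlim95 <- tm
    if (dlim50 == 0L && sw_tot_g >= d_max_50) dlim50 <- tm

    out[tm, -1] <- c(t_re, t_cr, t_sk, sw * 2.67 * adu / 1.8, sw_tot_g,
                     conv, rad, c_res, e_res, e_p, d_stor)
  }

  if (dlim_tre == 0L) dlim_tre <- n
  if (dlim95 == 0L) dlim95 <- n
  if (dlim50 == 0L) dlim50 <- n

  structure(
    list(minutes = out, dlim_tre = dlim_tre, dlim_loss95 = dlim95,
         dlim_loss50 = dlim50, max_time = min(dlim_tre, dlim95),
         dynamic = dyn, scenario_label = scenario$label,
         algorithm = algorithm, use_measured_vw = use_measured_vw,
         vw = vw, var = var, met = met, duration = n),
    class = "phs_result"
  )
}

#' Maximum allowable exposure time
#'
#' The shorter of the rectal-temperature limit (38 degC) and the 5 %
#' dehydration limit, capped at the simulated horizon.
#'
#' @param result A `phs_result` from [phs_simulate()].
#' @return Minutes.
#' @export
max_exposure_time <- function(result) {
  stopifnot(inherits(result, "phs_result"))
  min(result$dlim_tre, result$dlim_loss95, result$duration)
}

#' @export
print.phs_result <- function(x, ...) {
  last <- x$minutes[nrow(x$minutes), ]
  cat(sprintf("PHS result '%s' [%s, vw %s = %.3f m/s, var = %.2f m/s]\n",
              x$scenario_label, x$algorithm,
              if (x$use_measured_vw) "measured" else "estimated", x$vw, x$var))
  cat(sprintf("  final rectal %.2f degC, skin %.2f degC, water loss %.0f g over %d min\n",
              last$t_re, last$t_sk, last$water_loss_g, x$duration))
  cat(sprintf("  Dlimtre = %d min, Dlimloss95 = %d min, max time = %d min\n",
              x$dlim_tre, x$dlim_loss95, x$max_time))
  invisible(x)
}
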