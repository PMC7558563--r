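# Scenario registry and the algorithm-comparison machinery: the nine
# climate-chamber exposures, the algorithm x walking-speed-input run matrix,
# and the dynamic-property comparison grids.

#' Packaged exposure scenarios
#'
#' The nine climate-chamber exposures used to compare the clothing-dynamics
#' algorithms: one light-clothing (LC), six normal-clothing (NC-1..NC-6) and
#' two cold-weather (SC-1, SC-2) conditions. All share an air velocity of
#' 0.33 m/s, a measured (treadmill) walking speed of 1.25 m/s and a 70-min
#' horizon; mean radiant temperature equals air temperature. Subjects are
#' unacclimatized males free to drink: 80 kg / 1.78 m for NC and SC,
#' 77 kg / 1.76 m for LC.
#'
#' @return A named list of [phs_scenario()] objects.
#' @export
chamber_scenarios <- function() {
  sub_ncsc <- phs_subject(height = 1.78, weight = 80)
  sub_lc <- phs_subject(height = 1.76, weight = 77)
  rows <- list(
    #          icl    rt      imt   ta  pw   met
    LC     = c(0.48, 0.0198, 0.49, 30, 2.0, 163),
    `NC-1` = c(0.63, 0.0257, 0.43, 20, 2.0, 169),
    `NC-2` = c(0.63, 0.0257, 0.43, 40, 2.2, 171),
    `NC-3` = c(1.08, 0.0421, 0.36, 20, 2.0, 163),
    `NC-4` = c(1.08, 0.0421, 0.37, 40, 3.3, 155),
    `NC-5` = c(1.11, 0.0745, 0.21, 20, 2.0, 167),
    `NC-6` = c(1.11, 0.0745, 0.21, 30, 2.0, 175),
    `SC-1` = c(2.01, 0.1224, 0.20, 30, 2.0, 190),
    `SC-2` = c(2.01, 0.1224, 0.20, 40, 2.2, 190)
  )
  out <- lapply(names(rows), function(lab) {
    p <- rows[[lab]]
    phs_scenario(
      label = lab,
      ensemble = clothing_ensemble(icl = p[1], rt_static = p[2], imt = p[3]),
      ta = p[4], pw = p[5], va = 0.33, vw_measured = 1.25, met = p[6],
      duration = 70,
      subject = if (lab == "LC") sub_lc else sub_ncsc
    )
  })
  names(out) <- names(rows)
  out
}

# Algorithms applicable to a clothing category.
algorithms_for_category <- function(category) {
  if (category == "LC") c("ISO7933", "ISO9920", "LU") else c("ISO7933", "ISO9920")
}

#' Run the scenario x algorithm x walking-speed-input matrix
#'
#' Simulates every scenario under each applicable clothing-dynamics algorithm
#' (ISO 7933 and ISO 9920 everywhere; Lu additionally for light clothing),
#' once with the walking speed estimated from the metabolic rate and once
#' with the measured walking speed. Simulation errors are reported per row
#' without aborting the matrix.
#'
#' @param scenarios A list of [phs_scenario()] objects; defaults to the
#'   packaged registry [chamber_scenarios()].
#' @param vw_mode Passed to [phs_simulate()] for the measured-speed rows.
#' @return A data frame with one row per scenario x algorithm x input mode:
#'   duration limits (min), maximum allowable time, final rectal temperature
#'   (degC) and total water loss (g).
#' @export
phs_run_matrix <- function(scenarios = chamber_scenarios(), vw_mode = "max") {
  rows <- list()
  for (sc in scenarios) {
    for (algo in algorithms_for_category(sc$ensemble$category)) {
      for (measured in c(FALSE, TRUE)) {
        row <- data.frame(scenario = sc$label,
                          category = sc$ensemble$category,
                          algorithm = algo,
                          vw_input = if (measured) "measured" else "estimated",
                          dlim_tre = NA_integer_, dlim_loss95 = NA_integer_,
                          max_time = NA_integer_, t_re_final = NA_real_,
                          water_loss_g = NA_real_,
                          stringsAsFactors = FALSE)
        res <- tryCatch(
          suppressMessages(phs_simulate(sc, algo, use_measured_vw = measured,
                                        vw_mode = vw_mode)),
          error = function(e) {
            message(sprintf("row %s/%s/%s failed: %s", sc$label, algo,
                            if (measured) "measured" else "estimated",
                            conditionMessage(e)))
            NULL
          })
        if (!is.null(res)) {
          last <- res$minutes[nrow(res$minutes), ]
          row$dlim_tre <- res$dlim_tre
          row$dlim_loss95 <- res$dlim_loss95
          row$max_time <- res$max_time
          row$t_re_final <- last$t_re
          row$water_loss_g <- last$water_loss_g
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Basic-insulation subsets per category for the comparison grids.
grid_icl_values <- function(category, quantity) {
  if (quantity == "insulation") {
    switch(category, NC = c(0.6, 0.8, 1.0), SC = c(1.5, 2.0), LC = c(0.2, 0.4))
  } else {
    switch(category, NC = 1.0, SC = 2.0, LC = 0.4)
  }
}

# A plausible static moisture path for a grid-only ensemble: permeability
# index 0.38 (the conventional default) and the Lewis-consistent static
# resistance. The grids compare correction factors, so only ratios matter.
grid_ensemble <- function(icl) {
  itot <- icl + IA_STATIC_CLO / fcl_ratio(icl)
  imt <- 0.38
  clothing_ensemble(icl = icl, rt_static = itot * CLO_TO_SI / (imt * LEWIS),
                    imt = imt)
}

#' Algorithm-comparison grid of dynamic clothing properties
#'
#' Evaluates every applicable correction algorithm over the speed grid
#' (air speed 0.5/1/3 m/s, walking speed 0.4/0.8/1.2 m/s) and the
#' category's basic-insulation values. The grid's air speed is taken as the
#' relative air velocity seen by the correction formulas.
#'
#' @param category `"NC"`, `"SC"` or `"LC"`.
#' @param quantity `"insulation"` (category's full insulation subset) or
#'   `"evaporative_resistance"` (the single representative insulation:
#'   0.4 clo LC, 1 clo NC, 2 clo SC).
#' @param va,vw Grid speeds, m/s.
#' @param pr Air permeability for the SC ISO 9920 correction, L/m^2.s.
#' @return A data frame with one row per algorithm x insulation x speed
#'   combination and the dynamic quantities of [dynamic_clothing()].
#' @export
comparison_grid <- function(category = c("NC", "SC", "LC"),
                            quantity = c("insulation", "evaporative_resistance"),
                            va = c(0.5, 1, 3), vw = c(0.4, 0.8, 1.2), pr = 1) {
  category <- match.arg(category)
  quantity <- match.arg(quantity)
  icls <- grid_icl_values(category, quantity)
  algos <- if (quantity == "insulation") algorithms_for_category(category)
           else c("ISO7933", "ISO9920")
  cells <- expand.grid(algorithm = algos, icl_clo = icls, va_ms = va,
                       vw_ms = vw, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    ens <- grid_ensemble(cells$icl_clo[i])
    ens$pr <- pr
    kin <- kinematics(va = cells$va_ms[i], vw = cells$vw_ms[i],
                      var = cells$va_ms[i])
    dyn <- suppressMessages(dynamic_clothing(ens, kin, cells$algorithm[i]))
    data.frame(corr_tot = dyn$corr_tot, corr_a = dyn$corr_a,
               itot_dyn_clo = dyn$itot_dyn, ia_dyn_clo = dyn$ia_dyn,
               icl_dyn_clo = dyn$icl_dyn, rt_dyn = dyn$rt_dyn,
               imt_dyn = dyn$imt_dyn, clamped = dyn$clamped)
  })
  cbind(cells, do.call(rbind, res))
}

#' Pairwise percent difference over a comparison grid
#'
#' Percent difference of a dynamic quantity between two algorithms at every
#' grid point, as `100 * (other - baseline) / baseline` reported in absolute
#' value; ISO 7933, the incumbent standard, is the default baseline.
#'
#' @param grid Output of [comparison_grid()].
#' @param value Column to compare (default the clothing dynamic insulation).
#' @param baseline,other Algorithm labels present in `grid`.
#' @return The grid cells (insulation and speeds) with columns `baseline`,
#'   `other` and `pct_diff`.
#' @export
grid_percent_difference <- function(grid, value = "icl_dyn_clo",
                                    baseline = "ISO7933", other = "ISO9920") {
  stopifnot(value %in% names(grid))
  b <- grid[grid$algorithm == baseline, ]
  o <- grid[grid$algorithm == other, ]
  key <- c("icl_clo", "va_ms", "vw_ms")
  m <- merge(b[, c(key, value)], o[, c(key, value)], by = key,
             suffixes = c("_baseline", "_other"))
  m$pct_diff <- 100 * abs(m[[paste0(value, "_other")]] -
                          m[[paste0(value, "_baseline")]]) /
    m[[paste0(value, "_baseline")]]
  names(m)[names(m) == paste0(value, "_baseline")] <- "baseline"
  names(m)[names(m) == paste0(value, "_other")] <- "other"
  m[order(m$icl_clo, m$va_ms, m$vw_ms), ]
}
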