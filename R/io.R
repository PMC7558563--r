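# Plain-text configuration and result files.

# Parse "key = value" lines; '#' starts a comment; keys are
# case-insensitive.
parse_key_values <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) {
    stop(sprintf("cannot parse config line: '%s'", lines[bad][1]), call. = FALSE)
  }
  out <- lapply(kv, `[`, 3L)
  names(out) <- tolower(vapply(kv, `[`, "", 2L))
  lapply(out, trimws)
}

num_or <- function(x, default = NULL) {
  if (is.null(x)) return(default)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop(sprintf("not a number: '%s'", x), call. = FALSE)
  v
}

flag_or <- function(x, default) {
  if (is.null(x)) return(default)
  tolower(x) %in% c("true", "yes", "1")
}

#' Read a scenario from a plain-text config file
#'
#' The file holds `key = value` lines (units as in the package: clo,
#' m^2.kPa/W, degC, kPa, m/s, W/m^2, min, kg, m). Recognized keys:
#' `label`, `icl`, `rt_static`, `imt`, `pr`, `ta`, `tr`, `pw`, `va`, `vw`,
#' `met`, `duration`, `weight`, `height`, `acclimatized`, `drink`. `tr`
#' defaults to `ta`; omit `vw` for walking speed estimated from the
#' metabolic rate.
#'
#' @param path Config file path.
#' @return A [phs_scenario()].
#' @export
read_scenario_config <- function(path) {
  kv <- parse_key_values(path)
  need <- c("icl", "rt_static", "imt", "ta", "pw", "va", "met")
  missing <- setdiff(need, names(kv))
  if (length(missing)) {
    stop(sprintf("scenario config is missing: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  ens <- clothing_ensemble(icl = num_or(kv$icl), rt_static = num_or(kv$rt_static),
                           imt = num_or(kv$imt), pr = num_or(kv$pr, 1))
  sub <- phs_subject(height = num_or(kv$height, 1.78),
                     weight = num_or(kv$weight, 80),
                     acclimatized = flag_or(kv$acclimatized, FALSE),
                     drink = flag_or(kv$drink, TRUE))
  ta <- num_or(kv$ta)
  phs_scenario(label = if (is.null(kv$label)) basename(path) else kv$label,
               ensemble = ens, ta = ta, tr = num_or(kv$tr, ta),
               pw = num_or(kv$pw), va = num_or(kv$va),
               vw_measured = num_or(kv$vw, NULL), met = num_or(kv$met),
               duration = num_or(kv$duration, 70), subject = sub)
}

#' Write the per-minute trajectory of a simulation as CSV
#'
#' Columns: `minute, tre_C, tsk_C, tcr_C, swp_g_per_h, swtot_g`.
#'
#' @param result A `phs_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_minutes_csv <- function(result, path) {
  stopifnot(inherits(result, "phs_result"))
  m <- result$minutes
  out <- data.frame(minute = m$minute, tre_C = m$t_re, tsk_C = m$t_sk,
                    tcr_C = m$t_cr, swp_g_per_h = m$sweat_rate_gh,
                    swtot_g = m$water_loss_g)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulation summary as JSON
#'
#' @param result A `phs_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(result, path) {
  stopifnot(inherits(result, "phs_result"))
  last <- result$minutes[nrow(result$minutes), ]
  jsonlite::write_json(
    list(scenario = result$scenario_label, algorithm = result$algorithm,
         use_measured_vw = result$use_measured_vw,
         walking_speed_ms = result$vw, relative_air_velocity_ms = result$var,
         dlim_tre = result$dlim_tre, dlim_loss95 = result$dlim_loss95,
         dlim_loss50 = result$dlim_loss50, max_time = result$max_time,
         t_re_final = last$t_re, water_loss_g = last$water_loss_g),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
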