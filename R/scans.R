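scan_summary <- function(traj, label_name, label_value, eval_days) {
  et <- eval_table(traj)
  tibble::tibble(
    !!label_name := label_value,
    eval_day = et$time_days,
    cancer = et$C,
    total_cells = et$total_cells
  )
}

new_scan <- function(summary, trajectories, axis) {
  structure(summary, class = c("folfiri_scan", class(summary)),
            trajectories = trajectories, axis = axis)
}

#' Trajectories of a scan result
#' @param scan A `folfiri_scan`.
#' @return Named list of `folfiri_trajectory` objects, one per scan point.
#' @export
scan_trajectories <- function(scan) attr(scan, "trajectories")

#' Drug-combination scan
#'
#' Simulates the four FOLFIRI arms — 5-FU alone, 5-FU + leucovorin,
#' 5-FU + irinotecan, and all three drugs — by zeroing the complementary
#' doses of the given regimen; solver settings are identical across arms.
#'
#' @param initial Initial state (default: steady state, i.e. a large tumor).
#' @param params A [folfiri_params()].
#' @param reg Base [regimen()] (median doses by default).
#' @param eval_days,horizon,... Passed to [simulate_tme()].
#' @return A `folfiri_scan` tibble with columns `arm`, `eval_day`, `cancer`,
#'   `total_cells`; per-arm trajectories via [scan_trajectories()].
#' @export
combination_scan <- function(initial = state_vector(), params,
                             reg = regimen(), eval_days = EVAL_DAYS,
                             horizon = 3285, ...) {
  arms <- list(
    "5FU"       = regimen_with(reg, dose_lv = 0, dose_ir = 0),
    "5FU+LV"    = regimen_with(reg, dose_ir = 0),
    "5FU+Ir"    = regimen_with(reg, dose_lv = 0),
    "5FU+LV+Ir" = reg
  )
  trajs <- purrr::map(arms, function(r) {
    simulate_tme(initial, params, r, horizon = horizon,
                 eval_days = eval_days, ...)
  })
  summary <- purrr::imap(trajs, function(tr, nm) {
    scan_summary(tr, "arm", nm, eval_days)
  }) |> purrr::list_rbind()
  new_scan(summary, trajs, "arm")
}

regimen_with <- function(reg, ...) {
  args <- utils::modifyList(
    list(dose_5fu = reg$dose_5fu, dose_lv = reg$dose_lv, dose_ir = reg$dose_ir,
         n_cycles = reg$n_cycles, cycle_length = reg$cycle_length,
         start_day = reg$start_day, infusion_hours = reg$infusion_hours),
    list(...)
  )
  do.call(regimen, args)
}

#' Treatment start-time scan
#'
#' Delays the whole regimen by 1, 3, 5, 7 years (by default); the system
#' evolves untreated before the start day. The recommended initial
#' conditions are the smallest-tumor states
#' ([cluster_initial_conditions()]).
#'
#' @param initial Initial state.
#' @param params A [folfiri_params()].
#' @param reg Base [regimen()]; its `start_day` is replaced per scan point.
#' @param start_years Numeric vector of start times in years.
#' @param post_days Days simulated beyond the end of treatment (default two
#'   years).
#' @param ... Passed to [simulate_tme()].
#' @return A `folfiri_scan` tibble with columns `start_year`, `eval_day`
#'   (days counted from the treatment start), `cancer`, `total_cells`.
#' @export
start_time_scan <- function(initial, params, reg = regimen(),
                            start_years = c(1, 3, 5, 7), post_days = 730,
                            ...) {
  start_years <- sort(unique(start_years))
  treat_span <- (reg$n_cycles - 1) * reg$cycle_length +
    sum(reg$infusion_hours) / 24
  rel_days <- c(0, 169, 365, 730)
  trajs <- purrr::map(start_years, function(yr) {
    start <- 365 * yr
    r <- regimen_with(reg, start_day = start)
    horizon <- start + treat_span + post_days
    simulate_tme(initial, params, r, horizon = horizon,
                 eval_days = start + rel_days[start + rel_days <= horizon],
                 ...)
  })
  names(trajs) <- paste0("year", start_years)
  summary <- purrr::map2(trajs, start_years, function(tr, yr) {
    et <- eval_table(tr)
    tibble::tibble(start_year = yr, eval_day = et$time_days - 365 * yr,
                   cancer = et$C, total_cells = et$total_cells)
  }) |> purrr::list_rbind()
  new_scan(summary, trajs, "start_year")
}

#' Dose scan for one drug
#'
#' Scales one drug's dose by each multiplier while holding the others at the
#' regimen's values.
#'
#' @param reg Patient [regimen()].
#' @param params A [folfiri_params()].
#' @param initial Initial state.
#' @param multipliers Positive dose multipliers (default grid spans 0.1-10x).
#' @param target_drug One of `"fu"`, `"lv"`, `"ir"`.
#' @param eval_days,horizon,... Passed to [simulate_tme()].
#' @return A `folfiri_scan` tibble with columns `multiplier`, `eval_day`,
#'   `cancer`, `total_cells`.
#' @export
dose_scan <- function(reg, params, initial = state_vector(),
                      multipliers = c(0.1, 0.25, 0.5, 1, 2, 5, 10),
                      target_drug = c("lv", "fu", "ir"),
                      eval_days = EVAL_DAYS, horizon = 3285, ...) {
  target_drug <- match.arg(target_drug)
  stopifnot(all(multipliers >= 0))
  multipliers <- sort(unique(multipliers))
  field <- switch(target_drug, fu = "dose_5fu", lv = "dose_lv", ir = "dose_ir")
  trajs <- purrr::map(multipliers, function(m) {
    args <- stats::setNames(list(reg[[field]] * m), field)
    r <- do.call(regimen_with, c(list(reg), args))
    simulate_tme(initial, params, r, horizon = horizon,
                 eval_days = eval_days, ...)
  })
  names(trajs) <- paste0("x", multipliers)
  summary <- purrr::map2(trajs, multipliers, function(tr, m) {
    scan_summary(tr, "multiplier", m, eval_days)
  }) |> purrr::list_rbind()
  new_scan(summary, trajs, "multiplier")
}

#' Treatment-parameter scan
#'
#' Scales one treatment rate parameter by each multiplier (default grid spans
#' 0.1-5) and records cancer and total-cell densities at the evaluation
#' days; initial conditions default to the steady state (large tumors).
#'
#' @param params A [folfiri_params()].
#' @param param_name A treatment rate parameter, e.g. `"delta_CLV5fu"` or
#'   `"delta_5fuM"`.
#' @param initial Initial state.
#' @param reg [regimen()] used for every scan point.
#' @param multipliers Positive parameter multipliers.
#' @param eval_days,horizon,... Passed to [simulate_tme()].
#' @return A `folfiri_scan` tibble with columns `multiplier`, `eval_day`,
#'   `cancer`, `total_cells`.
#' @export
parameter_scan <- function(params, param_name, initial = state_vector(),
                           reg = regimen(),
                           multipliers = c(0.1, 0.5, 1, 2, 5),
                           eval_days = EVAL_DAYS, horizon = 3285, ...) {
  valid <- setdiff(TREATMENT_PARAM_NAMES,
                   c("A_5fu_daily", "A_LV_daily", "A_Ir_daily"))
  if (!param_name %in% valid) {
    stop("unknown treatment parameter '", param_name, "'; valid names: ",
         paste(valid, collapse = ", "))
  }
  stopifnot(all(multipliers >= 0))
  multipliers <- sort(unique(multipliers))
  trajs <- purrr::map(multipliers, function(m) {
    pt <- params$treatment
    pt[param_name] <- pt[param_name] * m
    simulate_tme(initial, folfiri_params(params$baseline, pt), reg,
                 horizon = horizon, eval_days = eval_days, ...)
  })
  names(trajs) <- paste0("x", multipliers)
  summary <- purrr::map2(trajs, multipliers, function(tr, m) {
    scan_summary(tr, "multiplier", m, eval_days)
  }) |> purrr::list_rbind()
  out <- new_scan(summary, trajs, "multiplier")
  attr(out, "param_name") <- param_name
  out
}
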