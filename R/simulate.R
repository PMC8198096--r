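#' Default evaluation days for scan summaries
#'
#' 169 days (just after the 12th cycle of the default schedule ends) and
#' years 1, 2, 3, 5 and 9.
#' @export
EVAL_DAYS <- c(169, 365, 730, 1095, 1825, 3285)

scaling_from_params <- function(params) {
  pt <- params$treatment
  structure(list(
    delta = c(fu = pt[["delta_5fu"]], lv = pt[["delta_LV"]],
              ir = pt[["delta_Ir"]]),
    A_daily = c(fu = pt[["A_5fu_daily"]], lv = pt[["A_LV_daily"]],
                ir = pt[["A_Ir_daily"]]),
    scale = c(fu = pt[["delta_5fu"]] / pt[["A_5fu_daily"]],
              lv = pt[["delta_LV"]] / pt[["A_LV_daily"]],
              ir = pt[["delta_Ir"]] / pt[["A_Ir_daily"]])
  ), class = "drug_scaling")
}

#' Simulate the treated (or untreated) tumor-microenvironment system
#'
#' Integrates the 17-variable system with the dimensionless infusion forcing
#' of the given regimen. Integration uses a stiff-capable solver
#' (`deSolve::lsoda`) with tight tolerances and is restarted at every
#' infusion breakpoint, so the piecewise-constant forcing is never stepped
#' over; within each segment the injection rate is exactly constant. A
#' zero-dose (or zero-cycle) regimen reproduces the untreated dynamics.
#'
#' @param initial 17-component named state ([state_vector()]); 14-component
#'   states are accepted and get zero drug levels appended.
#' @param params A [folfiri_params()] with a treatment block.
#' @param reg A [regimen()].
#' @param horizon Simulation end (days; default 9 years).
#' @param eval_days Times (subset of `[0, horizon]`) at which the full state
#'   is tabulated in the trajectory's evaluation table.
#' @param dt_out Output grid spacing in days (default 1); breakpoints and
#'   `eval_days` are always included exactly.
#' @param rtol,atol Solver tolerances (defaults `1e-8`, `1e-10`).
#' @return A `folfiri_trajectory`: a tibble with column `time_days` and one
#'   column per state variable, plus a `total_cells` column; attributes carry
#'   the regimen, a parameter fingerprint, and the evaluation-day table.
#' @export
simulate_tme <- function(initial = state_vector(), params, reg = regimen(),
                         horizon = 3285, eval_days = EVAL_DAYS,
                         dt_out = 1, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "folfiri_params"), horizon > 0)
  if (is.null(params$treatment)) {
    stop("params has no treatment block; derive one with derive_params()")
  }
  y0 <- unname(initial)
  if (length(y0) == 14L) y0 <- c(y0, 0, 0, 0)
  validate_state(stats::setNames(y0, STATE_NAMES))
  eval_days <- sort(unique(eval_days[eval_days <= horizon & eval_days >= 0]))

  pb <- params$baseline
  pt <- params$treatment
  scaling <- scaling_from_params(params)
  inj <- dimensionless_injection(reg, scaling)

  seg <- sort(unique(c(0, regimen_breakpoints(reg, horizon), horizon)))
  times <- sort(unique(c(seq(0, horizon, by = dt_out), eval_days, seg)))

  rows <- vector("list", length(seg) - 1L)
  y <- y0
  for (i in seq_len(length(seg) - 1L)) {
    a <- seg[i]; b <- seg[i + 1L]
    tt <- times[times >= a & times <= b]
    if (tt[1] > a) tt <- c(a, tt)
    if (tt[length(tt)] < b) tt <- c(tt, b)
    u <- as.numeric(inj((a + b) / 2))
    sol <- deSolve::lsoda(
      y = y, times = tt,
      func = function(t, y, p) list(rhs_treatment_core(y, pb, pt, u)),
      parms = NULL, rtol = rtol, atol = atol, maxsteps = 50000L
    )
    if (attr(sol, "istate")[1L] < 0 || sol[nrow(sol), 1L] < b) {
      stop("integration failed in segment [", a, ", ", b, "]; last successful ",
           "time ", sol[nrow(sol), 1L], "; state: ",
           paste(format(sol[nrow(sol), -1L], digits = 6), collapse = ", "))
    }
    rows[[i]] <- if (i == 1L) sol else sol[-1L, , drop = FALSE]
    y <- as.numeric(sol[nrow(sol), -1L])
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("time_days", STATE_NAMES)

  if (min(m[, STATE_NAMES]) < -10 * atol) {
    bad <- STATE_NAMES[apply(m[, STATE_NAMES, drop = FALSE], 2, min) < -10 * atol]
    stop("state went negative beyond solver tolerance: ",
         paste(bad, collapse = ", "))
  }

  out <- tibble::as_tibble(as.data.frame(m))
  out$total_cells <- rowSums(m[, CELL_STATE_NAMES, drop = FALSE])

  # net cancer-death bracket may go negative at extreme macrophage excess
  # (the macrophage term enters with a minus sign); report, don't clamp
  br <- apply(m[, STATE_NAMES, drop = FALSE], 1L,
              function(x) death_rate_C_treat(x, pb, pt))
  frac_neg <- mean(br < 0)
  if (frac_neg > 0.01) {
    warning(sprintf(
      "net cancer-death bracket negative at %.1f%% of evaluation points",
      100 * frac_neg))
  }

  eval_tab <- out[out$time_days %in% eval_days, , drop = FALSE]
  structure(out,
            class = c("folfiri_trajectory", class(out)),
            regimen = reg,
            fingerprint = param_fingerprint(params, reg),
            eval_table = eval_tab)
}

#' Evaluation-day table of a trajectory
#'
#' @param traj A `folfiri_trajectory`.
#' @return Tibble of full states at the requested evaluation days.
#' @export
eval_table <- function(traj) {
  attr(traj, "eval_table")
}

#' State at a given day (linear interpolation on the output grid)
#'
#' @param traj A `folfiri_trajectory`.
#' @param day Time in days within the simulated horizon.
#' @param var Variable name (default `"C"`, the cancer density).
#' @return Numeric value(s).
#' @export
state_at <- function(traj, day, var = "C") {
  rng <- range(traj$time_days)
  if (any(day < rng[1] | day > rng[2])) {
    stop("day outside the simulated horizon [", rng[1], ", ", rng[2], "]")
  }
  stats::approx(traj$time_days, traj[[var]], xout = day, ties = "ordered")$y
}

#' @export
print.folfiri_trajectory <- function(x, ...) {
  reg <- attr(x, "regimen")
  cat("<folfiri_trajectory> ", nrow(x), " time points over ",
      format(max(x$time_days)), " days\n", sep = "")
  if (!is.null(reg)) print(reg)
  NextMethod()
}
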