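#' FOLFIRI administration schedule
#'
#' A regimen is the clinically shaped repetitive cycle: a one-hour drip of
#' irinotecan, followed by a one-hour drip of leucovorin, after which 5-FU is
#' continuously infused for 46 hours; the pattern repeats every
#' `cycle_length` days for `n_cycles` cycles starting at `start_day`.
#'
#' @param dose_5fu,dose_lv,dose_ir Dose per cycle in mg. Defaults are the
#'   cohort medians (770 / 725 / 300 mg).
#' @param n_cycles Number of cycles (default 12).
#' @param cycle_length Days per cycle (default 14); must exceed the total
#'   infusion span of 48 h.
#' @param start_day Day treatment begins (default 0).
#' @param infusion_hours Named numeric: infusion durations in hours for
#'   `ir`, `lv`, `fu` (defaults 1, 1, 46), administered back-to-back in that
#'   order.
#' @return An object of class `folfiri_regimen`.
#' @export
regimen <- function(dose_5fu = 770, dose_lv = 725, dose_ir = 300,
                    n_cycles = 12, cycle_length = 14, start_day = 0,
                    infusion_hours = c(ir = 1, lv = 1, fu = 46)) {
  stopifnot(dose_5fu >= 0, dose_lv >= 0, dose_ir >= 0,
            n_cycles >= 0, start_day >= 0,
            all(c("ir", "lv", "fu") %in% names(infusion_hours)),
            all(infusion_hours > 0))
  span_days <- sum(infusion_hours[c("ir", "lv", "fu")]) / 24
  if (cycle_length <= span_days) {
    stop("cycle_length (", cycle_length, " d) must exceed the total infusion ",
         "span (", format(span_days), " d)")
  }
  structure(
    list(dose_5fu = dose_5fu, dose_lv = dose_lv, dose_ir = dose_ir,
         n_cycles = n_cycles, cycle_length = cycle_length,
         start_day = start_day,
         infusion_hours = infusion_hours[c("ir", "lv", "fu")]),
    class = "folfiri_regimen"
  )
}

#' @export
print.folfiri_regimen <- function(x, ...) {
  cat("<folfiri_regimen> ", x$dose_5fu, "/", x$dose_lv, "/", x$dose_ir,
      " mg (5-FU/LV/Ir), ", x$n_cycles, " cycles of ", x$cycle_length,
      " d, start day ", x$start_day, "\n", sep = "")
  invisible(x)
}

treatment_end_day <- function(reg) {
  if (reg$n_cycles == 0) return(reg$start_day)
  reg$start_day + (reg$n_cycles - 1) * reg$cycle_length +
    sum(reg$infusion_hours) / 24
}

# phase boundaries of one cycle (days from cycle start): ir | lv | fu | off
cycle_phase_bounds <- function(reg) {
  unname(cumsum(c(0, reg$infusion_hours))) / 24
}

#' Infusion rates at given times
#'
#' Piecewise-constant injection-rate step functions in mg/day. Within cycle
#' `k` (cycle start `s = start_day + k * cycle_length`), irinotecan runs on
#' `[s, s + 1/24)` at `dose_ir * 24` mg/day, leucovorin on
#' `[s + 1/24, s + 2/24)` at `dose_lv * 24` mg/day, and 5-FU on
#' `[s + 2/24, s + 2)` at `dose_5fu * 24/46` mg/day; rates are zero elsewhere
#' and after the last cycle. Intervals are half-open: a breakpoint belongs to
#' the later interval.
#'
#' @param t Numeric vector of times in days (all `>= 0`).
#' @param reg A [regimen()].
#' @return A tibble with columns `time_days`, `rate_5fu`, `rate_lv`,
#'   `rate_ir` (mg/day), one row per element of `t`.
#' @export
infusion_rates <- function(t, reg) {
  stopifnot(inherits(reg, "folfiri_regimen"))
  if (any(t < 0)) stop("t must be non-negative")
  b <- cycle_phase_bounds(reg)
  dur <- reg$infusion_hours / 24
  rate <- c(ir = reg$dose_ir, lv = reg$dose_lv, fu = reg$dose_5fu) / dur
  rel <- t - reg$start_day
  k <- floor(rel / reg$cycle_length)
  phase <- rel - k * reg$cycle_length
  in_cycle <- rel >= 0 & k <= (reg$n_cycles - 1)
  ir <- unname(ifelse(in_cycle & phase >= b[1] & phase < b[2], rate[["ir"]], 0))
  lv <- unname(ifelse(in_cycle & phase >= b[2] & phase < b[3], rate[["lv"]], 0))
  fu <- unname(ifelse(in_cycle & phase >= b[3] & phase < b[4], rate[["fu"]], 0))
  tibble::tibble(time_days = unname(t), rate_5fu = fu, rate_lv = lv,
                 rate_ir = ir)
}

#' Drug non-dimensionalization scales
#'
#' Each drug concentration is rescaled as `Dbar = delta_D * [D] / A_daily`,
#' where `delta_D` is its natural (first-order) decay rate and `A_daily` the
#' cohort daily-median dose per cycle (median dose per cycle divided by the
#' cycle length in days). Under a hypothetical continuous infusion at exactly
#' the daily-median rate with no consumption, `Dbar` equilibrates to 1.
#'
#' @param delta Named numeric: decay rates (per day) for `fu`, `lv`, `ir`.
#' @param median_dose Named numeric: cohort median doses per cycle (mg) for
#'   `fu`, `lv`, `ir` (defaults to the packaged treatment table).
#' @param cycle_length Cycle length in days used for the daily median
#'   (default 14).
#' @return An object of class `drug_scaling`: per-drug `delta`, `A_daily`
#'   (mg/day) and the scale factor `delta / A_daily`.
#' @export
drug_scaling <- function(delta,
                         median_dose = c(fu = 770, lv = 725, ir = 300),
                         cycle_length = 14) {
  stopifnot(all(c("fu", "lv", "ir") %in% names(delta)),
            all(delta > 0),
            all(c("fu", "lv", "ir") %in% names(median_dose)),
            all(median_dose > 0), cycle_length > 0)
  delta <- delta[c("fu", "lv", "ir")]
  A_daily <- median_dose[c("fu", "lv", "ir")] / cycle_length
  structure(list(delta = delta, A_daily = A_daily,
                 scale = delta / A_daily),
            class = "drug_scaling")
}

#' Dimensionless injection-rate function
#'
#' Converts a regimen's mg/day infusion step functions into the dimensionless
#' drug scale: rate of change contributed to `Dbar` is
#' `(delta_D / A_daily_D) * A_injD(t)`.
#'
#' @param reg A [regimen()].
#' @param scaling A [drug_scaling()].
#' @return A function `f(t)` returning, for a scalar or vector `t`, a matrix
#'   with columns `FU`, `LV`, `Ir` of dimensionless injection rates (per
#'   day).
#' @export
dimensionless_injection <- function(reg, scaling) {
  stopifnot(inherits(reg, "folfiri_regimen"), inherits(scaling, "drug_scaling"))
  doses <- c(fu = reg$dose_5fu, lv = reg$dose_lv, ir = reg$dose_ir)
  bad <- doses > 0 & scaling$A_daily[names(doses)] <= 0
  if (any(bad)) {
    stop("zero daily-median dose with nonzero prescribed dose for: ",
         paste(names(doses)[bad], collapse = ", "))
  }
  s <- scaling$scale
  function(t) {
    r <- infusion_rates(t, reg)
    cbind(FU = s[["fu"]] * r$rate_5fu,
          LV = s[["lv"]] * r$rate_lv,
          Ir = s[["ir"]] * r$rate_ir)
  }
}

#' Infusion breakpoints of a regimen
#'
#' All times at which an injection rate switches value, within `[0, horizon]`.
#' The integrator is restarted at each of these so that discontinuities in
#' the forcing are never stepped over.
#'
#' @param reg A [regimen()].
#' @param horizon Last time of interest (days).
#' @return Sorted numeric vector of breakpoint times (days).
#' @export
regimen_breakpoints <- function(reg, horizon) {
  if (reg$n_cycles == 0) return(numeric(0))
  starts <- reg$start_day + (seq_len(reg$n_cycles) - 1) * reg$cycle_length
  b <- cycle_phase_bounds(reg)
  bp <- as.vector(outer(b, starts, `+`))
  sort(unique(bp[bp > 0 & bp < horizon]))
}

# Closed-form pure-decay concentration profiles over one cycle (no carryover,
# no consumption): used to calibrate kill rates from per-cycle efficiencies.
# Returns a function Dbar(t) for t in days from cycle start.
decay_profile <- function(dose, duration_days, offset_days, delta, A_daily) {
  u <- delta * (dose / duration_days) / A_daily   # dimensionless inj rate
  plateau <- u / delta
  t_on <- offset_days
  t_off <- offset_days + duration_days
  peak <- plateau * (1 - exp(-delta * duration_days))
  function(t) {
    ifelse(t < t_on, 0,
           ifelse(t < t_off, plateau * (1 - exp(-delta * (t - t_on))),
                  peak * exp(-delta * (t - t_off))))
  }
}

#' Per-cycle dimensionless drug exposures under the median regimen
#'
#' Exposure is the time integral of the dimensionless concentration over one
#' cycle assuming pure first-order decay (no consumption, no carryover). For
#' a single drug this equals `dose / A_daily` in closed form (the full cycle
#' length for the median dose); the 5-FU x leucovorin product exposure, used
#' to calibrate the combined kill rate, is integrated numerically from the
#' closed-form profiles.
#'
#' @param reg A [regimen()].
#' @param scaling A [drug_scaling()].
#' @return Named numeric: `fu`, `lv`, `ir` (dimensionless-days) and `fu_lv`
#'   (the product integral).
#' @export
drug_exposure <- function(reg, scaling) {
  stopifnot(inherits(reg, "folfiri_regimen"), inherits(scaling, "drug_scaling"))
  b <- cycle_phase_bounds(reg)
  dur <- reg$infusion_hours / 24
  single <- c(
    fu = reg$dose_5fu / scaling$A_daily[["fu"]],
    lv = reg$dose_lv / scaling$A_daily[["lv"]],
    ir = reg$dose_ir / scaling$A_daily[["ir"]]
  )
  f_fu <- decay_profile(reg$dose_5fu, dur[["fu"]], b[3], scaling$delta[["fu"]],
                        scaling$A_daily[["fu"]])
  f_lv <- decay_profile(reg$dose_lv, dur[["lv"]], b[2], scaling$delta[["lv"]],
                        scaling$A_daily[["lv"]])
  if (reg$dose_5fu == 0 || reg$dose_lv == 0) {
    fu_lv <- 0
  } else {
    fu_lv <- stats::integrate(function(t) f_fu(t) * f_lv(t),
                              lower = b[3], upper = reg$cycle_length,
                              subdivisions = 2000L, rel.tol = 1e-10)$value
  }
  c(single, fu_lv = unname(fu_lv))
}
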