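test_that("a zero-dose run from steady state stays at the equilibrium", {
  p <- default_params_cached()
  tr <- simulate_tme(state_vector(), p, zero_dose_regimen(), horizon = 365)
  expect_lt(max(abs(as.matrix(tr[, BASELINE_STATE_NAMES]) - 1)), 1e-6)
  expect_equal(max(as.matrix(tr[, DRUG_STATE_NAMES])), 0)
})

test_that("the median regimen lowers cancer below its untreated value in every cluster", {
  p <- default_params_cached()
  end_day <- 168
  for (cl in 1:5) {
    ic <- cluster_initial_conditions(cl, "smallest")
    treated <- simulate_tme(ic, p, regimen(), horizon = 170,
                            eval_days = end_day)
    untreated <- simulate_tme(ic, p, zero_dose_regimen(), horizon = 170,
                              eval_days = end_day)
    expect_lt(eval_table(treated)$C, eval_table(untreated)$C)
  }
})

test_that("drug levels decay to a negligible residual before the next cycle", {
  # cell interactions off: all baseline rates zero, no consumption couplings
  pb <- stats::setNames(rep(0, 59), BASELINE_PARAM_NAMES)
  pb[c("M0", "C0")] <- 2
  p <- folfiri_params(pb, default_params_cached()$treatment)
  tr <- simulate_tme(stats::setNames(rep(0, 17), STATE_NAMES), p,
                     regimen(n_cycles = 1), horizon = 14, dt_out = 0.01)
  for (d in DRUG_STATE_NAMES) {
    peak <- max(tr[[d]])
    expect_gt(peak, 1)  # the infusion actually registered
    expect_lt(tr[[d]][nrow(tr)], 1e-6 * peak)
  }
})

test_that("identical inputs give bitwise-identical trajectories", {
  p <- default_params_cached()
  sc <- dose_scan(regimen(), p, state_vector(), multipliers = 1,
                  target_drug = "fu", horizon = 200, eval_days = c(100, 169))
  direct <- simulate_tme(state_vector(), p, regimen(), horizon = 200,
                         eval_days = c(100, 169))
  expect_identical(scan_trajectories(sc)[["x1"]]$C, direct$C)
})

test_that("a zero leucovorin multiplier reproduces the 5-FU-only arm", {
  p <- default_params_cached()
  sc <- dose_scan(regimen(dose_ir = 0), p, state_vector(),
                  multipliers = c(0, 1), target_drug = "lv",
                  horizon = 200, eval_days = 169)
  arm0 <- scan_trajectories(sc)[["x0"]]
  only_fu <- simulate_tme(state_vector(), p,
                          regimen(dose_lv = 0, dose_ir = 0), horizon = 200,
                          eval_days = 169)
  expect_equal(arm0$C, only_fu$C, tolerance = 1e-12)
})

test_that("cell trajectories are insensitive to leucovorin when 5-FU is absent", {
  p <- default_params_cached()
  lv_only <- simulate_tme(state_vector(), p,
                          regimen(dose_5fu = 0, dose_ir = 0), horizon = 120)
  nothing <- simulate_tme(state_vector(), p, zero_dose_regimen(),
                          horizon = 120)
  common <- intersect(lv_only$time_days, nothing$time_days)
  a <- as.matrix(lv_only[lv_only$time_days %in% common, BASELINE_STATE_NAMES])
  b <- as.matrix(nothing[nothing$time_days %in% common, BASELINE_STATE_NAMES])
  expect_lt(max(abs(a - b)), 1e-8)
})

test_that("combination arms show the leucovorin boost and irinotecan T-reg depletion", {
  p <- default_params_cached()
  sc <- combination_scan(state_vector(), p, regimen(), eval_days = 169,
                         horizon = 200)
  s <- tibble::as_tibble(sc)
  c_at <- function(arm) s$cancer[s$arm == arm]
  expect_lte(c_at("5FU+LV"), c_at("5FU"))
  expect_lt(c_at("5FU+LV+Ir"), c_at("5FU"))
  trajs <- scan_trajectories(sc)
  tr_end <- vapply(trajs, function(tr) state_at(tr, 169, "Tr"), numeric(1))
  expect_lt(tr_end[["5FU+Ir"]], tr_end[["5FU"]])
})

test_that("start-time scans are deterministic and reach equilibrium by late starts", {
  p <- default_params_cached()
  ic <- cluster_initial_conditions(3, "smallest")
  sc1 <- start_time_scan(ic, p, regimen(), start_years = c(1, 7),
                         post_days = 200)
  sc2 <- start_time_scan(ic, p, regimen(), start_years = c(1, 7),
                         post_days = 200)
  expect_identical(tibble::as_tibble(sc1), tibble::as_tibble(sc2))
  trajs <- scan_trajectories(sc1)
  dev <- function(tr, day) {
    max(abs(as.numeric(tr[tr$time_days == day, BASELINE_STATE_NAMES]) - 1))
  }
  # the pre-treatment state is closer to the untreated steady state at 7 y
  expect_lt(dev(trajs$year7, 7 * 365), dev(trajs$year1, 365))
})

test_that("delaying the start shifts the response when starting from equilibrium", {
  p <- default_params_cached()
  sc <- start_time_scan(state_vector(), p, regimen(), start_years = c(1, 3),
                        post_days = 300)
  s <- tibble::as_tibble(sc)
  c1 <- s$cancer[s$start_year == 1 & s$eval_day == 169]
  c3 <- s$cancer[s$start_year == 3 & s$eval_day == 169]
  expect_equal(c1, c3, tolerance = 1e-6)
})

test_that("trajectories stay non-negative and recover after treatment ends", {
  tr <- median_trajectory_cached()
  expect_gt(min(as.matrix(tr[, STATE_NAMES])), -1e-9)
  et <- eval_table(tr)
  # recurrence: cancer regrows monotonically across the evaluation days
  expect_true(all(diff(et$C) > 0))
  # and re-approaches the untreated steady state by year nine
  expect_gt(et$C[et$time_days == 3285], 0.9)
})

test_that("halving the solver tolerances leaves the day-169 cancer unchanged", {
  p <- default_params_cached()
  a <- simulate_tme(state_vector(), p, regimen(), horizon = 170,
                    eval_days = 169)
  b <- simulate_tme(state_vector(), p, regimen(), horizon = 170,
                    eval_days = 169, rtol = 5e-9, atol = 5e-11)
  ca <- eval_table(a)$C
  cb <- eval_table(b)$C
  expect_lt(abs(ca - cb) / ca, 1e-4)
})

test_that("the combined-kill parameter scan reproduces the reported orderings", {
  p <- default_params_cached()
  mult <- c(0.1, 1, 5)
  sc_lv <- parameter_scan(p, "delta_CLV5fu", multipliers = mult)
  s <- tibble::as_tibble(sc_lv)
  # cancer at 169 d declines as the combined 5-FU/LV kill rate grows
  c169 <- s$cancer[s$eval_day == 169]
  expect_true(all(diff(c169[order(unique(s$multiplier))]) < 0))
  # the minimum across evaluation days sits at 169 d for every multiplier
  for (m in mult) {
    sm <- s[s$multiplier == m, ]
    expect_equal(sm$eval_day[which.min(sm$cancer)], 169)
  }
  # the macrophage-shielding parameter moves cancer far less; at 5x the
  # net death bracket dips negative during infusions, which is reported
  expect_warning(
    sc_m <- parameter_scan(p, "delta_5fuM", multipliers = c(0.1, 5),
                           eval_days = 169, horizon = 200),
    "bracket negative")
  sm <- tibble::as_tibble(sc_m)
  rng_m <- abs(log(sm$cancer[sm$multiplier == 5] /
                     sm$cancer[sm$multiplier == 0.1]))
  rng_lv <- abs(log(c169[which(mult == 5)] / c169[which(mult == 0.1)]))
  expect_lt(rng_m, rng_lv / 5)
  expect_error(parameter_scan(p, "not_a_param"), "valid names")
})

test_that("trajectory accessors and tidiers expose the expected shapes", {
  tr <- median_trajectory_cached()
  td <- tidy(tr)
  expect_named(td, c("time_days", "variable", "value"))
  expect_setequal(levels(td$variable), c(STATE_NAMES, "total_cells"))
  g <- glance(tr)
  expect_equal(g$n_cycles, 12)
  expect_equal(g$cancer_min_day, tr$time_days[which.min(tr$C)])
  expect_equal(state_at(tr, 0, "C"), 1)
  expect_error(state_at(tr, 1e6), "horizon")
})
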