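test_that("treated RHS matches a literal transcription of the equations", {
  for (seed in 1:20) {
    p <- random_params(seed)
    x <- random_state17(seed + 100)
    u <- abs(stats::rnorm(3))
    expect_equal(unname(rhs_treatment(x, p, u)),
                 unname(rhs_reference(x, p, u)),
                 tolerance = 1e-14)
  }
})

test_that("all-zero state produces only the constant sources", {
  p <- random_params(1)
  d <- rhs_treatment(stats::setNames(rep(0, 17), STATE_NAMES), p)
  expect_equal(d[["TN"]], p$baseline[["A_TN"]])
  expect_equal(d[["DN"]], p$baseline[["A_DN"]])
  expect_equal(unname(d[setdiff(STATE_NAMES, c("TN", "DN"))]),
               rep(0, 15))
})

test_that("logistic growth term evaluates as printed", {
  pb <- stats::setNames(rep(0, 59), BASELINE_PARAM_NAMES)
  pb["lambda_C"] <- 0.1
  pb["C0"] <- 2
  pb["M0"] <- 1
  d <- rhs_baseline(state_vector(C = 1) * c(rep(0, 7), 1, rep(0, 9)), pb)
  expect_equal(d[["C"]], 0.1 * 1 * (1 - 1 / 2))
  expect_equal(sum(abs(d)), d[["C"]])
})

test_that("drug-free treated RHS reduces exactly to the baseline RHS", {
  for (seed in 1:10) {
    p <- random_params(seed)
    x <- random_state17(seed)
    x[c("FU", "LV", "Ir")] <- 0
    expect_identical(unname(rhs_treatment(x, p)[1:14]),
                     unname(rhs_baseline(x[1:14], p)))
  }
})

test_that("leucovorin without 5-FU leaves all cell and cytokine equations untouched", {
  p <- random_params(3)
  x <- random_state17(7)
  x["FU"] <- 0
  x["Ir"] <- 0
  x["LV"] <- 1.3
  d <- rhs_treatment(x, p)
  x0 <- x; x0["LV"] <- 0
  d0 <- rhs_treatment(x0, p)
  expect_identical(d[1:14], d0[1:14])
  expect_equal(d[["LV"]], -p$treatment[["delta_LV"]] * 1.3)
})

test_that("hand-evaluated irinotecan kill and necrosis conversion", {
  pb <- stats::setNames(rep(0, 59), BASELINE_PARAM_NAMES)
  pb["alpha_NC"] <- 0.5
  pb["C0"] <- 2
  pb["M0"] <- 1
  pt <- stats::setNames(rep(0, 19), TREATMENT_PARAM_NAMES)
  pt["delta_CIr"] <- 0.4
  pt[c("A_5fu_daily", "A_LV_daily", "A_Ir_daily")] <- 1
  p <- folfiri_params(pb, pt)
  x <- stats::setNames(rep(0, 17), STATE_NAMES)
  x["C"] <- 1
  x["Ir"] <- 1
  d <- rhs_treatment(x, p)
  expect_equal(d[["C"]], -0.4)
  expect_equal(d[["N"]], 0.2)
})

test_that("necrosis production equals alpha_NC times the cancer death flux", {
  for (seed in 1:10) {
    p <- random_params(seed + 50)
    x <- random_state17(seed + 60)
    d <- rhs_treatment(x, p)
    flux <- folfirisim:::death_rate_C_treat(unname(x), p$baseline,
                                            p$treatment) * x[["C"]]
    expect_equal(d[["N"]],
                 p$baseline[["alpha_NC"]] * flux - p$baseline[["delta_N"]] * x[["N"]])
  }
})

test_that("total_cells sums the nine cell populations only", {
  expect_equal(total_cells(state_vector()), 9)
  expect_equal(total_cells(stats::setNames(rep(0, 17), STATE_NAMES)), 0)
  # cluster 3 smallest-tumor row: sum of its nine printed cell entries
  cl3 <- cluster_initial_conditions(3, "smallest")
  expect_equal(total_cells(cl3),
               1.38e-1 + 2.20e-1 + 8.59e-2 + 6.26e-2 + 1.53e-1 + 2.61e-1 +
                 1.56e-1 + 1.83e-1 + 0)
})

test_that("state and parameter validation reject negatives by name", {
  p <- random_params(2)
  x <- state_vector()
  x["Tr"] <- -0.1
  expect_error(rhs_treatment(x, p), "Tr")
  pb <- p$baseline
  pb["delta_M"] <- -1
  expect_error(folfiri_params(pb), "delta_M")
  expect_error(folfiri_params(p$baseline[-3]), "missing")
  expect_error(state_vector(XX = 1), "unknown state")
})

test_that("Jacobian of a pure-decay configuration is diagonal", {
  pb <- stats::setNames(rep(0, 59), BASELINE_PARAM_NAMES)
  pb["delta_H"] <- 0.7
  pb["C0"] <- 2
  pb["M0"] <- 1
  pt <- stats::setNames(rep(0, 19), TREATMENT_PARAM_NAMES)
  pt[c("A_5fu_daily", "A_LV_daily", "A_Ir_daily")] <- 1
  J <- model_jacobian(random_state17(5), folfiri_params(pb, pt))
  expect_equal(J["H", "H"], -0.7, tolerance = 1e-9)
  J["H", "H"] <- 0
  expect_true(max(abs(J)) < 1e-9)
})

test_that("Jacobian matches the analytic logistic derivative", {
  pb <- stats::setNames(rep(0, 59), BASELINE_PARAM_NAMES)
  pb["lambda_C"] <- 0.3
  pb["C0"] <- 2.5
  pb["M0"] <- 1
  pt <- stats::setNames(rep(0, 19), TREATMENT_PARAM_NAMES)
  pt[c("A_5fu_daily", "A_LV_daily", "A_Ir_daily")] <- 1
  x <- stats::setNames(rep(0, 17), STATE_NAMES)
  x["C"] <- 0.8
  J <- model_jacobian(x, folfiri_params(pb, pt))
  expect_equal(J["C", "C"], 0.3 * (1 - 2 * 0.8 / 2.5), tolerance = 1e-6)
})

test_that("Jacobian agrees with a forward-difference oracle on random states", {
  for (seed in 1:20) {
    p <- random_params(seed + 200)
    x <- random_state17(seed + 300)
    J <- model_jacobian(x, p)
    # independent oracle: one-sided differences at a tenth of the step
    J_fd <- matrix(0, 17, 17)
    f0 <- unname(rhs_treatment(x, p))
    for (j in 1:17) {
      h <- 1e-7 * max(1, abs(x[j]))
      xp <- unname(x); xp[j] <- xp[j] + h
      J_fd[, j] <- (folfirisim:::rhs_treatment_core(xp, p$baseline,
                                                    p$treatment, c(0, 0, 0)) -
                      f0) / h
    }
    scale <- max(abs(J_fd))
    expect_lt(max(abs(J - J_fd)) / scale, 1e-4)
  }
})
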