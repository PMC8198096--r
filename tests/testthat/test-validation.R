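test_that("the ROC sweep recovers perfect separation and its endpoints", {
  preds <- c(0.1, 0.2, 0.3, 1.1, 1.5)
  labels <- c("tumor_free", "tumor_free", "tumor_free",
              "with_tumor", "with_tumor")
  roc <- roc_cancer(preds, labels)
  expect_equal(roc$auc, 1)
  sw <- tidy(roc)
  # at the lowest threshold nothing is called tumor-free ...
  expect_equal(sw$tpr[which.min(sw$threshold)], 0)
  expect_equal(sw$fpr[which.min(sw$threshold)], 0)
  # ... and beyond the maximum everything is
  expect_equal(sw$tpr[which.max(sw$threshold)], 1)
  expect_equal(sw$fpr[which.max(sw$threshold)], 1)
  expect_error(roc_cancer(preds, rep("tumor_free", 5)), "both classes")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(42)
  preds <- stats::rlnorm(80)
  labels <- ifelse(stats::runif(80) < stats::plogis(1 - preds),
                   "tumor_free", "with_tumor")
  a1 <- roc_cancer(preds, labels, n_thresholds = 4001)$auc
  a2 <- roc_cancer(log(preds), labels, n_thresholds = 4001)$auc
  a3 <- roc_cancer(preds^3, labels, n_thresholds = 4001)$auc
  expect_equal(a1, a2, tolerance = 1e-2)
  expect_equal(a1, a3, tolerance = 1e-2)
})

test_that("the threshold-sweep AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(7)
  preds <- stats::rnorm(200)
  labels <- ifelse(stats::runif(200) < stats::plogis(-preds),
                   "tumor_free", "with_tumor")
  ours <- roc_cancer(preds, labels, n_thresholds = 5001)$auc
  # pROC direction "<": lower prediction means tumor-free (our positive class)
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = preds, levels = c("with_tumor", "tumor_free"),
    direction = ">", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 5e-3)
})

test_that("AUC degrades monotonically with label noise", {
  traj <- median_trajectory_cached()
  co <- generate_cohort(500, seed = 31)
  aucs <- vapply(c(0, 0.1, 0.25, 0.5), function(noise) {
    lab <- assign_followup(co, traj, label_noise = noise, seed = 33)
    roc_cancer(lab$predicted_cancer, lab$status)$auc
  }, numeric(1))
  expect_equal(aucs[1], 1)
  expect_true(all(diff(aucs) < 0.02))  # monotone within simulation error
  expect_gt(aucs[2], aucs[4])
})

test_that("status matching applies the size-dependent rule", {
  # small tumor, cancer below initial, observed tumor-free: a match
  expect_true(status_match(0.9 * 0.2, 0.2, "tumor_free"))
  # large tumor needs better than half the initial value
  expect_false(status_match(0.7, 1.0, "tumor_free"))
  expect_true(status_match(0.4, 1.0, "tumor_free"))
  # with-tumor observation matches when cancer exceeds the cutoff
  expect_true(status_match(1.2 * 0.2, 0.2, "with_tumor"))
  expect_error(status_match(0.5, 1, NA), "missing")
})

test_that("predictions at follow-up reflect the patient regimen and day", {
  p <- default_params_cached()
  co <- generate_cohort(3, seed = 41)
  co$followup_day <- c(0.0, 169, 300)
  out <- predict_at_followup(co, p, ic = "steady")
  # day zero returns the initial cancer value
  expect_equal(out$predicted_cancer[1], 1)
  # end-of-treatment prediction sits far below the initial value
  expect_lt(out$predicted_cancer[2], 0.1)
  # a zero-dose regimen from equilibrium predicts 1 at any day
  co0 <- co
  co0[, c("dose_5fu", "dose_lv", "dose_ir")] <- 0
  out0 <- predict_at_followup(co0, p, ic = "steady")
  expect_equal(out0$predicted_cancer, rep(1, 3), tolerance = 1e-6)
  # excluded records are skipped with a message
  co$excluded <- c(TRUE, FALSE, FALSE)
  expect_message(out2 <- predict_at_followup(co, p, ic = "steady"),
                 "excluded")
  expect_true(is.na(out2$predicted_cancer[1]))
})

test_that("irinotecan drives the pre/post regulatory-T-cell decline", {
  p <- default_params_cached()
  # patients begin treatment near their (cluster-shaded) steady state: the
  # regimen starts at year 7, by which the untreated dynamics have almost
  # re-equilibrated from the smallest-tumor initial conditions
  start <- 7 * 365
  pre_post <- function(reg) {
    end <- folfirisim:::treatment_end_day(reg)
    purrr::map(1:5, function(cl) {
      tr <- simulate_tme(cluster_initial_conditions(cl, "smallest"), p, reg,
                         horizon = end + 10, eval_days = numeric(0))
      tibble::tibble(tr_pre = state_at(tr, start, "Tr"),
                     tr_post = state_at(tr, end, "Tr"))
    }) |> purrr::list_rbind()
  }
  with_ir <- pre_post(regimen(start_day = start))
  no_ir <- pre_post(regimen(dose_ir = 0, start_day = start))
  res <- treg_pre_post(with_ir)
  expect_setequal(res$group, c("high_treg", "low_treg"))
  # regulatory T-cells decline during treatment in both groups ...
  expect_true(all(res$mean_difference < 0))
  # ... and the decline is attributable to irinotecan: without it the
  # indirect effects move T-regs far less
  res0 <- treg_pre_post(no_ir)
  expect_lt(sum(res$mean_difference * res$n) / sum(res$n),
            sum(res0$mean_difference * res0$n) / sum(res0$n))
  expect_gt(mean(abs(res$mean_difference)), mean(abs(res0$mean_difference)))
  # identical pre/post values: zero difference, p = 1
  same <- tibble::tibble(tr_pre = c(1, 2, 3, 4), tr_post = c(1, 2, 3, 4))
  rs <- treg_pre_post(same)
  expect_equal(rs$mean_difference, c(0, 0))
  expect_equal(rs$p_value, c(1, 1))
  # an empty group is reported, not an error
  one_side <- tibble::tibble(tr_pre = c(1, 1), tr_post = c(0.9, 0.8))
  r1 <- treg_pre_post(one_side, grouping_threshold = 5)
  expect_equal(r1$n[r1$group == "high_treg"], 0L)
})
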