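#' Predicted cancer density at each patient's follow-up day
#'
#' Simulates each record under its own recorded regimen from the chosen
#' initial conditions and reads the cancer density at the follow-up day
#' (dense interpolation on the daily output grid). Records flagged
#' `excluded` are skipped (prediction `NA`).
#'
#' @param cohort Cohort tibble with regimen and `followup_day` columns.
#' @param params A [folfiri_params()].
#' @param ic `"steady"` (all-ones) or `"smallest"` cluster initial
#'   conditions.
#' @param horizon Simulation horizon; defaults to just past the latest
#'   follow-up.
#' @param ... Passed to [simulate_tme()].
#' @return The cohort with a `predicted_cancer` column (replaced if already
#'   present).
#' @export
predict_at_followup <- function(cohort, params, ic = c("steady", "smallest"),
                                horizon = NULL, ...) {
  ic <- match.arg(ic)
  if (is.null(horizon)) horizon <- max(cohort$followup_day) + 1
  excl <- if ("excluded" %in% names(cohort)) cohort$excluded else
    rep(FALSE, nrow(cohort))
  preds <- purrr::map_dbl(seq_len(nrow(cohort)), function(i) {
    if (excl[i]) {
      message("record ", cohort$patient_id[i], " excluded; skipped")
      return(NA_real_)
    }
    rec <- cohort[i, ]
    traj <- simulate_tme(cluster_initial_conditions(rec$cluster, ic), params,
                         record_regimen(rec), horizon = horizon,
                         eval_days = numeric(0), ...)
    state_at(traj, rec$followup_day, "C")
  })
  cohort$predicted_cancer <- preds
  cohort
}

#' ROC curve from a uniform threshold sweep
#'
#' Thresholds form a uniform grid spanning the minimum to the maximum
#' predicted value (inclusive), plus one threshold above the maximum so
#' the sweep reaches the all-positive corner. A record is classified
#' `tumor_free` (the positive class) when its prediction is strictly below
#' the threshold; AUC is the trapezoid over the sorted (FPR, TPR) sequence.
#'
#' @param predictions Numeric predictions (cancer density at follow-up).
#' @param labels Character or factor with values `"tumor_free"` /
#'   `"with_tumor"` (or logical, `TRUE` = tumor-free).
#' @param n_thresholds Grid size (default 101).
#' @return Object of class `folfiri_roc`: list with the sweep tibble
#'   (`threshold`, `tpr`, `fpr`) and `auc`.
#' @export
roc_cancer <- function(predictions, labels, n_thresholds = 101) {
  stopifnot(length(predictions) == length(labels), n_thresholds >= 2)
  keep <- !is.na(predictions) & !is.na(labels)
  predictions <- predictions[keep]
  labels <- labels[keep]
  pos <- if (is.logical(labels)) labels else labels == "tumor_free"
  if (all(pos) || !any(pos)) {
    stop("both classes must be present to form a ROC curve")
  }
  lo <- min(predictions)
  hi <- max(predictions)
  thresholds <- c(seq(lo, hi, length.out = n_thresholds),
                  hi + max(hi - lo, abs(hi), 1) * 1e-6)
  sweep <- purrr::map(thresholds, function(th) {
    called_free <- predictions < th
    tibble::tibble(
      threshold = th,
      tpr = sum(called_free & pos) / sum(pos),
      fpr = sum(called_free & !pos) / sum(!pos)
    )
  }) |> purrr::list_rbind()
  ord <- order(sweep$fpr, sweep$tpr)
  fpr <- c(0, sweep$fpr[ord], 1)
  tpr <- c(0, sweep$tpr[ord], 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(sweep = sweep, auc = auc,
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "folfiri_roc")
}

#' @export
print.folfiri_roc <- function(x, ...) {
  cat("<folfiri_roc> AUC = ", format(x$auc, digits = 4), " (",
      x$n_pos, " tumor-free vs ", x$n_neg, " with-tumor)\n", sep = "")
  invisible(x)
}

#' Tumor-status matching rule
#'
#' A patient is expected tumor-free when the simulated cancer at follow-up
#' is below the initial cancer value (small/medium tumors) or below half of
#' it (large tumors: initial dimensionless cancer `>= size_cutoff`). The
#' match is whether that expectation agrees with the observed status.
#'
#' @param c_followup Simulated cancer density at the follow-up day.
#' @param c_initial Initial cancer density.
#' @param status Observed `"tumor_free"` / `"with_tumor"`.
#' @param size_cutoff Large-tumor cutoff on the initial dimensionless
#'   cancer density (default 0.5; configurable, the study does not define
#'   the class boundary).
#' @return Logical: does the model expectation match the observation?
#' @export
status_match <- function(c_followup, c_initial, status,
                         size_cutoff = 0.5) {
  if (anyNA(status)) stop("missing tumor status")
  stopifnot(all(status %in% c("tumor_free", "with_tumor")))
  cutoff <- ifelse(c_initial >= size_cutoff, c_initial / 2, c_initial)
  expect_free <- c_followup < cutoff
  expect_free == (status == "tumor_free")
}

#' Regulatory T-cell level before versus after treatment
#'
#' Splits patients into high and low regulatory-T groups by their
#' pre-treatment `Tr` value (median split by default) and compares paired
#' pre/post values per group with a paired location test.
#'
#' @param data Tibble with columns `tr_pre` and `tr_post` (dimensionless
#'   regulatory-T densities at treatment start and end).
#' @param grouping_threshold Pre-treatment `Tr` value separating high from
#'   low; default is the cohort median.
#' @return Tibble with one row per group: `group`, `n`, `mean_pre`,
#'   `mean_post`, `mean_difference` (post minus pre), `p_value` (paired
#'   t-test; `p = 1` when all differences vanish, `NA` for n < 2). Empty
#'   groups are reported with `n = 0`, not as an error.
#' @export
treg_pre_post <- function(data, grouping_threshold = NULL) {
  stopifnot(all(c("tr_pre", "tr_post") %in% names(data)))
  if (is.null(grouping_threshold)) {
    grouping_threshold <- stats::median(data$tr_pre)
  }
  grp <- ifelse(data$tr_pre > grouping_threshold, "high_treg", "low_treg")
  purrr::map(c("high_treg", "low_treg"), function(g) {
    d <- data[grp == g, , drop = FALSE]
    if (nrow(d) == 0) {
      return(tibble::tibble(group = g, n = 0L, mean_pre = NA_real_,
                            mean_post = NA_real_, mean_difference = NA_real_,
                            p_value = NA_real_))
    }
    diffs <- d$tr_post - d$tr_pre
    p <- if (nrow(d) < 2) {
      NA_real_
    } else if (all(diffs == 0)) {
      1
    } else {
      stats::t.test(d$tr_post, d$tr_pre, paired = TRUE)$p.value
    }
    tibble::tibble(group = g, n = nrow(d), mean_pre = mean(d$tr_pre),
                   mean_post = mean(d$tr_post),
                   mean_difference = mean(diffs), p_value = p)
  }) |> purrr::list_rbind()
}
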