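#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trajectory into long format
#'
#' @param x A `folfiri_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `time_days`, `variable`, `value` (the 17
#'   state variables plus `total_cells`).
#' @method tidy folfiri_trajectory
#' @export
tidy.folfiri_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time_days",
                      names_to = "variable", values_to = "value") |>
    dplyr::mutate(variable = factor(.data$variable,
                                    levels = c(STATE_NAMES, "total_cells")))
}

#' @rdname tidy.folfiri_trajectory
#' @method glance folfiri_trajectory
#' @export
glance.folfiri_trajectory <- function(x, ...) {
  reg <- attr(x, "regimen")
  tibble::tibble(
    horizon_days = max(x$time_days),
    n_times = nrow(x),
    cancer_final = x$C[nrow(x)],
    cancer_min = min(x$C),
    cancer_min_day = x$time_days[which.min(x$C)],
    dose_5fu = reg$dose_5fu, dose_lv = reg$dose_lv, dose_ir = reg$dose_ir,
    n_cycles = reg$n_cycles
  )
}

#' Tidy a parameter set
#'
#' @param x A `folfiri_params`.
#' @param ... Unused.
#' @return Tibble with columns `parameter`, `value`, `block`.
#' @method tidy folfiri_params
#' @export
tidy.folfiri_params <- function(x, ...) {
  out <- tibble::tibble(parameter = names(x$baseline),
                        value = unname(x$baseline), block = "baseline")
  if (!is.null(x$treatment)) {
    out <- dplyr::bind_rows(out,
      tibble::tibble(parameter = names(x$treatment),
                     value = unname(x$treatment), block = "treatment"))
  }
  out
}

#' Tidy a sensitivity result
#'
#' @param x A `folfiri_sensitivity` or `folfiri_sensitivity_set`.
#' @param relative Also include the relative curves?
#' @param threshold Masking threshold for relative curves.
#' @param ... Unused.
#' @return Tibble with columns `parameter`, `time_days`, `variable`, `S`
#'   and (optionally) `S_rel`.
#' @method tidy folfiri_sensitivity
#' @export
tidy.folfiri_sensitivity <- function(x, relative = TRUE, threshold = 1e-8,
                                     ...) {
  out <- tibble::as_tibble(as.data.frame(x$S)) |>
    dplyr::mutate(time_days = x$times, parameter = x$parameter) |>
    tidyr::pivot_longer(-c("time_days", "parameter"),
                        names_to = "variable", values_to = "S")
  if (relative) {
    rel <- relative_sensitivity(x, threshold)
    rel_long <- tibble::as_tibble(as.data.frame(rel)) |>
      dplyr::mutate(time_days = x$times) |>
      tidyr::pivot_longer(-"time_days", names_to = "variable",
                          values_to = "S_rel")
    out <- dplyr::left_join(out, rel_long, by = c("time_days", "variable"))
  }
  out
}

#' @rdname tidy.folfiri_sensitivity
#' @method tidy folfiri_sensitivity_set
#' @export
tidy.folfiri_sensitivity_set <- function(x, ...) {
  purrr::map(unclass(x), tidy, ...) |> purrr::list_rbind()
}

#' Tidy a ROC sweep
#'
#' @param x A `folfiri_roc`.
#' @param ... Unused.
#' @return The sweep tibble (`threshold`, `tpr`, `fpr`).
#' @method tidy folfiri_roc
#' @export
tidy.folfiri_roc <- function(x, ...) x$sweep

#' @rdname tidy.folfiri_roc
#' @method glance folfiri_roc
#' @export
glance.folfiri_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_tumor_free = x$n_pos, n_with_tumor = x$n_neg)
}
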