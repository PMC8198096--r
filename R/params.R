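#' Parameter name registries
#'
#' The baseline (no-treatment) system carries exactly 59 named parameters:
#' two sources (`A_TN`, `A_DN`), two capacities (`M0`, `C0`), the necrosis
#' fraction `alpha_NC`, 31 activation/production rates (`lambda_*`) and 23
#' removal/inhibition rates (`delta_*`). The treatment extension adds exactly
#' 19 named parameters: seven drug kill/interaction rates, two 5-FU-assisted
#' T-cell activation rates, four drug-consumption efficiency constants, three
#' natural decay rates, and the three daily-median dose scales (mg/day) that,
#' together with a [regimen()], define the injection functions.
#'
#' @format Character vectors of parameter names.
#' @name param-names
NULL

#' @rdname param-names
#' @export
BASELINE_PARAM_NAMES <- c(
  "A_TN", "A_DN", "M0", "C0", "alpha_NC",
  # activation / production rates
  "lambda_ThD", "lambda_ThM", "lambda_Thmu1",
  "lambda_TCTh", "lambda_TCD",
  "lambda_TrTh", "lambda_Trmu2", "lambda_TrGb",
  "lambda_DH", "lambda_DC",
  "lambda_Mmu2", "lambda_MIg", "lambda_MTh",
  "lambda_C", "lambda_Cmu1",
  "lambda_HN", "lambda_HM", "lambda_HTh", "lambda_HTC", "lambda_HTr",
  "lambda_mu1Th", "lambda_mu1M", "lambda_mu1D",
  "lambda_mu2M", "lambda_mu2D", "lambda_mu2Tr",
  "lambda_IgTh", "lambda_IgTC", "lambda_IgM",
  "lambda_GbM", "lambda_GbTr",
  # removal / inhibition rates
  "delta_TN",
  "delta_Thmu2", "delta_ThTr", "delta_Th",
  "delta_TCmu2", "delta_TCTr", "delta_TC",
  "delta_Trmu1", "delta_Tr",
  "delta_DH", "delta_D", "delta_DC",
  "delta_M",
  "delta_CGb", "delta_CIg", "delta_CTC", "delta_C",
  "delta_N", "delta_H", "delta_mu1", "delta_mu2", "delta_Ig", "delta_Gb"
)

#' @rdname param-names
#' @export
TREATMENT_PARAM_NAMES <- c(
  "delta_C5fu", "delta_C5fuIg", "delta_5fuM", "delta_CLV5fu",
  "delta_CIr", "delta_TrIr", "delta_5fuD",
  "lambda_ThD5fu", "lambda_TCD5fu",
  "alpha_5fu", "alpha_LV", "alpha_IrC", "alpha_IrTr",
  "delta_5fu", "delta_LV", "delta_Ir",
  "A_5fu_daily", "A_LV_daily", "A_Ir_daily"
)

new_param_block <- function(values, registry, label) {
  if (is.list(values)) values <- unlist(values)
  if (is.null(names(values))) {
    stop(label, " parameters must be a named vector")
  }
  missing <- setdiff(registry, names(values))
  extra <- setdiff(names(values), registry)
  if (length(missing)) {
    stop(label, " parameters missing: ", paste(missing, collapse = ", "))
  }
  if (length(extra)) {
    stop("unknown ", label, " parameter(s): ", paste(extra, collapse = ", "))
  }
  v <- values[registry]
  if (anyNA(v) || any(!is.finite(v))) {
    stop("non-finite ", label, " parameter(s): ",
         paste(registry[!is.finite(v)], collapse = ", "))
  }
  if (any(v < 0)) {
    stop("negative ", label, " parameter(s): ",
         paste(registry[v < 0], collapse = ", "))
  }
  v
}

#' Bundle baseline and treatment parameters
#'
#' @param baseline Named numeric vector with exactly the 59 baseline
#'   parameters ([BASELINE_PARAM_NAMES]).
#' @param treatment Named numeric vector with exactly the 19 treatment
#'   parameters ([TREATMENT_PARAM_NAMES]), or `NULL` for a baseline-only set
#'   (drug states then stay at zero).
#' @return An object of class `folfiri_params`.
#' @seealso [derive_params()] for the steady-state derivation that produces
#'   the default set.
#' @export
folfiri_params <- function(baseline, treatment = NULL) {
  baseline <- new_param_block(baseline, BASELINE_PARAM_NAMES, "baseline")
  if (!is.null(treatment)) {
    treatment <- new_param_block(treatment, TREATMENT_PARAM_NAMES, "treatment")
  }
  structure(list(baseline = baseline, treatment = treatment),
            class = "folfiri_params")
}

#' @export
print.folfiri_params <- function(x, ...) {
  cat("<folfiri_params>\n")
  cat("  baseline : ", length(x$baseline), " parameters\n", sep = "")
  if (is.null(x$treatment)) {
    cat("  treatment: none (untreated system)\n")
  } else {
    cat("  treatment: ", length(x$treatment), " parameters\n", sep = "")
  }
  cat("  equilibrium residual (all-ones): ",
      format(verify_equilibrium(x), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Write / read a parameter set as a flat key-value text file
#'
#' One `name value` pair per line, full double precision; the treatment block
#' (if present) is appended after the baseline block. The format round-trips
#' exactly.
#'
#' @param params A `folfiri_params` object.
#' @param path File path.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   a `folfiri_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "folfiri_params"))
  v <- c(params$baseline, params$treatment)
  lines <- paste(names(v), formatC(v, format = "g", digits = 17))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("name", "value"),
                           colClasses = c("character", "numeric"))
  v <- stats::setNames(tab$value, tab$name)
  treatment <- NULL
  if (any(names(v) %in% TREATMENT_PARAM_NAMES)) {
    treatment <- v[TREATMENT_PARAM_NAMES]
  }
  folfiri_params(v[BASELINE_PARAM_NAMES], treatment)
}

param_fingerprint <- function(params, regimen = NULL) {
  rlang::hash(list(
    baseline = round(unname(params$baseline), 15),
    treatment = if (!is.null(params$treatment)) round(unname(params$treatment), 15),
    regimen = if (!is.null(regimen)) unclass(regimen)
  ))
}
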