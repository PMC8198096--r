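#' State-variable order of the tumor-microenvironment model
#'
#' The model tracks 14 dimensionless tumor-microenvironment variables (nine
#' cell populations and five cytokine species, each scaled by its untreated
#' steady-state value so that the untreated equilibrium is the all-ones state)
#' plus three dimensionless drug concentrations appended in the fixed order
#' `FU`, `LV`, `Ir`. This ordering is frozen: every state vector, trajectory
#' column block and Jacobian row/column in the package uses it.
#'
#' @format Character vectors of variable names.
#' @name state-order
NULL

#' @rdname state-order
#' @export
BASELINE_STATE_NAMES <- c(
  "TN",  # naive T-cells
  "Th",  # helper T-cells
  "TC",  # cytotoxic cells (CD8+ T and NK)
  "Tr",  # regulatory T-cells
  "DN",  # naive dendritic cells
  "D",   # activated dendritic cells
  "M",   # macrophages
  "C",   # cancer cells
  "N",   # necrotic cells
  "H",   # HMGB1
  "mu1", # carcinogenic cytokines (IL-6/17/21/22)
  "mu2", # immunosuppressive agents (IL-10, CCL20)
  "Ig",  # IFN-gamma
  "Gb"   # TGF-beta
)

#' @rdname state-order
#' @export
DRUG_STATE_NAMES <- c("FU", "LV", "Ir")

#' @rdname state-order
#' @export
STATE_NAMES <- c(BASELINE_STATE_NAMES, DRUG_STATE_NAMES)

CELL_STATE_NAMES <- c("TN", "Th", "TC", "Tr", "DN", "D", "M", "C", "N")

#' Construct a model state vector
#'
#' Builds the 17-component dimensionless state (14 tumor-microenvironment
#' variables followed by the three drug concentrations `FU`, `LV`, `Ir`).
#' Components not supplied default to the untreated steady state (1 for the
#' microenvironment variables) and to 0 for the drugs.
#'
#' @param ... Named components, e.g. `C = 0.18`. Unknown names are an error.
#' @param drugs Numeric length-3 default for `FU`, `LV`, `Ir` (default all 0).
#' @return A named numeric vector of length 17 in canonical order.
#' @examples
#' state_vector()                  # untreated equilibrium, no drug
#' state_vector(C = 0.05, N = 0)   # small tumor
#' @export
state_vector <- function(..., drugs = c(FU = 0, LV = 0, Ir = 0)) {
  x <- stats::setNames(c(rep(1, 14), unname(drugs)), STATE_NAMES)
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), STATE_NAMES)
    if (length(bad) || is.null(names(dots))) {
      stop("unknown state component(s): ", paste(bad, collapse = ", "))
    }
    x[names(dots)] <- dots
  }
  validate_state(x)
  x
}

validate_state <- function(x, n = 17L) {
  if (length(x) != n) {
    stop("state must have ", n, " components, got ", length(x))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("state contains non-finite values: ",
         paste(STATE_NAMES[seq_len(n)][!is.finite(x)], collapse = ", "))
  }
  neg <- x < 0
  if (any(neg)) {
    stop("negative state component(s): ",
         paste(STATE_NAMES[seq_len(n)][neg], collapse = ", "))
  }
  invisible(x)
}

#' Total cell density of a state
#'
#' Sum of all immune, cancer and necrotic cell populations
#' (`TN + Th + TC + Tr + DN + D + M + C + N`); cytokines and drugs are
#' excluded. This is the "Total cells" summary reported alongside the
#' individual trajectories.
#'
#' @param state Named numeric state vector (14 or 17 components) or a
#'   trajectory tibble with the state columns, in which case a numeric vector
#'   (one value per row) is returned.
#' @return Dimensionless total cell density.
#' @export
total_cells <- function(state) {
  if (is.data.frame(state)) {
    return(rowSums(as.matrix(state[, CELL_STATE_NAMES, drop = FALSE])))
  }
  if (is.null(names(state))) {
    names(state) <- STATE_NAMES[seq_along(state)]
  }
  sum(state[CELL_STATE_NAMES])
}
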