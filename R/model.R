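# Fast positional RHS cores. Parameter vectors are guaranteed to be in the
# canonical registry order by folfiri_params(); the index map is spelled out
# next to each access. An independent name-based re-implementation of every
# equation lives in the test suite and is compared against these cores on
# random states and parameters.

# baseline per-capita cancer death rate (shared between the C and N equations)
death_rate_C_base <- function(x, pb) {
  # 50 delta_CGb, 51 delta_CIg, 52 delta_CTC, 53 delta_C
  unname(pb[50L] * x[14L] + pb[51L] * x[13L] + pb[52L] * x[3L] + pb[53L])
}

rhs_baseline_core <- function(x, pb) {
  pb <- unname(pb)
  TN <- x[1L]; Th <- x[2L]; TC <- x[3L]; Tr <- x[4L]
  DN <- x[5L]; D <- x[6L]; M <- x[7L]; C <- x[8L]; N <- x[9L]
  H <- x[10L]; mu1 <- x[11L]; mu2 <- x[12L]; Ig <- x[13L]; Gb <- x[14L]

  act_Th <- pb[6L] * D + pb[7L] * M + pb[8L] * mu1       # lambda_ThD/ThM/Thmu1
  act_TC <- pb[9L] * Th + pb[10L] * D                    # lambda_TCTh/TCD
  act_Tr <- pb[11L] * Th + pb[12L] * mu2 + pb[13L] * Gb  # lambda_TrTh/Trmu2/TrGb
  act_D  <- pb[14L] * H + pb[15L] * C                    # lambda_DH/DC

  death_C <- death_rate_C_base(x, pb)

  dTN <- pb[1L] - (act_Th + act_TC + act_Tr) * TN - pb[37L] * TN
  dTh <- act_Th * TN - (pb[38L] * mu2 + pb[39L] * Tr + pb[40L]) * Th
  dTC <- act_TC * TN - (pb[41L] * mu2 + pb[42L] * Tr + pb[43L]) * TC
  dTr <- act_Tr * TN - (pb[44L] * mu1 + pb[45L]) * Tr
  dDN <- pb[2L] - act_D * DN - (pb[46L] * H + pb[47L]) * DN
  dD  <- act_D * DN - (pb[46L] * H + pb[48L] * C + pb[47L]) * D
  dM  <- (pb[16L] * mu2 + pb[17L] * Ig + pb[18L] * Th) * (pb[3L] - M) - pb[49L] * M
  dC  <- (pb[19L] + pb[20L] * mu1) * C * (1 - C / pb[4L]) - death_C * C
  dN  <- pb[5L] * death_C * C - pb[54L] * N
  dH  <- pb[21L] * N + pb[22L] * M + pb[23L] * Th + pb[24L] * TC + pb[25L] * Tr -
    pb[55L] * H
  dmu1 <- pb[26L] * Th + pb[27L] * M + pb[28L] * D - pb[56L] * mu1
  dmu2 <- pb[29L] * M + pb[30L] * D + pb[31L] * Tr - pb[57L] * mu2
  dIg  <- pb[32L] * Th + pb[33L] * TC + pb[34L] * M - pb[58L] * Ig
  dGb  <- pb[35L] * M + pb[36L] * Tr - pb[59L] * Gb

  c(dTN, dTh, dTC, dTr, dDN, dD, dM, dC, dN, dH, dmu1, dmu2, dIg, dGb)
}

# per-capita cancer death rate with the drug terms of the treated system;
# the minus sign on delta_5fuM (macrophages shielding cancer from 5-FU) is
# kept exactly as the model defines it -- no clamping.
death_rate_C_treat <- function(x, pb, pt) {
  pb <- unname(pb)
  pt <- unname(pt)
  FU <- x[15L]; LV <- x[16L]; Ir <- x[17L]
  death_rate_C_base(x, pb) +
    pt[1L] * FU +                 # delta_C5fu
    pt[2L] * FU * x[13L] -        # delta_C5fuIg * FU * Ig
    pt[3L] * FU * x[7L] +         # delta_5fuM  * FU * M (protective, minus)
    pt[4L] * FU * LV +            # delta_CLV5fu
    pt[5L] * Ir                   # delta_CIr
}

rhs_treatment_core <- function(x, pb, pt, u) {
  pb <- unname(pb)
  pt <- unname(pt)
  u <- unname(u)
  TN <- x[1L]; Th <- x[2L]; TC <- x[3L]; Tr <- x[4L]
  DN <- x[5L]; D <- x[6L]; M <- x[7L]; C <- x[8L]; N <- x[9L]
  H <- x[10L]; mu1 <- x[11L]; mu2 <- x[12L]; Ig <- x[13L]; Gb <- x[14L]
  FU <- x[15L]; LV <- x[16L]; Ir <- x[17L]

  act_Th <- pb[6L] * D + pt[8L] * FU * D + pb[7L] * M + pb[8L] * mu1
  act_TC <- pb[9L] * Th + pb[10L] * D + pt[9L] * FU * D
  act_Tr <- pb[11L] * Th + pb[12L] * mu2 + pb[13L] * Gb
  act_D  <- pb[14L] * H + pb[15L] * C

  death_C <- death_rate_C_treat(x, pb, pt)

  dTN <- pb[1L] - (act_Th + act_TC + act_Tr) * TN - pb[37L] * TN
  dTh <- act_Th * TN - (pb[38L] * mu2 + pb[39L] * Tr + pb[40L]) * Th
  dTC <- act_TC * TN - (pb[41L] * mu2 + pb[42L] * Tr + pb[43L]) * TC
  dTr <- act_Tr * TN - (pb[44L] * mu1 + pb[45L] + pt[6L] * Ir) * Tr
  dDN <- pb[2L] - act_D * DN - (pb[46L] * H + pb[47L]) * DN
  dD  <- act_D * DN - (pb[46L] * H + pb[48L] * C + pb[47L]) * D
  dM  <- (pb[16L] * mu2 + pb[17L] * Ig + pb[18L] * Th) * (pb[3L] - M) - pb[49L] * M
  dC  <- (pb[19L] + pb[20L] * mu1) * C * (1 - C / pb[4L]) - death_C * C
  dN  <- pb[5L] * death_C * C - pb[54L] * N
  dH  <- pb[21L] * N + pb[22L] * M + pb[23L] * Th + pb[24L] * TC + pb[25L] * Tr -
    pb[55L] * H
  dmu1 <- pb[26L] * Th + pb[27L] * M + pb[28L] * D - pb[56L] * mu1
  dmu2 <- pb[29L] * M + pb[30L] * D + pb[31L] * Tr - pb[57L] * mu2
  dIg  <- pb[32L] * Th + pb[33L] * TC + pb[34L] * M - pb[58L] * Ig
  dGb  <- pb[35L] * M + pb[36L] * Tr - pb[59L] * Gb

  # 5-FU consumption bracket: same kill bracket as the cancer equation,
  # scaled by alpha_5fu, excluding the irinotecan term
  consume_fu <- (pt[1L] * FU + pt[2L] * FU * Ig - pt[3L] * FU * M +
                   pt[4L] * FU * LV) * C
  dFU <- u[1L] - pt[10L] * consume_fu - pt[7L] * FU * D - pt[14L] * FU
  dLV <- u[2L] - pt[15L] * LV - pt[11L] * pt[4L] * C * FU * LV
  dIr <- u[3L] - pt[12L] * pt[5L] * C * Ir - pt[13L] * pt[6L] * Ir * Tr -
    pt[16L] * Ir

  c(dTN, dTh, dTC, dTr, dDN, dD, dM, dC, dN, dH, dmu1, dmu2, dIg, dGb,
    dFU, dLV, dIr)
}

#' Right-hand side of the untreated tumor-microenvironment system
#'
#' Evaluates the 14 coupled mass-action equations of the no-treatment model:
#' naive-T-cell bookkeeping (all helper/cytotoxic/regulatory activation terms
#' are subtracted from the naive pool), the saturating macrophage activation
#' factor `(M0 - M)`, logistic cancer growth `(1 - C/C0)`, and a necrosis
#' source equal to `alpha_NC` times the cancer death flux. The death flux
#' expression is computed once and shared between the cancer and necrosis
#' equations.
#'
#' @param state Named numeric vector with the 14 microenvironment components
#'   (a 17-component state is accepted; drugs are ignored). All components
#'   must be non-negative.
#' @param params A `folfiri_params` object (or the bare named baseline
#'   vector).
#' @return Named numeric vector of 14 time-derivatives (per day).
#' @export
rhs_baseline <- function(state, params) {
  pb <- as_baseline_vector(params)
  x <- check_rhs_state(state, 14L)
  stats::setNames(rhs_baseline_core(x, pb), BASELINE_STATE_NAMES)
}

#' Right-hand side of the FOLFIRI-treated system
#'
#' Extends [rhs_baseline()] with the drug terms: the cancer death bracket
#' gains `delta_C5fu*FU + delta_C5fuIg*FU*Ig - delta_5fuM*FU*M +
#' delta_CLV5fu*FU*LV + delta_CIr*Ir` (macrophages reduce the net 5-FU kill),
#' mirrored in the necrosis source; 5-FU-assisted dendritic activation of
#' helper and cytotoxic T-cells (also debited from the naive pool);
#' irinotecan depletion of regulatory T-cells; and the three drug balance
#' equations with injection, consumption and first-order decay.
#'
#' @inheritParams rhs_baseline
#' @param state Named numeric vector with all 17 components.
#' @param infusion Length-3 non-negative vector of dimensionless injection
#'   rates (per day) for `FU`, `LV`, `Ir` at the evaluation time, as produced
#'   by [dimensionless_injection()].
#' @return Named numeric vector of 17 time-derivatives (per day).
#' @export
rhs_treatment <- function(state, params, infusion = c(0, 0, 0)) {
  stopifnot(inherits(params, "folfiri_params"))
  if (is.null(params$treatment)) {
    stop("params has no treatment block; derive one with derive_params()")
  }
  x <- check_rhs_state(state, 17L)
  infusion <- unname(infusion)
  if (length(infusion) != 3L || any(!is.finite(infusion)) || any(infusion < 0)) {
    stop("infusion must be 3 non-negative finite rates (FU, LV, Ir)")
  }
  stats::setNames(
    rhs_treatment_core(x, params$baseline, params$treatment, infusion),
    STATE_NAMES
  )
}

as_baseline_vector <- function(params) {
  if (inherits(params, "folfiri_params")) return(params$baseline)
  new_param_block(params, BASELINE_PARAM_NAMES, "baseline")
}

check_rhs_state <- function(state, n) {
  x <- unname(state)
  if (length(x) == 17L && n == 14L) x <- x[1:14]
  if (length(x) != n) stop("state must have ", n, " components")
  neg <- which(x < 0)
  if (length(neg)) {
    stop("negative state component(s): ",
         paste(STATE_NAMES[neg], collapse = ", "))
  }
  x
}

#' Numerical Jacobian of the treated system
#'
#' Central finite differences of the 17-variable treated right-hand side with
#' a per-column relative step `h = 1e-6 * max(1, |x_j|)`.
#'
#' @inheritParams rhs_treatment
#' @return A 17 x 17 matrix with entry (i, j) = d(dX_i/dt)/dX_j.
#' @export
model_jacobian <- function(state, params, infusion = c(0, 0, 0)) {
  stopifnot(inherits(params, "folfiri_params"))
  pb <- params$baseline
  pt <- params$treatment
  if (is.null(pt)) stop("params has no treatment block")
  x <- unname(state)
  stopifnot(length(x) == 17L)
  u <- unname(infusion)
  J <- matrix(0, 17L, 17L, dimnames = list(STATE_NAMES, STATE_NAMES))
  for (j in seq_len(17L)) {
    h <- 1e-6 * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    fp <- rhs_treatment_core(xp, pb, pt, u)
    fm <- rhs_treatment_core(xm, pb, pt, u)
    col <- (fp - fm) / (2 * h)
    if (any(!is.finite(col))) {
      stop("non-finite derivative when perturbing ", STATE_NAMES[j])
    }
    J[, j] <- col
  }
  J
}
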