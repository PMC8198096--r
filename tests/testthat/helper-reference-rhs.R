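# Independent oracle: a literal, name-based transcription of the treated
# system's equations, evaluated with with(). Deliberately written without
# reusing any package internals so that an indexing mistake in the fast
# positional cores cannot also hide here.

rhs_reference <- function(state, params, infusion = c(0, 0, 0)) {
  e <- c(as.list(state), as.list(params$baseline), as.list(params$treatment),
         list(u_fu = infusion[1], u_lv = infusion[2], u_ir = infusion[3]))
  with(e, {
    kill <- delta_CGb * Gb + delta_CIg * Ig + delta_CTC * TC + delta_C +
      delta_C5fu * FU + delta_C5fuIg * FU * Ig - delta_5fuM * FU * M +
      delta_CLV5fu * FU * LV + delta_CIr * Ir
    c(
      TN = A_TN -
        (lambda_ThD * D + lambda_ThD5fu * FU * D + lambda_ThM * M +
           lambda_Thmu1 * mu1) * TN -
        (lambda_TCTh * Th + lambda_TCD * D + lambda_TCD5fu * FU * D) * TN -
        (lambda_TrTh * Th + lambda_Trmu2 * mu2 + lambda_TrGb * Gb) * TN -
        delta_TN * TN,
      Th = (lambda_ThD * D + lambda_ThD5fu * FU * D + lambda_ThM * M +
              lambda_Thmu1 * mu1) * TN -
        (delta_Thmu2 * mu2 + delta_ThTr * Tr + delta_Th) * Th,
      TC = (lambda_TCTh * Th + lambda_TCD * D + lambda_TCD5fu * FU * D) * TN -
        (delta_TCmu2 * mu2 + delta_TCTr * Tr + delta_TC) * TC,
      Tr = (lambda_TrTh * Th + lambda_Trmu2 * mu2 + lambda_TrGb * Gb) * TN -
        (delta_Trmu1 * mu1 + delta_Tr + delta_TrIr * Ir) * Tr,
      DN = A_DN - (lambda_DH * H + lambda_DC * C) * DN -
        (delta_DH * H + delta_D) * DN,
      D = (lambda_DH * H + lambda_DC * C) * DN -
        (delta_DH * H + delta_DC * C + delta_D) * D,
      M = (lambda_Mmu2 * mu2 + lambda_MIg * Ig + lambda_MTh * Th) * (M0 - M) -
        delta_M * M,
      C = (lambda_C + lambda_Cmu1 * mu1) * C * (1 - C / C0) - kill * C,
      N = alpha_NC * kill * C - delta_N * N,
      H = lambda_HN * N + lambda_HM * M + lambda_HTh * Th + lambda_HTC * TC +
        lambda_HTr * Tr - delta_H * H,
      mu1 = lambda_mu1Th * Th + lambda_mu1M * M + lambda_mu1D * D -
        delta_mu1 * mu1,
      mu2 = lambda_mu2M * M + lambda_mu2D * D + lambda_mu2Tr * Tr -
        delta_mu2 * mu2,
      Ig = lambda_IgTh * Th + lambda_IgTC * TC + lambda_IgM * M -
        delta_Ig * Ig,
      Gb = lambda_GbM * M + lambda_GbTr * Tr - delta_Gb * Gb,
      FU = u_fu -
        alpha_5fu * (delta_C5fu * FU + delta_C5fuIg * FU * Ig -
                       delta_5fuM * FU * M + delta_CLV5fu * FU * LV) * C -
        delta_5fuD * FU * D - delta_5fu * FU,
      LV = u_lv - delta_LV * LV - alpha_LV * delta_CLV5fu * C * FU * LV,
      Ir = u_ir - alpha_IrC * delta_CIr * C * Ir -
        alpha_IrTr * delta_TrIr * Ir * Tr - delta_Ir * Ir
    )
  })
}
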