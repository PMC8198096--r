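#' Default assumption set for parameter derivation
#'
#' The model is solved in the dimensionless scale in which every untreated
#' variable has steady state 1, so rates are fixed by (i) a total turnover
#' rate per variable (from a configured half-life) and (ii) weight vectors
#' allocating each variable's steady-state production and removal among its
#' equation's terms. Drug assumptions hold the per-cycle kill efficiencies,
#' plasma half-lives, synergy fractions and consumption fractions used to
#' derive the 19 treatment parameters.
#'
#' Defaults (documented in the methods vignette): cell half-lives of days to
#' weeks, cytokine half-lives of hours, cancer turnover slow enough that the
#' untreated approach to steady state takes several years; irinotecan
#' cancer-kill efficiency 0.40 per cycle, 5-FU 0.10, incremental leucovorin
#' 0.35 (both below irinotecan's 0.40), regulatory-T-cell depletion by
#' irinotecan 0.30, hepatic elimination fraction of 5-FU 0.80, and equal
#' weights within every production/removal group.
#'
#' @return A nested list with components `half_life_days`, `capacities`,
#'   `weights` (`$production`, `$removal`), and `drugs`.
#' @export
default_assumptions <- function() {
  eq <- function(...) {
    nm <- c(...)
    stats::setNames(rep(1 / length(nm), length(nm)), nm)
  }
  list(
    half_life_days = c(
      TN = 70, Th = 3.5, TC = 3.5, Tr = 3.5, D = 2.3, M = 14,
      C = 140, N = 350, H = 0.7, mu1 = 0.35, mu2 = 0.35,
      Ig = 0.17, Gb = 0.23
    ),
    capacities = c(M0 = 2, C0 = 2),
    weights = list(
      production = list(
        Th = eq("lambda_ThD", "lambda_ThM", "lambda_Thmu1"),
        TC = eq("lambda_TCTh", "lambda_TCD"),
        Tr = eq("lambda_TrTh", "lambda_Trmu2", "lambda_TrGb"),
        D  = eq("lambda_DH", "lambda_DC"),
        M  = eq("lambda_Mmu2", "lambda_MIg", "lambda_MTh"),
        C  = eq("lambda_C", "lambda_Cmu1"),
        H  = eq("lambda_HN", "lambda_HM", "lambda_HTh", "lambda_HTC",
                "lambda_HTr"),
        mu1 = eq("lambda_mu1Th", "lambda_mu1M", "lambda_mu1D"),
        mu2 = eq("lambda_mu2M", "lambda_mu2D", "lambda_mu2Tr"),
        Ig = eq("lambda_IgTh", "lambda_IgTC", "lambda_IgM"),
        Gb = eq("lambda_GbM", "lambda_GbTr")
      ),
      removal = list(
        Th = eq("delta_Thmu2", "delta_ThTr", "delta_Th"),
        TC = eq("delta_TCmu2", "delta_TCTr", "delta_TC"),
        Tr = eq("delta_Trmu1", "delta_Tr"),
        D  = eq("delta_DH", "delta_DC", "delta_D"),
        C  = eq("delta_CGb", "delta_CIg", "delta_CTC", "delta_C")
      )
    ),
    drugs = list(
      # per-cycle kill efficiencies under the median regimen
      efficiency = c(ir = 0.40, fu = 0.10, lv = 0.35, treg_ir = 0.30),
      hepatic_fraction_5fu = 0.80,
      # plasma half-lives in days (5-FU ~20 min, LV ~6 h, irinotecan ~12 h)
      half_life_days = c(fu = 0.0139, lv = 0.26, ir = 0.5),
      # auxiliary rates as fractions of their parent rates
      synergy_fractions = c(C5fuIg = 0.5, fuM = 0.5, ThD5fu = 0.1,
                            TCD5fu = 0.1, fuD = 0.05),
      # drug consumption by each modeled interaction, as fraction of decay
      consumption_fraction = 0.1,
      median_dose = c(fu = 770, lv = 725, ir = 300),
      cycle_length = 14
    )
  )
}

#' Read / write an assumption set as YAML
#'
#' @param assumptions Assumption list as from [default_assumptions()].
#' @param path File path.
#' @export
write_assumptions <- function(assumptions, path) {
  # yaml drops the names of atomic vectors; serialize them as maps
  listify <- function(x) {
    if (is.list(x)) {
      lapply(x, listify)
    } else if (!is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(listify(assumptions), path, precision = 15)
  invisible(path)
}

#' @rdname write_assumptions
#' @export
read_assumptions <- function(path) {
  a <- yaml::read_yaml(path)
  a$half_life_days <- unlist(a$half_life_days)
  a$capacities <- unlist(a$capacities)
  a$weights$production <- lapply(a$weights$production, unlist)
  a$weights$removal <- lapply(a$weights$removal, unlist)
  a$drugs$efficiency <- unlist(a$drugs$efficiency)
  a$drugs$half_life_days <- unlist(a$drugs$half_life_days)
  a$drugs$synergy_fractions <- unlist(a$drugs$synergy_fractions)
  a$drugs$median_dose <- unlist(a$drugs$median_dose)
  a
}

check_weights <- function(w, label) {
  if (any(w < 0)) stop("negative weight in ", label)
  if (abs(sum(w) - 1) > 1e-12) {
    stop("weights for ", label, " must sum to 1 (got ", sum(w), ")")
  }
  w
}

allocate <- function(w, flux, factor, label) {
  w <- check_weights(w, label)
  if (factor <= 0 && any(w > 0)) {
    stop("unallocatable flux in ", label,
         ": steady-state factor is 0 but a weight is positive")
  }
  w * flux / factor
}

#' Derive the 59 baseline parameters from steady-state assumptions
#'
#' For each variable with dimensionless steady state 1, the total removal
#' flux is its turnover rate; each removal-term rate is its weight times the
#' turnover divided by the term's state factor at equilibrium, and the
#' production terms are allocated likewise against an equal total flux. The
#' sources `A_TN` and `A_DN` are the residual production of their equations,
#' `M0` and `C0` place the saturation and logistic factors at their midpoint
#' (default 2), and `alpha_NC` is set so the necrosis equation balances:
#' `alpha_NC = delta_N / (cancer per-capita death rate at equilibrium)`.
#' By construction `rhs_baseline(all-ones)` vanishes.
#'
#' @param assumptions Assumption set ([default_assumptions()]).
#' @return Named numeric vector of the 59 baseline parameters.
#' @export
derive_baseline_params <- function(assumptions = default_assumptions()) {
  hl <- assumptions$half_life_days
  need <- setdiff(BASELINE_STATE_NAMES, c("DN"))
  missing <- setdiff(need, names(hl))
  if (length(missing)) stop("half_life_days missing: ",
                            paste(missing, collapse = ", "))
  if (any(hl <= 0)) stop("half-lives must be positive")
  turn <- log(2) / hl
  M0 <- assumptions$capacities[["M0"]]
  C0 <- assumptions$capacities[["C0"]]
  wp <- assumptions$weights$production
  wr <- assumptions$weights$removal

  p <- stats::setNames(numeric(length(BASELINE_PARAM_NAMES)),
                       BASELINE_PARAM_NAMES)
  p["M0"] <- M0
  p["C0"] <- C0

  # production allocations (steady-state factor 1 except M and C)
  prod_factor <- c(Th = 1, TC = 1, Tr = 1, D = 1, M = M0 - 1, C = 1 - 1 / C0,
                   H = 1, mu1 = 1, mu2 = 1, Ig = 1, Gb = 1)
  for (v in names(wp)) {
    rates <- allocate(wp[[v]], turn[[v]], prod_factor[[v]],
                      paste0("production of ", v))
    p[names(rates)] <- rates
  }
  # removal allocations (all factors 1 at the all-ones state)
  for (v in names(wr)) {
    rates <- allocate(wr[[v]], turn[[v]], 1, paste0("removal of ", v))
    p[names(rates)] <- rates
  }
  # single-term removals carry the full turnover
  p["delta_M"] <- turn[["M"]]
  p["delta_N"] <- turn[["N"]]
  p["delta_H"] <- turn[["H"]]
  p["delta_mu1"] <- turn[["mu1"]]
  p["delta_mu2"] <- turn[["mu2"]]
  p["delta_Ig"] <- turn[["Ig"]]
  p["delta_Gb"] <- turn[["Gb"]]
  p["delta_TN"] <- turn[["TN"]]

  # residual sources: naive pools replenish their own decay plus every
  # activation outflow, which at equilibrium equals the downstream turnover
  p["A_TN"] <- turn[["Th"]] + turn[["TC"]] + turn[["Tr"]] + p["delta_TN"]
  p["A_DN"] <- (p["lambda_DH"] + p["lambda_DC"]) + (p["delta_DH"] + p["delta_D"])

  # necrosis balance: production alpha_NC * (death flux) = delta_N at eq
  p["alpha_NC"] <- p[["delta_N"]] / turn[["C"]]

  p
}

#' Per-cycle efficiency to kill-rate calibration
#'
#' Survival-fraction semantics: a drug that is a fraction `e` efficient per
#' treatment cycle kills so that the survival is `1 - e` after one cycle's
#' dimensionless exposure `E`, giving rate `-log(1 - e) / E`.
#'
#' @param e Efficiency in `[0, 1)`.
#' @param exposure Per-cycle dimensionless drug exposure (time integral of
#'   the scaled concentration).
#' @return Kill rate (per day per unit dimensionless concentration).
#' @export
calibrate_kill_rate <- function(e, exposure) {
  if (any(e < 0) || any(e >= 1)) {
    stop("efficiency must be in [0, 1); got ", paste(e, collapse = ", "))
  }
  ifelse(e == 0, 0, -log(1 - e) / exposure)
}

#' Derive the 19 treatment parameters
#'
#' Kill rates are calibrated so that, under the cohort-median regimen acting
#' alone on its target, one cycle removes the configured efficiency fraction
#' (`rate = -log(1 - e) / E` with `E` the per-cycle dimensionless exposure;
#' for the combined 5-FU/leucovorin rate, `E` is the product exposure).
#' Synergy and auxiliary rates are configured fractions of their parent
#' rates; the consumption-efficiency constants `alpha_*` are set so that drug
#' consumption by each interaction (at unit states) is a configured fraction
#' of natural decay; decay rates come from plasma half-lives; and the three
#' daily-median dose scales complete the injection functions.
#'
#' @param assumptions Assumption set ([default_assumptions()]).
#' @param baseline Baseline parameter vector from
#'   [derive_baseline_params()] (parents of the 5-FU-assisted activation
#'   rates).
#' @return Named numeric vector of the 19 treatment parameters.
#' @export
derive_treatment_params <- function(assumptions = default_assumptions(),
                                    baseline = derive_baseline_params(assumptions)) {
  dr <- assumptions$drugs
  e <- dr$efficiency
  if (any(e >= 1)) stop("drug efficiency of 1 implies an infinite kill rate")
  delta <- log(2) / dr$half_life_days[c("fu", "lv", "ir")]
  scaling <- drug_scaling(delta, dr$median_dose, dr$cycle_length)
  med_reg <- regimen(dose_5fu = dr$median_dose[["fu"]],
                     dose_lv = dr$median_dose[["lv"]],
                     dose_ir = dr$median_dose[["ir"]],
                     cycle_length = dr$cycle_length)
  E <- drug_exposure(med_reg, scaling)

  fr <- dr$synergy_fractions
  cf <- dr$consumption_fraction

  pt <- stats::setNames(numeric(length(TREATMENT_PARAM_NAMES)),
                        TREATMENT_PARAM_NAMES)
  pt["delta_5fu"] <- delta[["fu"]]
  pt["delta_LV"] <- delta[["lv"]]
  pt["delta_Ir"] <- delta[["ir"]]
  pt["A_5fu_daily"] <- scaling$A_daily[["fu"]]
  pt["A_LV_daily"] <- scaling$A_daily[["lv"]]
  pt["A_Ir_daily"] <- scaling$A_daily[["ir"]]

  pt["delta_C5fu"] <- calibrate_kill_rate(e[["fu"]], E[["fu"]])
  pt["delta_CIr"] <- calibrate_kill_rate(e[["ir"]], E[["ir"]])
  pt["delta_TrIr"] <- calibrate_kill_rate(e[["treg_ir"]], E[["ir"]])
  pt["delta_CLV5fu"] <- if (E[["fu_lv"]] > 0) {
    calibrate_kill_rate(e[["lv"]], E[["fu_lv"]])
  } else 0

  pt["delta_C5fuIg"] <- fr[["C5fuIg"]] * pt[["delta_C5fu"]]
  pt["delta_5fuM"] <- fr[["fuM"]] * pt[["delta_C5fu"]]
  pt["lambda_ThD5fu"] <- fr[["ThD5fu"]] * baseline[["lambda_ThD"]]
  pt["lambda_TCD5fu"] <- fr[["TCD5fu"]] * baseline[["lambda_TCD"]]
  pt["delta_5fuD"] <- fr[["fuD"]] * pt[["delta_5fu"]]

  bracket <- pt[["delta_C5fu"]] + pt[["delta_C5fuIg"]] - pt[["delta_5fuM"]] +
    pt[["delta_CLV5fu"]]
  pt["alpha_5fu"] <- if (bracket > 0) cf * pt[["delta_5fu"]] / bracket else 0
  pt["alpha_LV"] <- if (pt[["delta_CLV5fu"]] > 0) {
    cf * pt[["delta_LV"]] / pt[["delta_CLV5fu"]]
  } else 0
  pt["alpha_IrC"] <- if (pt[["delta_CIr"]] > 0) {
    cf * pt[["delta_Ir"]] / pt[["delta_CIr"]]
  } else 0
  pt["alpha_IrTr"] <- if (pt[["delta_TrIr"]] > 0) {
    cf * pt[["delta_Ir"]] / pt[["delta_TrIr"]]
  } else 0

  pt
}

#' Derive the full parameter set from an assumption set
#'
#' @inheritParams derive_baseline_params
#' @return A [folfiri_params()] object with both blocks.
#' @export
derive_params <- function(assumptions = default_assumptions()) {
  baseline <- derive_baseline_params(assumptions)
  folfiri_params(baseline,
                 derive_treatment_params(assumptions, baseline))
}

#' Residual of the untreated all-ones equilibrium
#'
#' @param params A `folfiri_params` object or baseline vector.
#' @return `max(abs(rhs_baseline(all-ones)))`.
#' @export
verify_equilibrium <- function(params) {
  ones <- stats::setNames(rep(1, 14), BASELINE_STATE_NAMES)
  max(abs(rhs_baseline(ones, params)))
}

#' Scaling object implied by an assumption set
#'
#' @inheritParams derive_baseline_params
#' @return A [drug_scaling()] built from the assumption set's drug
#'   half-lives, median doses and cycle length.
#' @export
assumed_scaling <- function(assumptions = default_assumptions()) {
  dr <- assumptions$drugs
  drug_scaling(log(2) / dr$half_life_days[c("fu", "lv", "ir")],
               dr$median_dose, dr$cycle_length)
}
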