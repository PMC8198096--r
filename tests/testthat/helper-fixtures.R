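# Shared fixtures, memoized across test files (derivation and the long
# median-regimen simulation are reused by several suites).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_params_cached <- function() cached("params", derive_params())

median_trajectory_cached <- function() {
  cached("median_traj",
         simulate_tme(state_vector(), default_params_cached(), regimen(),
                      horizon = 3285))
}

zero_dose_regimen <- function(...) {
  regimen(dose_5fu = 0, dose_lv = 0, dose_ir = 0, ...)
}

random_state17 <- function(seed, max = 2) {
  set.seed(seed)
  stats::setNames(stats::runif(17, 0, max), STATE_NAMES)
}

random_params <- function(seed) {
  set.seed(seed)
  pb <- stats::setNames(stats::runif(59, 0, 1), BASELINE_PARAM_NAMES)
  pb["M0"] <- 2 + stats::runif(1)
  pb["C0"] <- 2 + stats::runif(1)
  pt <- stats::setNames(stats::runif(19, 0, 0.5), TREATMENT_PARAM_NAMES)
  pt[c("A_5fu_daily", "A_LV_daily", "A_Ir_daily")] <- c(55, 51.8, 21.4)
  folfiri_params(pb, pt)
}
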