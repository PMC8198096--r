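#' Forward sensitivity of a parameterized ODE system
#'
#' Integrates the augmented system `dS/dt = dF/dtheta + (dF/dX) S` alongside
#' the state, with `S(0) = 0` (parameters do not affect the initial
#' condition). Both the parameter derivative `dF/dtheta` and the
#' Jacobian-vector product `(dF/dX) S` are directional derivatives of the
#' right-hand side; by default they are evaluated by complex-step
#' differentiation, which is exact to machine precision for the polynomial
#' mass-action right-hand sides used here (no subtractive cancellation, so
#' the step-size controller never sees differentiation noise). A central
#' finite-difference fallback is provided for right-hand sides that do not
#' accept complex arithmetic.
#'
#' This generic core is exposed so the machinery can be verified on systems
#' with closed-form sensitivities (e.g. pure exponential decay).
#'
#' @param make_f Function of the scalar parameter value returning the RHS
#'   `f(t, y)`. For the complex-step method, the returned RHS must tolerate
#'   complex `y` and a complex parameter (plain arithmetic does).
#' @param theta Parameter value at which to differentiate.
#' @param y0 Initial state.
#' @param times Output time grid (first element is the initial time).
#' @param S0 Initial sensitivity (default zero).
#' @param rtol,atol Solver tolerances.
#' @param method `"complex-step"` (default) or `"finite-difference"`.
#' @return List with `times`, `state` (matrix), `S` (matrix of the same
#'   shape: sensitivity of each state component).
#' @export
sensitivity_ode <- function(make_f, theta, y0, times, S0 = NULL,
                            rtol = 1e-8, atol = 1e-10,
                            method = c("complex-step", "finite-difference")) {
  method <- match.arg(method)
  n <- length(y0)
  if (is.null(S0)) S0 <- numeric(n)
  f0 <- make_f(theta)
  if (method == "complex-step") {
    hc <- 1e-20
    fth <- make_f(complex(real = theta, imaginary = hc))
    aug <- function(t, z, p) {
      y <- z[seq_len(n)]
      S <- z[-seq_len(n)]
      dy <- f0(t, y)
      dfdth <- Im(fth(t, y + 0i)) / hc
      JS <- Im(f0(t, y + (1i * hc) * S)) / hc
      list(c(dy, dfdth + JS))
    }
  } else {
    h_th <- if (theta != 0) 1e-6 * abs(theta) else 1e-8
    fp <- make_f(theta + h_th)
    fm <- make_f(theta - h_th)
    aug <- function(t, z, p) {
      y <- z[seq_len(n)]
      S <- z[-seq_len(n)]
      dy <- f0(t, y)
      dfdth <- (fp(t, y) - fm(t, y)) / (2 * h_th)
      nS <- sqrt(sum(S * S))
      JS <- if (nS == 0) {
        numeric(n)
      } else {
        v <- S / nS
        eps <- 1e-7 * (1 + sqrt(sum(y * y)))
        nS * (f0(t, y + eps * v) - f0(t, y - eps * v)) / (2 * eps)
      }
      list(c(dy, dfdth + JS))
    }
  }
  sol <- deSolve::lsoda(c(y0, S0), times, aug, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000L)
  if (attr(sol, "istate")[1L] < 0 || sol[nrow(sol), 1L] < times[length(times)]) {
    stop("sensitivity integration failed at t = ", sol[nrow(sol), 1L])
  }
  list(times = sol[, 1L],
       state = sol[, 1L + seq_len(n), drop = FALSE],
       S = sol[, 1L + n + seq_len(n), drop = FALSE])
}

set_model_param <- function(params, theta_name, value) {
  if (theta_name %in% BASELINE_PARAM_NAMES) {
    pb <- params$baseline
    pb[theta_name] <- value
    folfiri_params(pb, params$treatment)
  } else if (theta_name %in% TREATMENT_PARAM_NAMES) {
    pt <- params$treatment
    pt[theta_name] <- value
    folfiri_params(params$baseline, pt)
  } else {
    stop("unknown parameter '", theta_name, "'")
  }
}

#' Time-dependent forward sensitivity of the treated model
#'
#' For each requested parameter, integrates the state together with its
#' sensitivity block (17 + 17 components, one parameter at a time) under the
#' same piecewise infusion forcing as [simulate_tme()]. Sensitivity to the
#' daily-median dose scales propagates through the injection forcing as
#' well.
#'
#' @param params A [folfiri_params()].
#' @param theta Character vector of parameter names (baseline or treatment).
#' @param initial Initial state (default: steady state, i.e. large tumors).
#' @param reg A [regimen()].
#' @param horizon Averaging/integration horizon in days; default is the end
#'   of treatment plus two years.
#' @param dt_out Output spacing (days).
#' @param rtol,atol Solver tolerances (sensitivity default `1e-6`/`1e-8`).
#' @param method Differentiation method, see [sensitivity_ode()].
#' @return An object of class `folfiri_sensitivity_set`: a named list with
#'   one `folfiri_sensitivity` element per parameter, each holding `times`,
#'   the state matrix, the sensitivity matrix `S` and the parameter value.
#' @export
forward_sensitivity <- function(params, theta, initial = state_vector(),
                                reg = regimen(), horizon = NULL, dt_out = 1,
                                rtol = 1e-6, atol = 1e-8,
                                method = c("complex-step",
                                           "finite-difference")) {
  stopifnot(inherits(params, "folfiri_params"))
  method <- match.arg(method)
  if (is.null(params$treatment)) stop("params has no treatment block")
  all_names <- c(BASELINE_PARAM_NAMES, TREATMENT_PARAM_NAMES)
  bad <- setdiff(theta, all_names)
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(horizon)) horizon <- treatment_end_day(reg) + 730
  y0 <- unname(initial)
  if (length(y0) == 14L) y0 <- c(y0, 0, 0, 0)

  pb0 <- params$baseline
  pt0 <- params$treatment
  seg <- sort(unique(c(0, regimen_breakpoints(reg, horizon), horizon)))
  grid <- sort(unique(c(seq(0, horizon, by = dt_out), seg)))

  results <- purrr::map(theta, function(th_name) {
    is_base <- th_name %in% BASELINE_PARAM_NAMES
    th_val <- if (is_base) pb0[[th_name]] else pt0[[th_name]]
    z_state <- y0
    z_S <- numeric(17L)
    pieces <- vector("list", length(seg) - 1L)
    for (i in seq_len(length(seg) - 1L)) {
      a <- seg[i]; b <- seg[i + 1L]
      tt <- grid[grid >= a & grid <= b]
      if (tt[1] > a) tt <- c(a, tt)
      if (tt[length(tt)] < b) tt <- c(tt, b)
      r_mid <- infusion_rates((a + b) / 2, reg)  # mg/day, constant on segment
      make_f <- function(th) {
        pb <- pb0
        pt <- pt0
        if (is_base) pb[th_name] <- th else pt[th_name] <- th
        u <- c(pt[["delta_5fu"]] / pt[["A_5fu_daily"]] * r_mid$rate_5fu,
               pt[["delta_LV"]] / pt[["A_LV_daily"]] * r_mid$rate_lv,
               pt[["delta_Ir"]] / pt[["A_Ir_daily"]] * r_mid$rate_ir)
        function(t, y) rhs_treatment_core(y, pb, pt, u)
      }
      sol <- sensitivity_ode(make_f, th_val, z_state, tt, S0 = z_S,
                             rtol = rtol, atol = atol, method = method)
      keep <- if (i == 1L) seq_along(sol$times) else -1L
      pieces[[i]] <- list(times = sol$times[keep],
                          state = sol$state[keep, , drop = FALSE],
                          S = sol$S[keep, , drop = FALSE])
      z_state <- sol$state[nrow(sol$state), ]
      z_S <- sol$S[nrow(sol$S), ]
    }
    times <- do.call(c, purrr::map(pieces, "times"))
    state <- do.call(rbind, purrr::map(pieces, "state"))
    S <- do.call(rbind, purrr::map(pieces, "S"))
    colnames(state) <- STATE_NAMES
    colnames(S) <- STATE_NAMES
    structure(list(parameter = th_name, theta = th_val, times = times,
                   state = state, S = S, horizon = horizon),
              class = "folfiri_sensitivity")
  })
  names(results) <- theta
  structure(results, class = "folfiri_sensitivity_set")
}

#' Relative sensitivity curves
#'
#' `Sbar_i(t) = S_i(t) * theta_i / X(t)`, masked (`NA`) wherever the state
#' falls below `threshold` — cancer can approach zero after treatment, and
#' the division blow-up is reported rather than propagated.
#'
#' @param result A `folfiri_sensitivity` (one element of
#'   [forward_sensitivity()]'s output).
#' @param threshold Masking threshold on the state (default `1e-8`).
#' @return Matrix of relative sensitivities (same shape as `result$S`) with
#'   attribute `n_masked`.
#' @export
relative_sensitivity <- function(result, threshold = 1e-8) {
  stopifnot(inherits(result, "folfiri_sensitivity"))
  X <- result$state
  rel <- result$S * result$theta / X
  mask <- X < threshold
  rel[mask] <- NA_real_
  structure(rel, n_masked = sum(mask))
}

#' Time-averaged curves
#'
#' Trapezoidal quadrature of each curve over `[0, T]` on the solution grid,
#' divided by `T`. Columns containing masked (`NA`) points average to `NA`.
#'
#' @param values Numeric vector or matrix (rows indexed by `times`).
#' @param times Time grid.
#' @param T Averaging horizon (default: last time).
#' @return Scalar or named vector of averages.
#' @export
time_average <- function(values, times, T = max(times)) {
  stopifnot(T <= max(times), T > min(times))
  keep <- times <= T
  tt <- times[keep]
  trapz <- function(y) {
    if (anyNA(y)) return(NA_real_)
    sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) / T
  }
  if (is.matrix(values)) {
    apply(values[keep, , drop = FALSE], 2L, trapz)
  } else {
    trapz(values[keep])
  }
}

#' Rank parameters by time-averaged sensitivity
#'
#' Ranks the analyzed parameters by the absolute value of their
#' time-averaged sensitivity of the chosen output (cancer density or total
#' cell density). Both the absolute and the relative variants are reported;
#' the default ranking uses the absolute (non-relative) averages.
#'
#' @param sens A `folfiri_sensitivity_set` from [forward_sensitivity()].
#' @param output `"C"` (cancer) or `"total_cells"`.
#' @param variant Ranking variant: `"absolute"` (default) or `"relative"`.
#' @param T Averaging horizon (default: each result's full grid).
#' @param threshold Masking threshold for the relative curves.
#' @return Tibble with columns `parameter`, `theta`, `avg_sensitivity`,
#'   `avg_relative_sensitivity`, `rank`, sorted by rank.
#' @export
rank_parameters <- function(sens, output = c("C", "total_cells"),
                            variant = c("absolute", "relative"),
                            T = NULL, threshold = 1e-8) {
  stopifnot(inherits(sens, "folfiri_sensitivity_set"), length(sens) >= 2)
  output <- match.arg(output)
  variant <- match.arg(variant)
  rows <- purrr::map(unclass(sens), function(r) {
    Tr <- if (is.null(T)) max(r$times) else T
    if (output == "C") {
      s <- r$S[, "C"]
      x <- r$state[, "C"]
    } else {
      s <- rowSums(r$S[, CELL_STATE_NAMES, drop = FALSE])
      x <- rowSums(r$state[, CELL_STATE_NAMES, drop = FALSE])
    }
    rel <- s * r$theta / x
    rel[x < threshold] <- NA_real_
    tibble::tibble(
      parameter = r$parameter,
      theta = r$theta,
      avg_sensitivity = time_average(s, r$times, Tr),
      avg_relative_sensitivity = time_average(rel, r$times, Tr)
    )
  }) |> purrr::list_rbind()
  key <- if (variant == "absolute") {
    abs(rows$avg_sensitivity)
  } else {
    abs(rows$avg_relative_sensitivity)
  }
  key[is.na(key)] <- -Inf
  rows <- rows[order(key, decreasing = TRUE), , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rows
}
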