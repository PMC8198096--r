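---
title: "Modeling colon-cancer microenvironment dynamics under FOLFIRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling colon-cancer microenvironment dynamics under FOLFIRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(folfirisim)
```

## The model

`folfirisim` integrates a mass-action ODE model of the colon-cancer tumor
microenvironment: nine cell populations (naive, helper, cytotoxic and
regulatory T-cells; naive and activated dendritic cells; macrophages; cancer
cells; necrotic cells) and five cytokine species (HMGB1, IFN-γ, TGF-β, and
two aggregated pools — carcinogenic interleukins μ1 and immunosuppressive
agents μ2), extended by the three FOLFIRI drugs: 5-fluorouracil (5-FU),
leucovorin (LV) and irinotecan (Ir).

Every interaction is a mass-action product. The structural features worth
calling out:

* **Naive-pool bookkeeping.** Every activation term that creates helper,
  cytotoxic or regulatory T-cells is debited from the naive T-cell
  equation, which stabilizes the T-cell subsystem.
* **Shared cancer-death flux.** The per-capita cancer death rate (killing
  by TGF-β, IFN-γ, cytotoxic cells, natural death, and all drug terms) is
  computed once; the necrosis equation receives exactly `alpha_NC` times
  that flux. The two equations cannot drift apart.
* **Macrophage shielding.** Inside the cancer-death bracket the
  macrophage–5-FU term carries a *minus* sign (macrophages reduce the net
  5-FU kill). We keep the sign exactly as the model defines it, with no
  clamping; `simulate_tme()` warns if the net bracket is negative at more
  than 1% of output points, which would indicate an extreme
  macrophage-excess regime.
* **Drug pharmacodynamics.** Each drug has an injection term, first-order
  natural decay, and consumption terms tied to the interactions it powers
  (scaled by the `alpha_*` efficiency constants). Leucovorin has no
  cytotoxic term of its own: every leucovorin action multiplies the 5-FU
  concentration, so with no 5-FU the cell dynamics are provably
  insensitive to the LV dose — a property the test suite asserts.

## The dimensionless scale and parameter derivation

The system is solved in the scale in which each microenvironment variable
is divided by its untreated steady-state value, so the untreated
equilibrium is the all-ones vector. Drugs are scaled as
`Dbar = delta_D * [D] / A_daily`, where `delta_D` is the natural decay rate
and `A_daily` is the cohort daily-median dose (median dose per cycle / cycle
length, e.g. 770/14 mg/day for 5-FU): a hypothetical continuous infusion at
the daily-median rate equilibrates at `Dbar = 1`.

Absolute rate constants cannot be recovered from the dimensionless
trajectories alone, so `derive_baseline_params()` constructs them from two
kinds of assumptions:

* a **turnover rate** per variable (from a configured half-life), which
  fixes the total production = total removal flux at the all-ones state;
* **weight vectors** splitting each flux among the production and removal
  terms of that variable's equation (equal weights by default).

Sources (`A_TN`, `A_DN`) are the residual production of their equations;
`M0 = C0 = 2` place the macrophage saturation and cancer logistic factors
at their midpoints; and the necrosis fraction falls out of the balance as
`alpha_NC = turnover_N / turnover_C` (0.4 under the defaults). By
construction the derived set satisfies `rhs_baseline(all-ones) = 0` to
machine precision, and the Jacobian at the equilibrium has strictly
negative real spectral abscissa (≈ −0.002/day), so the equilibrium is
asymptotically stable: a ten-year untreated run stays at all-ones.

The half-life defaults are engineering choices, not measured quantities:
activated T-cells and dendritic cells live days, macrophages weeks,
cytokines hours, and naive T-cells months. Cancer turnover is set to
0.005/day, which makes the untreated approach to carrying capacity from a
small-tumor state take roughly five to seven years — the regrowth
timescale the downstream experiments probe. Necrotic clearance at
0.002/day gives `alpha_NC = 0.4`. All of these are config-overridable
(`default_assumptions()`, YAML round-trip via `write_assumptions()`).

## Drug parameters: per-cycle efficiency calibration

The 19 treatment parameters come from `derive_treatment_params()`:

* **Kill rates** follow survival-fraction semantics: a drug that is a
  fraction *e* efficient per cycle satisfies `exp(-rate * E) = 1 - e`,
  where `E` is the per-cycle dimensionless exposure under the median
  regimen acting alone (`E = dose / A_daily`, i.e. one cycle length for
  the median dose; the 5-FU × LV product exposure is integrated
  numerically from the closed-form decay profiles, ≈ 91 under the
  defaults). This reading scales correctly with dose and is the standard
  pharmacodynamic interpretation of "x% efficient".
* **Efficiency defaults**: irinotecan kills 40% of cancer cells per cycle;
  5-FU alone 10% (the order of the reported single-agent response rates);
  the incremental leucovorin effect 35%, so that 5-FU + LV lands near the
  40–50% response range reported for the combinations while both remain
  below irinotecan's 40%. Irinotecan's regulatory-T depletion efficiency
  is 30%. About 80% of 5-FU is eliminated hepatically; its natural decay
  rate is taken from a ~20-minute plasma half-life (LV ~6 h, Ir ~12 h).
* **Auxiliary rates** (IFN-γ synergy, macrophage shielding, 5-FU-assisted
  T-cell activation, dendritic consumption of 5-FU) are configured
  fractions of their parent rates, and the `alpha_*` consumption constants
  are set so that consumption by each interaction is 10% of natural decay
  at unit states.

## Infusion schedule

One cycle is a 1-h irinotecan drip, a 1-h leucovorin drip, then a 46-h
continuous 5-FU infusion; the default schedule is 12 cycles of 14 days at
the cohort-median doses 770/725/300 mg. Injection rates are
piecewise-constant step functions on half-open intervals (a breakpoint
belongs to the later phase, so evaluation at breakpoints is
deterministic), and hour-zero alignment of the irinotecan drip with the
cycle start is assumed. The integral of the rate over a cycle equals the
prescribed doses exactly.

## Numerical choices

* Integration uses `deSolve::lsoda` (stiff-capable) at `rtol = 1e-8`,
  `atol = 1e-10`, *restarted at every infusion breakpoint*: step-size
  control is never asked to discover a forcing discontinuity. Within a
  segment the injection rate is exactly constant.
* States are never clipped; a trajectory that goes negative beyond
  10 × `atol` fails the run rather than being silently repaired.
* The Jacobian (`model_jacobian()`) is numerical — central differences
  with step `1e-6 * max(1, |x_j|)` — and is verified against an
  independent finite-difference oracle in the tests.
* Forward sensitivities integrate the augmented system
  `dS/dt = dF/dθ + (dF/dX) S`, one parameter at a time (17 + 17 states),
  with `S(0) = 0`. Both directional derivatives are evaluated by
  **complex-step differentiation**, which is exact to machine precision
  for these polynomial right-hand sides. This matters numerically, not
  just for speed: subtractive-cancellation noise from real-valued
  differencing sits above the absolute tolerance whenever `|S|` is large
  and forces the step-size controller into a crawl. A central
  finite-difference fallback (`method = "finite-difference"`) is kept for
  right-hand sides that cannot take complex arguments, and the machinery
  is verified against the closed form of the exponential-decay model and
  against central differences of full simulations.
* Relative sensitivities `S θ / X` are masked where `X < 1e-8` (cancer
  approaches zero right after a successful course), and masked points make
  the corresponding time average undefined rather than infinite.
* Parameter ranking reports both the absolute and the relative
  time-averaged sensitivities over the treatment horizon plus two years;
  the default ranking uses the absolute variant, which weights a
  parameter by its exposure leverage (the 5-FU × LV product exposure is
  ~6× a single-drug exposure, which is why the combined kill rate
  dominates) rather than by the calibrated per-cycle efficiency alone.

## Synthetic cohorts and validation

The study's patient records (immune fractions estimated from bulk
expression by digital cytometry, tumor dimensions and necrosis from
biospecimen data, prescribed doses and follow-up status from clinical
records) are not redistributable, so `generate_cohort()` emulates their
statistical shape: 22 immune-cell fractions from a Dirichlet around
config-defined cluster centroids (qualitatively anchored: cluster 3 has
the highest, cluster 2 the lowest regulatory-T/helper-T ratio), log-normal
tumor dimensions, Beta-distributed necrosis with mean 0.1, doses uniform
between the cohort minimum and twice the median, and the 12 × 14-day
cycle structure. `tumor_scalars()` reproduces the density bookkeeping
(total cell density proportional to tumor size, scaled by
`alpha_dim = 7.5e4` cells/cm³ so the average cancer density is
4.5e4 cells/cm³; composition 0.3 : 0.6 : 0.1 at 10% necrosis).

Follow-up labels are generated *from the model itself*
(`assign_followup()`): tumor-free when simulated cancer at the follow-up
day is below the initial value (small/medium tumors) or half of it (large
tumors — initial dimensionless cancer ≥ 0.5, a configurable boundary the
study leaves undefined), then flipped with a configurable noise
probability. This makes the ROC validation self-consistent by
construction: at zero label noise the threshold sweep must reach AUC = 1,
at noise 0.5 it must collapse to the null. Passing these checks shows the
prediction-and-scoring pipeline is internally correct; it says nothing
about how well the model predicts *real* follow-up outcomes, for which
the original clinical records (and the co-administered drugs the model
omits, e.g. oxaliplatin) would be required. The ROC itself classifies
tumor-free (the positive class) when the prediction falls below a
threshold, sweeping a 101-point uniform grid between the minimum and
maximum predictions plus one point above the maximum so the sweep closes
at the all-positive corner.

The regulatory-T comparison (`treg_pre_post()`) splits patients into high
and low pre-treatment T-reg groups (median split unless a threshold is
given — the study does not state its grouping threshold) and applies a
paired t-test to the pre/post difference per group; a degenerate group is
reported as empty rather than raised as an error, and an all-zero
difference vector reports p = 1.

## Worked example

```{r example, eval = FALSE}
params <- derive_params()          # 59 + 19 parameters, all-ones equilibrium
reg <- regimen()                   # 770/725/300 mg, 12 x 14-day cycles
traj <- simulate_tme(state_vector(), params, reg, horizon = 3285)
eval_table(traj)[, c("time_days", "C", "Tr", "total_cells")]
autoplot(traj, vars = c("C", "Tr", "Th", "total_cells"))

sens <- forward_sensitivity(params, c("delta_CLV5fu", "delta_CIr", "delta_5fuM"))
rank_parameters(sens, output = "C")
```

## Problem sizes

The experiment functions default to the sizes actually used throughout
the package's own analyses: nine-year horizons (3285 days) for
steady-state questions, treatment-plus-two-years (~900 days) for
sensitivity averaging, five-point multiplier grids for the parameter
scans, and cohorts of a few hundred synthetic patients for the ROC
studies. A full 16-parameter sensitivity ranking takes on the order of a
minute on a single core; individual nine-year simulations take a couple
of seconds.

## Known limitations

* Dimensionless trajectories only; mapping back to cells/cm³ requires the
  per-cluster dimensional anchors, which enter only through
  `tumor_scalars()`.
* The parameter set reproduces the *structure* and the calibrated
  efficiencies, not any particular fitted parameter table; numerical
  equality with trajectories produced from other parameterizations is not
  expected, and conclusions are therefore ordering- and shape-level.
* Single-compartment drug pools: no bolus/infusion distinction beyond the
  step-function schedule, no hepatic/renal compartments.
* Local forward sensitivity only — no global (Sobol/Morris) indices.
* The synthetic cohort emulates marginal shapes, not the covariance
  structure of real records (e.g. dose–size correlations are absent), so
  cohort-level tests exercise plumbing and self-consistency, not clinical
  realism.
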