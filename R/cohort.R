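#' Packaged smallest-tumor initial conditions (five immune clusters)
#'
#' Dimensionless initial conditions of the 14 microenvironment variables for
#' the patient with the smallest tumor in each of the five immune clusters.
#'
#' @return Tibble with column `cluster` and one column per baseline state
#'   variable.
#' @export
load_initial_conditions <- function() {
  path <- system.file("extdata", "table2_initial_conditions.csv",
                      package = "folfirisim", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, colClasses = "numeric"))
}

#' Packaged cohort treatment statistics
#'
#' Median and minimum prescribed doses per cycle (mg), cycle counts and
#' cycle lengths for the three FOLFIRI drugs.
#'
#' @return Tibble with columns `drug`, `median_mg`, `min_mg`, `n_cycles`,
#'   `cycle_length`.
#' @export
load_treatment_table <- function() {
  path <- system.file("extdata", "table3_treatment.csv",
                      package = "folfirisim", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path,
                                    colClasses = c("character", rep("numeric", 4))))
}

#' Cluster initial conditions
#'
#' @param cluster Cluster id in 1..5.
#' @param ic `"smallest"` for the packaged smallest-tumor values,
#'   `"steady"` for the untreated steady state (all ones, i.e. large
#'   tumors).
#' @return A 17-component [state_vector()] with zero drug levels.
#' @export
cluster_initial_conditions <- function(cluster, ic = c("smallest", "steady")) {
  ic <- match.arg(ic)
  if (!cluster %in% 1:5) stop("unknown cluster ", cluster, "; must be 1..5")
  if (ic == "steady") return(state_vector())
  tab <- load_initial_conditions()
  row <- tab[tab$cluster == cluster, BASELINE_STATE_NAMES, drop = FALSE]
  x <- stats::setNames(c(as.numeric(row[1, ]), 0, 0, 0), STATE_NAMES)
  validate_state(x)
  x
}

#' Tumor scalar densities from dimensions and necrosis
#'
#' Implements the density bookkeeping used to set dimensional anchors: tumor
#' size is longest x shortest dimension (cm^2); total cell density is
#' proportional to size, `TCD = alpha_dim * size / mean(size)`; necrotic
#' density `N = TCD * Np`; cancer density `C = (2/3) * TCD * (1 - Np)`
#' (cancer assumed twice the total immune cells); and total immune cells
#' `TIC = 0.5 * C`. With `Np = 0.1` the composition is exactly
#' `TIC : C : N = 0.3 : 0.6 : 0.1`.
#'
#' @param data Data frame with columns `longest_cm`, `shortest_cm`, `np`
#'   (necrosis fraction in `[0, 1]`).
#' @param cohort_mean_size Mean tumor size (cm^2) used as the proportionality
#'   anchor; defaults to the mean of `data`'s sizes.
#' @param alpha_dim Density scale (cells/cm^3, default `7.5e4`).
#' @return The input tibble with columns `size_cm2`, `TCD`, `N`, `C`, `TIC`
#'   appended (densities in cells/cm^3).
#' @export
tumor_scalars <- function(data, cohort_mean_size = NULL, alpha_dim = 7.5e4) {
  stopifnot(all(c("longest_cm", "shortest_cm", "np") %in% names(data)))
  if (any(data$longest_cm <= 0) || any(data$shortest_cm <= 0)) {
    stop("tumor dimensions must be positive")
  }
  if (any(data$np < 0 | data$np > 1)) stop("np must be in [0, 1]")
  size <- data$longest_cm * data$shortest_cm
  if (is.null(cohort_mean_size)) cohort_mean_size <- mean(size)
  stopifnot(cohort_mean_size > 0)
  tcd <- alpha_dim * size / cohort_mean_size
  dplyr::mutate(tibble::as_tibble(data),
                size_cm2 = size,
                TCD = tcd,
                N = tcd * data$np,
                C = (2 / 3) * tcd * (1 - data$np),
                TIC = 0.5 * (2 / 3) * tcd * (1 - data$np))
}

#' The 22 immune-cell labels carried in patient records
#'
#' Standard leukocyte signature labels (digital-cytometry convention). Only
#' the model's aggregated classes are used downstream; the full fractions
#' are carried for record realism.
#' @export
IMMUNE_CELL_TYPES <- c(
  "B_cells_naive", "B_cells_memory", "Plasma_cells",
  "T_cells_CD8", "T_cells_CD4_naive", "T_cells_CD4_memory_resting",
  "T_cells_CD4_memory_activated", "T_cells_follicular_helper",
  "T_cells_regulatory", "T_cells_gamma_delta",
  "NK_cells_resting", "NK_cells_activated",
  "Monocytes", "Macrophages_M0", "Macrophages_M1", "Macrophages_M2",
  "Dendritic_cells_resting", "Dendritic_cells_activated",
  "Mast_cells_resting", "Mast_cells_activated",
  "Eosinophils", "Neutrophils"
)

#' Default per-cluster centroid immune fractions
#'
#' Qualitatively anchored, non-measured defaults: cluster 3 has the highest
#' regulatory-T/helper-T ratio and cluster 2 the lowest; cluster 4 is
#' dendritic-cell rich and cluster 5 NK rich. Rows sum to 1.
#'
#' @return 5 x 22 matrix (rows: clusters, columns: [IMMUNE_CELL_TYPES]).
#' @export
default_cluster_centroids <- function() {
  base <- c(
    B_cells_naive = 0.06, B_cells_memory = 0.03, Plasma_cells = 0.06,
    T_cells_CD8 = 0.10, T_cells_CD4_naive = 0.04,
    T_cells_CD4_memory_resting = 0.14, T_cells_CD4_memory_activated = 0.03,
    T_cells_follicular_helper = 0.04, T_cells_regulatory = 0.05,
    T_cells_gamma_delta = 0.02, NK_cells_resting = 0.04,
    NK_cells_activated = 0.03, Monocytes = 0.04, Macrophages_M0 = 0.15,
    Macrophages_M1 = 0.06, Macrophages_M2 = 0.12,
    Dendritic_cells_resting = 0.02, Dendritic_cells_activated = 0.01,
    Mast_cells_resting = 0.04, Mast_cells_activated = 0.01,
    Eosinophils = 0.005, Neutrophils = 0.045
  )
  base <- base[IMMUNE_CELL_TYPES]
  tweak <- function(v, ...) {
    mult <- c(...)
    v[names(mult)] <- v[names(mult)] * mult
    v / sum(v)
  }
  m <- rbind(
    tweak(base),  # cluster 1: near-average profile
    tweak(base, T_cells_regulatory = 0.4, T_cells_CD4_memory_resting = 1.3,
          T_cells_CD4_memory_activated = 1.3),
    tweak(base, T_cells_regulatory = 2.2, T_cells_CD4_memory_resting = 0.7,
          T_cells_CD4_memory_activated = 0.7),
    tweak(base, Dendritic_cells_resting = 3, Dendritic_cells_activated = 3,
          Macrophages_M2 = 1.2),
    tweak(base, NK_cells_activated = 2, NK_cells_resting = 1.5,
          T_cells_CD8 = 1.2)
  )
  rownames(m) <- paste0("cluster", 1:5)
  m
}

#' Cohort-generation configuration
#'
#' @param dirichlet_concentration Total Dirichlet concentration around the
#'   cluster centroid (larger = tighter fractions).
#' @param size_median_cm,size_sdlog Log-normal parameters for the tumor's
#'   longest dimension (cm).
#' @param np_shape1,np_shape2 Beta parameters for the necrosis fraction
#'   (defaults give mean 0.1).
#' @param followup_range Days (after treatment start) within which the
#'   follow-up is drawn.
#' @param centroids Cluster centroid matrix
#'   ([default_cluster_centroids()]).
#' @return Named list of settings.
#' @export
cohort_config <- function(dirichlet_concentration = 150,
                          size_median_cm = 3, size_sdlog = 0.35,
                          np_shape1 = 2, np_shape2 = 18,
                          followup_range = c(200, 3285),
                          centroids = default_cluster_centroids()) {
  list(dirichlet_concentration = dirichlet_concentration,
       size_median_cm = size_median_cm, size_sdlog = size_sdlog,
       np_shape1 = np_shape1, np_shape2 = np_shape2,
       followup_range = followup_range, centroids = centroids)
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic patient cohort
#'
#' Emulates the statistical shape of the study records: 22 immune-cell
#' fractions drawn from a Dirichlet around the cluster centroid, log-normal
#' tumor dimensions, Beta-distributed necrosis fraction with mean 0.1,
#' prescribed doses uniform between the cohort minimum and twice the median,
#' and the standard 12 x 14-day cycle structure. Pure function of
#' `(n, cluster_mix, seed, config)`.
#'
#' @param n Number of patients.
#' @param cluster_mix Length-5 non-negative mixture over clusters (sums
#'   to 1).
#' @param seed Integer seed (required; generation is reproducible).
#' @param config A [cohort_config()].
#' @return Tibble, one row per patient: `patient_id`, `cluster`, the 22
#'   `frac_*` columns, `longest_cm`, `shortest_cm`, `np`, the regimen
#'   columns (`dose_5fu`, `dose_lv`, `dose_ir`, `n_cycles`, `cycle_length`,
#'   `start_day`), and `followup_day` (status is attached by
#'   [assign_followup()]).
#' @export
generate_cohort <- function(n, cluster_mix = rep(0.2, 5), seed,
                            config = cohort_config()) {
  stopifnot(n >= 1, length(cluster_mix) == 5, all(cluster_mix >= 0))
  if (abs(sum(cluster_mix) - 1) > 1e-9) stop("cluster_mix must sum to 1")
  if (missing(seed)) stop("an explicit seed is required")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  treat <- load_treatment_table()
  cl <- sample.int(5L, n, replace = TRUE, prob = cluster_mix)
  conc <- config$dirichlet_concentration
  fr <- matrix(NA_real_, n, length(IMMUNE_CELL_TYPES))
  for (k in 1:5) {
    idx <- which(cl == k)
    if (length(idx)) {
      fr[idx, ] <- rdirichlet(length(idx), conc * config$centroids[k, ])
    }
  }
  colnames(fr) <- paste0("frac_", IMMUNE_CELL_TYPES)
  longest <- stats::rlnorm(n, log(config$size_median_cm), config$size_sdlog)
  shortest <- longest * stats::runif(n, 0.4, 1)
  np <- stats::rbeta(n, config$np_shape1, config$np_shape2)
  dose_of <- function(drug) {
    row <- treat[treat$drug == drug, ]
    stats::runif(n, row$min_mg, 2 * row$median_mg)
  }
  fu_range <- config$followup_range
  tibble::tibble(
    patient_id = sprintf("SYN-%04d", seq_len(n)),
    cluster = cl
  ) |>
    dplyr::bind_cols(tibble::as_tibble(fr)) |>
    dplyr::mutate(
      longest_cm = longest,
      shortest_cm = shortest,
      np = np,
      dose_5fu = dose_of("fu"),
      dose_lv = dose_of("lv"),
      dose_ir = dose_of("ir"),
      n_cycles = treat$n_cycles[1],
      cycle_length = treat$cycle_length[1],
      start_day = 0,
      followup_day = stats::runif(n, fu_range[1], fu_range[2])
    )
}

#' Regimen of one cohort row
#'
#' @param record One-row data frame with the regimen columns of
#'   [generate_cohort()].
#' @return A [regimen()].
#' @export
record_regimen <- function(record) {
  stopifnot(nrow(record) == 1L)
  regimen(dose_5fu = record$dose_5fu, dose_lv = record$dose_lv,
          dose_ir = record$dose_ir, n_cycles = record$n_cycles,
          cycle_length = record$cycle_length, start_day = record$start_day)
}

#' Attach model-generated follow-up labels to a cohort
#'
#' Ground-truth status is derived from the simulated cancer trajectory of
#' the record's cluster via the size-dependent rule: a patient is
#' `tumor_free` when the cancer density at follow-up is below the initial
#' value (small/medium tumors) or below half the initial value (large
#' tumors, initial dimensionless cancer `>= size_cutoff`). Each label is
#' then flipped independently with probability `label_noise`. Records whose
#' follow-up precedes the end of treatment are flagged `excluded`.
#'
#' @param cohort Cohort tibble ([generate_cohort()]).
#' @param trajectories List of `folfiri_trajectory` objects indexed by
#'   cluster (1..5, or a single trajectory used for all).
#' @param label_noise Flip probability in `[0, 0.5]`.
#' @param seed Integer seed for the label noise.
#' @param size_cutoff Initial dimensionless cancer density at or above which
#'   a tumor counts as large (default 0.5).
#' @return The cohort with columns `predicted_cancer`, `status`
#'   (`"tumor_free"` / `"with_tumor"`), and `excluded` appended.
#' @export
assign_followup <- function(cohort, trajectories, label_noise = 0, seed = 1,
                            size_cutoff = 0.5) {
  stopifnot(label_noise >= 0, label_noise <= 1)
  get_traj <- function(k) {
    if (inherits(trajectories, "folfiri_trajectory")) return(trajectories)
    trajectories[[k]]
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  flips <- stats::runif(nrow(cohort)) < label_noise

  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    rec <- cohort[i, ]
    traj <- get_traj(rec$cluster)
    if (rec$followup_day > max(traj$time_days)) {
      stop("follow-up day ", rec$followup_day,
           " outside simulated horizon for cluster ", rec$cluster)
    }
    c0 <- state_at(traj, 0, "C")
    pred <- state_at(traj, rec$followup_day, "C")
    cutoff <- if (c0 >= size_cutoff) c0 / 2 else c0
    truth_free <- pred < cutoff
    status <- if (xor(truth_free, flips[i])) "tumor_free" else "with_tumor"
    end_day <- treatment_end_day(record_regimen(rec))
    tibble::tibble(predicted_cancer = pred, status = status,
                   excluded = rec$followup_day < end_day)
  }) |> purrr::list_rbind()
  dplyr::bind_cols(cohort, rows)
}
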