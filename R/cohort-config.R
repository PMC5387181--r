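#' Configuration for the synthetic neonatal cohort generator
#'
#' Defines the study conditions the generator emulates: cohort size and
#' repeated scans, the parcellation size, the raw-density range and its decline
#' with post-menstrual age (PMA) at scan, maturational slopes of the
#' microstructural edge weights, and the gestational-age (GA) at birth effect
#' that is confined to designated "local" edges while sparing a designated
#' "core".
#'
#' Defaults reproduce the structure of a preterm/term neonatal MRI cohort:
#' 65 infants of whom 8 are scanned twice, GA at birth spanning roughly 24-41
#' weeks (median near 33), scans up to 46 weeks PMA, raw network density
#' falling from about 0.88 in the youngest to about 0.56 in the oldest scans,
#' FA and NDI edge weights rising and the coherence weight 1-ODI falling with
#' PMA, and covariate frequencies matching the clinical table of such a cohort
#' (41/65 male, 19/65 small for gestational age, 22/65 with more than two days
#' of respiratory support, 7/65 necrotising enterocolitis, 18/65 twins).
#'
#' @param n_subjects Number of subjects.
#' @param n_repeat_scans Number of subjects scanned a second time.
#' @param node_count Number of parcellation regions (default 91).
#' @param target_raw_density_range Length-2 numeric; approximate raw network
#'   density (after the 5-streamline filter) at the youngest and oldest PMA.
#' @param age_effect_density Logit-scale slope (per week of PMA) of the
#'   presence probability of non-backbone edges; negative so density falls
#'   with age. If `NULL` it is solved from `target_raw_density_range` and
#'   `pma_range`.
#' @param age_effect_fa,age_effect_ndi Linear slope of edge FA / NDI per week
#'   of PMA.
#' @param age_effect_odi_c Linear slope of edge coherence (1-ODI) per week of
#'   PMA; negative, since dispersion rises as crossing fibres develop.
#' @param ga_effect_local_ndi Additional NDI slope per week of GA at birth,
#'   applied only to edges flagged "local" in the latent design.
#' @param core_fraction_of_edges Fraction of all possible edges flagged as
#'   "core" in the latent design (strongest backbone edges; they carry no GA
#'   effect).
#' @param edge_noise_sd Standard deviation of independent edge-level noise on
#'   each microstructure weight.
#' @param ga_range,pma_range Length-2 bounds (weeks) for GA at birth and PMA
#'   at scan.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 65,
                          n_repeat_scans = 8,
                          node_count = 91,
                          target_raw_density_range = c(0.56, 0.88),
                          age_effect_density = NULL,
                          age_effect_fa = 0.008,
                          age_effect_ndi = 0.010,
                          age_effect_odi_c = -0.007,
                          ga_effect_local_ndi = 0.008,
                          core_fraction_of_edges = 0.10,
                          edge_noise_sd = 0.03,
                          ga_range = c(24.3, 41.1),
                          pma_range = c(25, 46),
                          seed = 1L) {
  cfg <- structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_repeat_scans = as.integer(n_repeat_scans),
      node_count = as.integer(node_count),
      target_raw_density_range = as.numeric(target_raw_density_range),
      age_effect_density = age_effect_density,
      age_effect_fa = age_effect_fa,
      age_effect_ndi = age_effect_ndi,
      age_effect_odi_c = age_effect_odi_c,
      ga_effect_local_ndi = ga_effect_local_ndi,
      core_fraction_of_edges = core_fraction_of_edges,
      edge_noise_sd = edge_noise_sd,
      ga_range = as.numeric(ga_range),
      pma_range = as.numeric(pma_range),
      # cohort covariate frequencies (counts over cohort size in the emulated
      # clinical table): male, SGA, respiratory support, NEC, twins
      covariate_rates = c(male = 41 / 65, sga = 19 / 65, resp_support = 22 / 65,
                          nec = 7 / 65, twin = 18 / 65),
      # additive covariate effects on NDI so mixed-model adjustment is testable
      covariate_effects_ndi = c(male = 0.005, sga = -0.010,
                                resp_support = -0.010, nec = -0.010),
      # baseline microstructure (edge-level means) and scan-level intercept sds
      base_fa = 0.25, base_ndi = 0.40, base_odi = 0.35,
      scan_noise_sd = c(fa = 0.035, ndi = 0.040, odi = 0.025, density = 1.0),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  r <- cfg$target_raw_density_range
  eff <- c(cfg$age_effect_fa, cfg$age_effect_ndi, cfg$age_effect_odi_c,
           cfg$ga_effect_local_ndi, cfg$age_effect_density %||% 0)
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (cfg$n_repeat_scans < 0 || cfg$n_repeat_scans > cfg$n_subjects) {
    stop("n_repeat_scans must lie in [0, n_subjects]", call. = FALSE)
  }
  if (cfg$node_count < 2) stop("node_count must be >= 2", call. = FALSE)
  if (length(r) != 2 || r[1] >= r[2] || r[1] <= 0 || r[2] > 1) {
    stop("target_raw_density_range must be increasing within (0, 1]", call. = FALSE)
  }
  if (r[1] < 0.5) {
    stop("target_raw_density_range[1] < 0.5: the cost sweep requires every ",
         "raw network density to be at least 0.50 (sweep upper bound)",
         call. = FALSE)
  }
  if (!all(is.finite(eff))) stop("all effect sizes must be finite", call. = FALSE)
  if (cfg$core_fraction_of_edges <= 0 || cfg$core_fraction_of_edges >= 1) {
    stop("core_fraction_of_edges must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$core_fraction_of_edges >= r[1]) {
    stop("core_fraction_of_edges must be smaller than the backbone fraction ",
         "(target_raw_density_range[1])", call. = FALSE)
  }
  if (cfg$edge_noise_sd < 0) stop("edge_noise_sd must be >= 0", call. = FALSE)
  if (diff(cfg$ga_range) <= 0 || diff(cfg$pma_range) <= 0) {
    stop("ga_range and pma_range must be increasing", call. = FALSE)
  }
  cfg
}

# survival probability of a non-backbone edge count under the >=5 filter;
# counts are 1 + NegBin(size = 2, mu = 9)
nonbackbone_survival <- function() 1 - stats::pnbinom(3, size = 2, mu = 9)

# logistic presence model for non-backbone edges: p(pma) = plogis(a + b (pma -
# mid)). Solved so the filtered density hits the target range at the PMA
# bounds; b can be overridden via age_effect_density.
presence_model <- function(cfg) {
  r <- cfg$target_raw_density_range
  surv <- nonbackbone_survival()
  span <- 1 - r[1]
  p_hi <- clamp((r[2] - r[1]) / (span * surv), 0.02, 0.98)
  p_lo <- 0.05
  mid <- mean(cfg$pma_range)
  b_solved <- (stats::qlogis(p_lo) - stats::qlogis(p_hi)) / diff(cfg$pma_range)
  b <- cfg$age_effect_density %||% b_solved
  a <- stats::qlogis(p_hi) - b * (cfg$pma_range[1] - mid)
  list(a = a, b = b, mid = mid, backbone_fraction = r[1])
}

#' Latent edge-level design of a synthetic cohort
#'
#' The ground-truth table behind [simulate_cohort()]: the partition of all
#' possible edges into "core" (strong backbone edges that carry no GA-at-birth
#' effect) and "local" (everything else; their NDI carries the GA effect),
#' whether each edge belongs to the always-present backbone, its expected
#' streamline count, and its baseline microstructure. Deterministic given the
#' config seed; it is the oracle for parameter-recovery tests.
#'
#' The core size is `round(core_fraction_of_edges * M)` with round-half-up,
#' where `M` is the number of possible edges.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per possible edge: `i, j, backbone, core,
#'   ga_effect, mu_count, base_fa, base_ndi, base_odi` and the per-week NDI
#'   slope for GA at birth (`ga_slope_ndi`, zero on core edges).
#' @export
latent_design <- function(config) {
  config <- validate_cohort_config(config)
  n <- config$node_count
  m <- n_possible_edges(n)
  pairs <- edge_pairs(n)
  pm <- presence_model(config)
  n_backbone <- min(m, ceiling(pm$backbone_fraction * m))
  n_core <- round_half_up(config$core_fraction_of_edges * m)

  withr::with_seed(config$seed, {
    # random edge ordering: first n_core are core, first n_backbone backbone
    ord <- sample.int(m)
    rank <- integer(m)
    rank[ord] <- seq_len(m)
    backbone <- rank <= n_backbone
    core <- rank <= n_core
    # expected streamline counts decline log-linearly across backbone ranks so
    # count-based thresholds track the latent ordering; non-backbone edges
    # share a weak long-tailed count model
    mu <- rep(9, m)
    if (n_backbone > 1) {
      frac <- (rank[backbone] - 1) / (n_backbone - 1)
      mu[backbone] <- exp(log(250) + frac * (log(8) - log(250)))
    } else if (n_backbone == 1) {
      mu[backbone] <- 250
    }
    base_fa <- clamp(stats::rnorm(m, config$base_fa, 0.05), 0.05, 0.95)
    base_ndi <- clamp(stats::rnorm(m, config$base_ndi, 0.05), 0.05, 0.95)
    base_odi <- clamp(stats::rnorm(m, config$base_odi, 0.05), 0.05, 0.95)
  })

  tibble::tibble(
    i = pairs$i, j = pairs$j,
    backbone = backbone, core = core, ga_effect = !core,
    mu_count = mu,
    base_fa = base_fa, base_ndi = base_ndi, base_odi = base_odi,
    ga_slope_ndi = ifelse(core, 0, config$ga_effect_local_ndi)
  )
}
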