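#' Simulate a synthetic neonatal connectome cohort
#'
#' Generates a seeded cohort of multi-weight connectomes with the metadata,
#' repeated-scan, age and prematurity structure the downstream analysis
#' assumes. The latent model (see [latent_design()]):
#'
#' * a backbone of always-present edges (counts >= 5) guarantees raw density
#'   above 0.5 so the full cost sweep is feasible; non-backbone edges are
#'   present with a logistic probability that declines with PMA at scan, so
#'   raw density falls with age;
#' * edge FA and NDI rise and coherence 1-ODI falls linearly with PMA, with
#'   independent edge noise and a shared scan-level intercept;
#' * NDI on "local" edges additionally rises with GA at birth; "core" edges
#'   carry no GA effect;
#' * binary covariates (sex, SGA, respiratory support, NEC) have small
#'   additive NDI effects, and respiratory support is more frequent at low GA,
#'   so covariate adjustment is non-vacuous.
#'
#' @param config A [cohort_config()].
#' @return A tibble of class `neoconn_cohort`, one row per scan, with columns
#'   `subject_id, scan_id, ga_birth, pma_scan, sex, sga, resp_support, nec,
#'   twin` and a list-column `connectome` of [multiweight_connectome()]
#'   objects. `n_subjects + n_repeat_scans` rows in total.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 4, n_repeat_scans = 1,
#'                                         node_count = 20, seed = 42))
#' nrow(cohort)
simulate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  design <- latent_design(config)
  meta <- withr::with_seed(config$seed + 1L, simulate_scan_table(config))
  pm <- presence_model(config)

  connectomes <- withr::with_seed(config$seed + 2L, {
    lapply(seq_len(nrow(meta)), function(k) {
      simulate_connectome(config, design, pm,
                          ga = meta$ga_birth[k], pma = meta$pma_scan[k],
                          male = meta$sex[k] == "M", sga = meta$sga[k],
                          resp = meta$resp_support[k], nec = meta$nec[k],
                          scan_id = meta$scan_id[k])
    })
  })
  meta$connectome <- connectomes
  class(meta) <- c("neoconn_cohort", class(meta))
  attr(meta, "config") <- config
  meta
}

# subject/scan metadata: ages, covariates, repeated scans
simulate_scan_table <- function(config) {
  n <- config$n_subjects
  rates <- config$covariate_rates
  ga <- stats::runif(n, config$ga_range[1], config$ga_range[2])
  sex <- ifelse(stats::rbinom(n, 1, rates["male"]) == 1, "M", "F")
  sga <- stats::rbinom(n, 1, rates["sga"]) == 1
  nec <- stats::rbinom(n, 1, rates["nec"]) == 1
  twin <- stats::rbinom(n, 1, rates["twin"]) == 1
  # respiratory support more likely with lower GA (logistic in centred GA)
  p_resp <- stats::plogis(stats::qlogis(rates["resp_support"]) - 0.25 * (ga - 33))
  resp <- stats::rbinom(n, 1, p_resp) == 1

  pma_max <- config$pma_range[2]
  delay <- stats::runif(n, 0.7, pmin(13, pma_max - 0.1 - ga))
  pma <- pmax(ga + delay, config$pma_range[1])

  subject_id <- sprintf("sub-%03d", seq_len(n))
  meta <- tibble::tibble(
    subject_id = subject_id,
    scan_id = paste0(subject_id, "_ses-1"),
    ga_birth = ga, pma_scan = pma,
    sex = factor(sex, levels = c("F", "M")),
    sga = sga, resp_support = resp, nec = nec, twin = twin
  )

  if (config$n_repeat_scans > 0) {
    # the most preterm infants are rescanned, mirroring clinical follow-up
    idx <- order(ga)[seq_len(config$n_repeat_scans)]
    gap <- stats::runif(length(idx), 3.4, 8.7)
    pma2 <- pmin(pma[idx] + gap, pma_max - 0.05)
    second <- meta[idx, ]
    second$scan_id <- paste0(second$subject_id, "_ses-2")
    second$pma_scan <- pma2
    meta <- dplyr::bind_rows(meta, second)
  }
  dplyr::arrange(meta, .data$subject_id, .data$scan_id)
}

simulate_connectome <- function(config, design, pm, ga, pma, male, sga, resp,
                                nec, scan_id) {
  m <- nrow(design)
  n <- config$node_count
  mid_pma <- pm$mid
  # edge presence: backbone always; others age-dependent logistic with a
  # scan-level intercept so cohort density-age correlations are noisy rather
  # than deterministic
  u_dens <- stats::rnorm(1, 0, config$scan_noise_sd["density"])
  p_edge <- stats::plogis(pm$a + pm$b * (pma - mid_pma) + u_dens)
  present <- design$backbone | (stats::runif(m) < p_edge)

  counts <- integer(m)
  bb <- design$backbone
  counts[bb] <- 5L + stats::rnbinom(sum(bb), size = 8, mu = design$mu_count[bb])
  other <- present & !bb
  counts[other] <- 1L + stats::rnbinom(sum(other), size = 2, mu = 9)

  filtered_density <- mean(counts >= 5)
  if (filtered_density < 0.5) {
    stop(sprintf(
      paste0("scan %s: raw network density %.3f violates the cost-sweep ",
             "precondition (raw density must be >= 0.50, the sweep's upper ",
             "density bound); adjust target_raw_density_range"),
      scan_id, filtered_density), call. = FALSE)
  }

  eff <- config$covariate_effects_ndi
  cov_shift <- eff["male"] * male + eff["sga"] * sga +
    eff["resp_support"] * resp + eff["nec"] * nec
  u_fa <- stats::rnorm(1, 0, config$scan_noise_sd["fa"])
  u_ndi <- stats::rnorm(1, 0, config$scan_noise_sd["ndi"])
  u_odi <- stats::rnorm(1, 0, config$scan_noise_sd["odi"])
  sd_e <- config$edge_noise_sd

  fa <- design$base_fa + config$age_effect_fa * (pma - mid_pma) + u_fa +
    stats::rnorm(m, 0, sd_e)
  ndi <- design$base_ndi + config$age_effect_ndi * (pma - mid_pma) +
    design$ga_slope_ndi * (ga - 33) + cov_shift + u_ndi +
    stats::rnorm(m, 0, sd_e)
  # ODI stored as dispersion: coherence slope enters with opposite sign
  odi <- design$base_odi - config$age_effect_odi_c * (pma - mid_pma) + u_odi +
    stats::rnorm(m, 0, sd_e)

  fa <- clamp(fa, 0.01, 0.99); ndi <- clamp(ndi, 0.01, 0.99)
  odi <- clamp(odi, 0.01, 0.99)
  fa[counts == 0] <- NA_real_
  ndi[counts == 0] <- NA_real_
  odi[counts == 0] <- NA_real_

  multiweight_connectome(
    counts = sym_from_ut(counts, n),
    fa = sym_from_ut(fa, n, diag_value = NA_real_),
    ndi = sym_from_ut(ndi, n, diag_value = NA_real_),
    odi = sym_from_ut(odi, n, diag_value = NA_real_),
    node_labels = default_node_labels(n)
  )
}

#' Calibration cohort with known signal and null edges
#'
#' A targeted simulator for calibrating the edge-wise statistics: single-scan
#' subjects drawn from the same subject model as [simulate_cohort()], and a
#' fixed edge mask in which a known subset of edges carries a GA-at-birth
#' effect on NDI while the rest are pure noise. Used to estimate the empirical
#' false-discovery proportion of [edgewise_association()].
#'
#' @param n_scans Number of single-scan subjects.
#' @param n_signal,n_null Numbers of signal and null edges in the mask.
#' @param ga_effect NDI slope per week of GA at birth on signal edges.
#' @param edge_noise_sd,scan_noise_sd Edge-level and scan-level noise sds.
#' @param seed Integer seed.
#' @return A list with elements `cohort` (a `neoconn_cohort` tibble), `grid`
#'   (logical edge mask matrix) and `truth` (tibble `i, j, signal`).
#' @export
simulate_edgewise_calibration <- function(n_scans = 65, n_signal = 100,
                                          n_null = 400, ga_effect = 0.010,
                                          edge_noise_sd = 0.03,
                                          scan_noise_sd = 0.02, seed = 1L) {
  m_need <- n_signal + n_null
  n_nodes <- 2
  while (n_possible_edges(n_nodes) < m_need) n_nodes <- n_nodes + 1
  m <- n_possible_edges(n_nodes)
  base_cfg <- cohort_config(n_subjects = n_scans, n_repeat_scans = 0,
                            seed = seed)

  withr::with_seed(seed, {
    meta <- simulate_scan_table(base_cfg)
    sel <- sample.int(m, m_need)
    signal <- sel[seq_len(n_signal)]
    base_ndi <- clamp(stats::rnorm(m, 0.40, 0.05), 0.05, 0.95)
    conns <- lapply(seq_len(nrow(meta)), function(k) {
      ga <- meta$ga_birth[k]; pma <- meta$pma_scan[k]
      ndi <- base_ndi + 0.010 * (pma - 35.5) +
        stats::rnorm(1, 0, scan_noise_sd) + stats::rnorm(m, 0, edge_noise_sd)
      ndi[signal] <- ndi[signal] + ga_effect * (ga - 33)
      ndi <- clamp(ndi, 0.01, 0.99)
      cnt <- rep(10L, m)
      multiweight_connectome(
        counts = sym_from_ut(cnt, n_nodes),
        fa = sym_from_ut(clamp(stats::rnorm(m, 0.3, edge_noise_sd), 0.01, 0.99),
                         n_nodes, NA_real_),
        ndi = sym_from_ut(ndi, n_nodes, NA_real_),
        odi = sym_from_ut(clamp(stats::rnorm(m, 0.35, edge_noise_sd), 0.01, 0.99),
                          n_nodes, NA_real_)
      )
    })
  })
  meta$connectome <- conns
  class(meta) <- c("neoconn_cohort", class(meta))

  in_mask <- logical(m)
  in_mask[sel] <- TRUE
  grid <- sym_from_ut(in_mask, n_nodes) > 0
  pairs <- edge_pairs(n_nodes)
  truth <- tibble::tibble(i = pairs$i[sel], j = pairs$j[sel],
                          signal = sel %in% signal)
  list(cohort = meta, grid = grid, truth = truth)
}
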