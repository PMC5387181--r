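# Synthetic cohort generator: determinism, invariants, latent design.

test_that("cohort has the configured number of scans and valid records", {
  co <- small_cohort(n_subjects = 6, n_repeat = 2, nodes = 20, seed = 5)
  expect_equal(nrow(co), 8)
  expect_equal(length(unique(co$subject_id)), 6)
  expect_equal(anyDuplicated(co$scan_id), 0L)
  expect_true(all(co$pma_scan >= co$ga_birth))
  expect_true(all(co$ga_birth >= 24 & co$ga_birth <= 42))
  expect_true(all(co$pma_scan >= 25 & co$pma_scan <= 46))
  # repeated scans share subject metadata
  reps <- co |> dplyr::count(subject_id) |> dplyr::filter(n == 2)
  expect_equal(nrow(reps), 2)
})

test_that("connectomes satisfy the multi-weight invariants", {
  co <- small_cohort(n_subjects = 2, n_repeat = 0, nodes = 25, seed = 9)
  for (cn in co$connectome) {
    expect_identical(cn$counts, t(cn$counts))
    expect_true(all(diag(cn$counts) == 0))
    expect_true(all(cn$counts >= 0))
    for (nm in c("fa", "ndi", "odi")) {
      v <- cn[[nm]][cn$counts > 0]
      expect_false(anyNA(v))
      expect_true(all(v >= 0 & v <= 1))
      expect_true(all(is.na(cn[[nm]][cn$counts == 0])))
    }
  }
})

test_that("a single-subject config yields one full-size connectome", {
  co <- simulate_cohort(cohort_config(n_subjects = 1, n_repeat_scans = 0))
  expect_equal(nrow(co), 1)
  expect_equal(dim(co$connectome[[1]]$counts), c(91, 91))
})

test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(n_subjects = 4, n_repeat_scans = 1, node_count = 15,
                       seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$ga_birth, b$ga_birth)
  expect_identical(a$connectome, b$connectome)
  c2 <- simulate_cohort(cohort_config(n_subjects = 4, n_repeat_scans = 1,
                                      node_count = 15, seed = 78))
  expect_false(identical(a$connectome, c2$connectome))
})

test_that("raw density exceeds 0.5 everywhere and the filter is exercised", {
  co <- small_cohort(n_subjects = 5, n_repeat = 0, nodes = 40, seed = 2)
  dens <- vapply(co$connectome,
                 function(cn) network_density(build_network(cn, "BINARY")),
                 numeric(1))
  expect_true(all(dens >= 0.5))
  # some positive-count edges fall below the 5-streamline floor
  sub5 <- vapply(co$connectome, function(cn) {
    v <- cn$counts[upper.tri(cn$counts)]
    sum(v > 0 & v < 5)
  }, numeric(1))
  expect_true(all(sub5 > 0))
})

test_that("invalid configs are rejected with informative errors", {
  expect_error(cohort_config(n_repeat_scans = 10, n_subjects = 5),
               "n_repeat_scans")
  expect_error(cohort_config(core_fraction_of_edges = 0), "core_fraction")
  expect_error(cohort_config(target_raw_density_range = c(0.3, 0.9)),
               "cost sweep")
  expect_error(cohort_config(age_effect_ndi = Inf), "finite")
})

test_that("latent design partitions edges into core and local", {
  cfg <- cohort_config(seed = 4)
  des <- latent_design(cfg)
  m <- n_possible_edges(91)
  expect_equal(nrow(des), m)
  # round-half-up of 0.1 * 4095
  expect_equal(sum(des$core), 410)
  expect_true(all(des$core == !des$ga_effect))     # partition property
  expect_identical(des, latent_design(cfg))        # deterministic
  expect_true(all(des$ga_slope_ndi[des$core] == 0))
  expect_true(all(des$ga_slope_ndi[!des$core] > 0))
})

test_that("cohort emulates the study's density and NDI age trends", {
  # sign checks with p < 0.01 across a handful of replicate seeds; the full
  # 100-replicate version lives in the acceptance suite
  for (seed in 1:3) {
    co <- simulate_cohort(cohort_config(seed = seed))
    dens <- vapply(co$connectome,
                   function(cn) network_density(build_network(cn, "BINARY")),
                   numeric(1))
    ndi <- vapply(co$connectome,
                  function(cn) median_connectivity(build_network(cn, "NDI")),
                  numeric(1))
    ct_d <- suppressWarnings(cor.test(dens, co$pma_scan, method = "spearman"))
    ct_n <- suppressWarnings(cor.test(ndi, co$pma_scan, method = "spearman"))
    expect_lt(ct_d$estimate, 0)
    expect_gt(ct_n$estimate, 0)
    expect_lt(ct_d$p.value, 0.01)
    expect_lt(ct_n$p.value, 0.01)
    expect_true(all(dens >= 0.5 & dens <= 0.95))
  }
})

test_that("calibration simulator marks signal and null edges as designed", {
  sim <- simulate_edgewise_calibration(n_scans = 30, n_signal = 10,
                                       n_null = 40, seed = 3)
  expect_equal(nrow(sim$cohort), 30)
  expect_equal(sum(sim$truth$signal), 10)
  expect_equal(sum(sim$grid[upper.tri(sim$grid)]), 50)
  sim2 <- simulate_edgewise_calibration(n_scans = 30, n_signal = 10,
                                        n_null = 40, seed = 3)
  expect_identical(sim$cohort$connectome, sim2$cohort$connectome)
})
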