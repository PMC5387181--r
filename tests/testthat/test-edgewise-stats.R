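# Minimum grid and edge-wise statistics: masks, intersection, mixed-effects
# residualisation, partial Spearman, BH-FDR.

test_that("subject masks hold round(0.3 * 4095) edges on the 91-node atlas", {
  co <- simulate_cohort(cohort_config(n_subjects = 1, n_repeat_scans = 0,
                                      seed = 13))
  m <- subject_mask(co$connectome[[1]])
  expect_identical(m, t(m))
  expect_true(all(diag(m) == FALSE))
  expect_equal(sum(m[upper.tri(m)]), 1229)    # round-half-up of 1228.5
  expect_lte(abs(sum(m[upper.tri(m)]) / 4095 - 0.3), 1 / 4095)
  # d = raw density keeps every raw edge
  raw <- build_network(co$connectome[[1]], "BINARY")
  m_all <- subject_mask(co$connectome[[1]], d = network_density(raw))
  expect_equal(sum(m_all[upper.tri(m_all)]), n_edges(raw))
})

test_that("the minimum grid is the intersection of the masks", {
  mk <- function(idx, n = 4) {
    m <- matrix(FALSE, n, n)
    m[idx] <- TRUE
    m | t(m)
  }
  a <- mk(cbind(c(1, 1, 2), c(2, 3, 3)))
  b <- mk(cbind(c(1, 2, 2), c(3, 3, 4)))
  g <- minimum_grid(list(a, b))
  expect_equal(sum(g[upper.tri(g)]), 2)
  expect_true(g[1, 3] && g[2, 3])
  expect_equal(unclass(minimum_grid(list(a, a)))[], a[],
               ignore_attr = TRUE)
  expect_warning(minimum_grid(list(a, mk(cbind(2, 4)))), "empty")
  expect_error(minimum_grid(list(a, matrix(FALSE, 5, 5))), "node set")
  # grid is a subset of every source mask on simulated cohorts
  co <- small_cohort(n_subjects = 5, n_repeat = 1, nodes = 30, seed = 17)
  masks <- lapply(co$connectome, subject_mask)
  g2 <- minimum_grid(masks)
  for (mm in masks) expect_true(all(mm[unclass(g2)]))
})

test_that("residualisation reduces to OLS for single scans", {
  withr::with_seed(5, {
    y <- rnorm(20)
    expect_equal(lme_residualize(y), y - mean(y), tolerance = 1e-12)
    x <- rnorm(20)
    r <- lme_residualize(y, data.frame(x = x))
    expect_equal(r, unname(resid(lm(y ~ x))), tolerance = 1e-10)
    # covariate equal to the outcome leaves ~zero residuals
    expect_lt(max(abs(lme_residualize(y, data.frame(z = y)))), 1e-10)
  })
  expect_error(lme_residualize(rnorm(10), data.frame(a = 1:10, b = 2 * (1:10))),
               "collinear")
})

test_that("the random-intercept fit recovers known variance structure", {
  # subjects with two scans, known intercept sd 1 and residual sd 0.5
  withr::with_seed(99, {
    est <- replicate(25, {
      ns <- 150
      subj <- rep(seq_len(ns), each = 2)
      u <- rnorm(ns, 0, 1)
      x <- rnorm(2 * ns)
      y <- 2 + 0.5 * x + u[subj] + rnorm(2 * ns, 0, 0.5)
      X <- stats::model.matrix(~x)
      fit <- neoconn:::lme_fit(y, X, subj)
      sqrt(unlist(lme4::VarCorr(fit))[1])
    })
  })
  expect_lt(abs(mean(est) - 1), 0.15)
})

test_that("marginal residuals remove fixed effects under repeated measures", {
  withr::with_seed(42, {
    subj <- rep(1:20, each = 2)
    x <- rnorm(40)
    u <- rnorm(20, 0, 0.8)
    y <- 1 + 2 * x + u[subj] + rnorm(40, 0.3)
    r <- lme_residualize(y, data.frame(x = x), subj)
    # residuals no longer carry the x effect
    expect_lt(abs(coef(lm(r ~ x))[2]), 0.2)
  })
})

test_that("partial Spearman hits the rank-correlation limits", {
  x <- 1:12
  expect_equal(partial_spearman(x, exp(x / 3))$rho, 1)
  expect_equal(partial_spearman(x, -x^3)$rho, -1)
  expect_error(partial_spearman(x, rep(1, 12)), "constant")
  expect_error(partial_spearman(1:4, 1:4), "at least 5")
})

test_that("partial Spearman is invariant under monotone transforms", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      x <- rnorm(30); y <- rnorm(30)
      r0 <- partial_spearman(x, y)$rho
      expect_equal(partial_spearman(exp(x), y)$rho, r0, tolerance = 1e-12)
      expect_equal(partial_spearman(x, y^3)$rho, r0, tolerance = 1e-12)
    }
  })
})

test_that("the t-approximation is calibrated under the null", {
  # independent x, y at the study's scan count; rejection rate ~ alpha
  withr::with_seed(7, {
    n_rep <- 2000
    p <- vapply(seq_len(n_rep), function(k) {
      partial_spearman(rnorm(65), rnorm(65))$p_value
    }, numeric(1))
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("permutation p-values broadly agree with the approximation", {
  withr::with_seed(3, {
    x <- rnorm(40); y <- 0.5 * x + rnorm(40)
    pa <- partial_spearman(x, y)$p_value
    pp <- partial_spearman(x, y, p_method = "permutation", n_perm = 1999,
                           seed = 11)$p_value
    expect_lt(abs(log10(max(pa, 5e-4)) - log10(max(pp, 5e-4))), 1)
  })
})

test_that("BH correction follows the step-up rule", {
  r <- fdr_bh(c(0.001, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(r$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(fdr_bh(rep(1, 5))$significant == FALSE))
  expect_true(fdr_bh(0.04)$significant)
  expect_true(all(r$q_value >= r$p_value))
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH agrees with a brute-force step-up evaluation", {
  bf_bh <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    thresh <- which(p[ord] <= q * seq_len(m) / m)
    rej <- logical(m)
    if (length(thresh) > 0) rej[ord[seq_len(max(thresh))]] <- TRUE
    rej
  }
  withr::with_seed(77, {
    for (rep in 1:50) {
      p <- runif(sample(1:6, 1))
      expect_identical(fdr_bh(p, 0.05)$significant, bf_bh(p, 0.05))
    }
  })
})

test_that("edgewise association on a designed grid finds the signal edges", {
  sim <- simulate_edgewise_calibration(n_scans = 40, n_signal = 10,
                                       n_null = 90, ga_effect = 0.012,
                                       seed = 21)
  es <- edgewise_association(sim$cohort, sim$grid, "NDI", "ga_birth")
  expect_equal(nrow(es), 100)
  key <- paste(es$i, es$j)
  sig_truth <- paste(sim$truth$i, sim$truth$j)[sim$truth$signal]
  hits <- es$significant & es$rho > 0
  expect_gt(mean(hits[key %in% sig_truth]), 0.5)
  # reproducible given the seed
  es2 <- edgewise_association(sim$cohort, sim$grid, "NDI", "ga_birth")
  expect_identical(es$q_value, es2$q_value)
})

test_that("a single-edge grid reduces to q = p", {
  sim <- simulate_edgewise_calibration(n_scans = 20, n_signal = 1, n_null = 0,
                                       seed = 2)
  es <- edgewise_association(sim$cohort, sim$grid, "NDI", "ga_birth")
  expect_equal(nrow(es), 1)
  expect_equal(es$q_value, es$p_value)
})

test_that("edgewise matches per-edge partial Spearman on repeated measures", {
  co <- small_cohort(n_subjects = 12, n_repeat = 3, nodes = 15, seed = 61)
  masks <- lapply(co$connectome, subject_mask)
  g <- minimum_grid(masks)
  es <- edgewise_association(co, g, "NDI", "ga_birth")
  covs <- data.frame(sex = as.integer(co$sex == "M"),
                     sga = as.integer(co$sga),
                     resp_support = as.integer(co$resp_support),
                     nec = as.integer(co$nec),
                     other_age = co$pma_scan)
  for (row in c(1, nrow(es))) {
    y <- vapply(co$connectome, function(cn) cn$ndi[es$i[row], es$j[row]],
                numeric(1))
    ps <- partial_spearman(co$ga_birth, y, covs, co$subject_id)
    expect_equal(es$rho[row], ps$rho, tolerance = 1e-8)
  }
})

test_that("missing grid weights raise an error naming the scan", {
  co <- small_cohort(n_subjects = 5, n_repeat = 0, nodes = 15, seed = 71)
  g <- matrix(FALSE, 15, 15)
  # pick an edge absent in at least one scan
  absent <- which(co$connectome[[1]]$counts == 0 & upper.tri(g), arr.ind = TRUE)[1, ]
  g[absent[1], absent[2]] <- g[absent[2], absent[1]] <- TRUE
  expect_error(edgewise_association(co, g, "NDI", "ga_birth"),
               "missing edge weights")
})
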