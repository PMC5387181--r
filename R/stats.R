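# Minimum-grid construction and edge-wise association statistics: partial
# Spearman correlation with mixed-effects covariate control and BH-FDR.

#' Per-subject strongest-connection mask
#'
#' The edges holding the top `round(d * M)` streamline counts of one scan
#' (same ranking and tie rule as [cost_threshold()]); the building block of
#' the minimum grid.
#'
#' @inheritParams cost_threshold
#' @param d Mask density (default 0.3).
#' @return A symmetric logical matrix with zero diagonal.
#' @export
subject_mask <- function(connectome, d = 0.3, min_streamlines = 5,
                         scan_id = "scan") {
  net <- cost_threshold(connectome, "BINARY", d, min_streamlines, scan_id)
  net$weights > 0
}

#' Minimum grid of connectivity
#'
#' Element-wise intersection of per-subject masks: the backbone of connections
#' present in every scan of the cohort.
#'
#' @param masks List of symmetric logical edge masks on a common node set.
#' @return A symmetric logical matrix of class `minimum_grid`, with the input
#'   masks kept in attribute `source_masks`.
#' @export
minimum_grid <- function(masks) {
  stopifnot(length(masks) >= 1)
  dims <- vapply(masks, nrow, integer(1))
  if (length(unique(dims)) != 1) {
    stop("masks must share one node set (differing dimensions found)",
         call. = FALSE)
  }
  grid <- Reduce(`&`, masks)
  if (!any(grid)) warning("minimum grid is empty: no edge is common to all scans")
  structure(grid, class = c("minimum_grid", class(grid)),
            source_masks = masks)
}

#' Residualise a per-scan variable on covariates with a random intercept
#'
#' Fits a linear mixed-effects model of `values` on the covariates with a
#' subject-dependent random intercept (restricted maximum likelihood) and
#' returns the marginal residuals `y - X beta-hat`. When every subject has a
#' single scan the model degenerates to ordinary least squares. With no
#' covariates and single scans, residuals are the mean-centred values.
#'
#' @param values Numeric vector, one element per scan.
#' @param covariates Data frame (or matrix) of fixed-effect covariates, or
#'   `NULL`.
#' @param subject_ids Vector linking scans to subjects for the random
#'   intercept, or `NULL` for independent scans.
#' @return Numeric vector of residuals.
#' @export
lme_residualize <- function(values, covariates = NULL, subject_ids = NULL) {
  n <- length(values)
  X <- residual_design(covariates, n)
  repeated <- !is.null(subject_ids) && anyDuplicated(subject_ids) > 0
  if (!repeated) {
    return(stats::lm.fit(X, values)$residuals)
  }
  fit <- lme_fit(values, X, subject_ids)
  as.numeric(values - X %*% lme4::fixef(fit))
}

# fixed-effect design matrix with intercept; errors on rank deficiency naming
# the collinear columns
residual_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  # constant columns carry no information beyond the intercept; drop them so
  # small cohorts with, e.g., no NEC cases still fit
  keep <- vapply(covariates, function(v) length(unique(v)) > 1, logical(1))
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  X <- stats::model.matrix(~ ., data = covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (n < ncol(X) + 3) {
    stop("need at least 3 more scans than fixed-effect parameters",
         call. = FALSE)
  }
  X
}

lme_fit <- function(values, X, subject_ids) {
  df <- as.data.frame(X[, -1, drop = FALSE])
  df$.y <- values
  df$.subject <- factor(subject_ids)
  rhs <- if (ncol(df) > 2) {
    paste(sprintf("`%s`", setdiff(names(df), c(".y", ".subject"))),
          collapse = " + ")
  } else "1"
  form <- stats::as.formula(paste0(".y ~ ", rhs, " + (1 | .subject)"))
  fit_with <- function(optimizer) {
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(optimizer = optimizer,
                                           check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  }
  fit <- fit_with("bobyqa")
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    fit <- fit_with("Nelder_Mead")   # fall back before giving up
    conv <- fit@optinfo$conv$opt
    if (!is.null(conv) && conv != 0) {
      stop("mixed-model fit did not converge (optimizer code ", conv, "); ",
           paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "),
           call. = FALSE)
    }
  }
  fit
}

#' Partial Spearman correlation with mixed-effects covariate control
#'
#' Residualises `x` and `y` on the covariates via [lme_residualize()] (double
#' residualisation; `method = "single"` residualises only `y`), then computes
#' the Spearman rank correlation of the residuals. The p-value uses the
#' t-approximation by default; a seeded permutation option is available.
#'
#' @param x,y Numeric vectors, one element per scan.
#' @param covariates Data frame of covariates or `NULL`.
#' @param subject_ids Subject linkage for repeated scans, or `NULL`.
#' @param method `"double"` (default) or `"single"` residualisation.
#' @param p_method `"approx"` (t-approximation) or `"permutation"`.
#' @param n_perm,seed Permutation count and seed when
#'   `p_method = "permutation"`.
#' @return A one-row tibble: `rho, p_value, n`.
#' @export
partial_spearman <- function(x, y, covariates = NULL, subject_ids = NULL,
                             method = c("double", "single"),
                             p_method = c("approx", "permutation"),
                             n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  p_method <- match.arg(p_method)
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 5) stop("partial Spearman requires at least 5 scans", call. = FALSE)
  rx <- if (method == "double") {
    lme_residualize(x, covariates, subject_ids)
  } else x
  ry <- lme_residualize(y, covariates, subject_ids)
  if (stats::sd(rx) <= 1e-12 * max(1, stats::sd(x)) ||
      stats::sd(ry) <= 1e-12 * max(1, stats::sd(y))) {
    stop("constant residual vector: correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rank(rx), rank(ry))
  n_cov <- ncol(residual_design(covariates, n)) - 1L
  p <- switch(
    p_method,
    approx = spearman_p_approx(rho, n, n_cov),
    permutation = withr::with_seed(seed, {
      ranks_x <- rank(rx); ranks_y <- rank(ry)
      r0 <- abs(rho)
      hits <- sum(vapply(seq_len(n_perm), function(k) {
        abs(stats::cor(ranks_x, sample(ranks_y))) >= r0 - 1e-12
      }, logical(1)))
      (1 + hits) / (n_perm + 1)
    })
  )
  tibble::tibble(rho = rho, p_value = p, n = n)
}

# t-approximation for a (partial) Spearman coefficient; k covariates removed
# by residualisation cost k degrees of freedom on top of the usual n - 2
spearman_p_approx <- function(rho, n, k = 0) {
  rho <- pmin(pmax(rho, -1), 1)
  df <- n - 2 - k
  tstat <- rho * sqrt(df / pmax(1 - rho^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), df = df)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR correction: returns monotone-adjusted q-values and the
#' rejection mask at level `q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A tibble: `p_value, q_value, significant`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  qv <- stats::p.adjust(p_values, method = "BH")
  tibble::tibble(p_value = p_values, q_value = qv, significant = qv <= q)
}

#' Edge-wise association in the minimum grid
#'
#' For every edge of the grid, the partial Spearman correlation between the
#' edge's weight across scans and a predictor (GA at birth or age at MRI),
#' controlling sex, SGA, perinatal complications (respiratory support, NEC)
#' and the other age variable via mixed-effects residualisation; BH-FDR across
#' exactly the grid's edges.
#'
#' Absolute weights (`FA`, `NDI`, `ODI_C`) are the stored per-edge values;
#' with `relative = TRUE` the weights are taken from the network thresholded
#' at `relative_density` and normalised to unit total (rFA, rNDI, r(1-ODI)).
#'
#' @param cohort A `neoconn_cohort` tibble (see [simulate_cohort()]).
#' @param grid Logical edge mask (e.g. [minimum_grid()]).
#' @param weight_kind `"NDI"`, `"FA"` or `"ODI_C"`.
#' @param predictor `"ga_birth"` or `"age_at_mri"`.
#' @param q FDR level.
#' @param relative Use relative (normalised) weights?
#' @param relative_density Density at which relative weights are computed
#'   (defaults to the grid's 0.3).
#' @param method Residualisation passed to [partial_spearman()].
#' @return A tibble of class `edgewise_stats`: one row per grid edge with
#'   `i, j, region_i, region_j, weight_kind, predictor, rho, p_value,
#'   q_value, significant`.
#' @export
edgewise_association <- function(cohort, grid,
                                 weight_kind = c("NDI", "FA", "ODI_C"),
                                 predictor = c("ga_birth", "age_at_mri"),
                                 q = 0.05, relative = FALSE,
                                 relative_density = 0.3,
                                 method = c("double", "single")) {
  weight_kind <- match.arg(weight_kind)
  predictor <- match.arg(predictor)
  method <- match.arg(method)
  grid_m <- unclass(grid)
  idx <- which(upper.tri(grid_m) & grid_m)
  if (length(idx) == 0) stop("grid is empty", call. = FALSE)
  n_scan <- nrow(cohort)

  Y <- matrix(NA_real_, n_scan, length(idx))
  for (k in seq_len(n_scan)) {
    conn <- cohort$connectome[[k]]
    if (relative) {
      net <- normalize_weights(cost_threshold(conn, weight_kind,
                                              relative_density,
                                              scan_id = cohort$scan_id[k]))
      Y[k, ] <- net$weights[idx]
    } else {
      vals <- switch(weight_kind, NDI = conn$ndi, FA = conn$fa,
                     ODI_C = 1 - conn$odi)
      Y[k, ] <- vals[idx]
    }
  }
  if (anyNA(Y)) {
    bad <- unique(cohort$scan_id[rowSums(is.na(Y)) > 0])
    stop("missing edge weights inside the grid for scan(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  x <- cohort[[if (predictor == "ga_birth") "ga_birth" else "pma_scan"]]
  covs <- data.frame(
    sex = as.integer(cohort$sex == "M"),   # F = 0, M = 1
    sga = as.integer(cohort$sga),
    resp_support = as.integer(cohort$resp_support),
    nec = as.integer(cohort$nec),
    other_age = if (predictor == "ga_birth") cohort$pma_scan else cohort$ga_birth
  )
  subject_ids <- cohort$subject_id
  repeated <- anyDuplicated(subject_ids) > 0

  if (!repeated) {
    X <- residual_design(covs, n_scan)
    Qr <- qr(X)
    xres <- qr.resid(Qr, x)
    Yres <- qr.resid(Qr, Y)
  } else {
    X <- residual_design(covs, n_scan)
    xres <- if (method == "double") {
      as.numeric(x - X %*% lme4::fixef(lme_fit(x, X, subject_ids)))
    } else x
    fit0 <- lme_fit(Y[, 1], X, subject_ids)
    Yres <- matrix(NA_real_, n_scan, ncol(Y))
    Yres[, 1] <- Y[, 1] - as.numeric(X %*% lme4::fixef(fit0))
    if (ncol(Y) > 1) {
      for (e in 2:ncol(Y)) {
        # refit() reuses the model structure for speed; near-convergence
        # optimizer chatter is silenced and a full guarded fit is the fallback
        fe <- tryCatch(
          lme4::fixef(suppressWarnings(suppressMessages(
            lme4::refit(fit0, newresp = Y[, e])))),
          error = function(err) NULL
        )
        if (is.null(fe) || any(!is.finite(fe))) {
          fe <- lme4::fixef(lme_fit(Y[, e], X, subject_ids))
        }
        Yres[, e] <- Y[, e] - as.numeric(X %*% fe)
      }
    }
  }
  if (!repeated && method == "single") xres <- x

  rk_x <- rank(xres)
  rk_y <- apply(Yres, 2, rank)
  rho <- as.numeric(stats::cor(rk_x, rk_y))
  p <- spearman_p_approx(rho, n_scan, ncol(X) - 1L)
  adj <- fdr_bh(p, q)

  labels <- cohort$connectome[[1]]$node_labels
  nn <- nrow(grid_m)
  jj <- ((idx - 1) %/% nn) + 1
  ii <- ((idx - 1) %% nn) + 1
  out <- tibble::tibble(
    i = ii, j = jj,
    region_i = labels[ii], region_j = labels[jj],
    weight_kind = if (relative) paste0("r", weight_kind) else weight_kind,
    predictor = predictor,
    rho = rho, p_value = adj$p_value, q_value = adj$q_value,
    significant = adj$significant
  )
  structure(out, class = c("edgewise_stats", class(out)),
            q = q, n_scans = n_scan, relative = relative)
}
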