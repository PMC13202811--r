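#' Build the EWAS design matrix
#'
#' Cell-means coding for microbiome clusters (one indicator per cluster, no
#' intercept) so that pairwise contrasts are simple coefficient differences,
#' plus the adjustment set: sex, age, BMI z-score, race/ethnicity indicators
#' (reference level dropped), maternal education, annual and biannual season
#' harmonics of the collection day, sequencing-batch indicators, surrogate
#' cell-composition components, and optional extra covariates. Seasonality is
#' encoded as \eqn{\sin(2\pi d/365.25)}, \eqn{\cos(2\pi d/365.25)},
#' \eqn{\sin(4\pi d/365.25)}, \eqn{\cos(4\pi d/365.25)}.
#'
#' @param cov covariate table with columns `sample_id`, `sex`, `age`, `bmi_z`,
#'   `race`, `education`, `day_of_year`, `batch`.
#' @param labels per-sample cluster labels (1..k), aligned with `cov` rows.
#' @param refactor optional `mm_refactor` (or samples x k score matrix).
#' @param extra optional extra covariates (vector, matrix or data frame),
#'   e.g. a medication-use indicator for sensitivity re-runs.
#' @param harmonics 2 for annual + biannual season terms (4 columns), 1 for
#'   annual only.
#' @return Numeric design matrix with attribute `cluster_cols` giving the
#'   cluster-indicator columns. Errors if rank deficient.
#' @export
build_design <- function(cov, labels, refactor = NULL, extra = NULL,
                         harmonics = 2) {
  mm_assert(nrow(cov) == length(labels),
            "`cov` and `labels` must describe the same samples")
  k <- length(unique(labels))
  clusters <- sort(unique(labels))
  X_cl <- sapply(clusters, function(cl) as.numeric(labels == cl))
  colnames(X_cl) <- paste0("cluster", clusters)

  onehot <- function(x, nm) {
    f <- factor(x)
    if (nlevels(f) < 2) return(NULL)
    m <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(m) <- paste0(nm, levels(f)[-1])
    m
  }
  d <- cov$day_of_year
  season <- cbind(season_sin1 = sin(2 * pi * d / 365.25),
                  season_cos1 = cos(2 * pi * d / 365.25))
  if (harmonics >= 2)
    season <- cbind(season,
                    season_sin2 = sin(4 * pi * d / 365.25),
                    season_cos2 = cos(4 * pi * d / 365.25))
  X <- cbind(X_cl,
             sex = as.numeric(cov$sex),
             age = cov$age,
             bmi_z = cov$bmi_z,
             onehot(cov$race, "race_"),
             education = as.numeric(cov$education),
             season,
             onehot(cov$batch, "batch_"))
  if (!is.null(refactor)) {
    sc <- if (inherits(refactor, "mm_refactor")) refactor$scores else
      as.matrix(refactor)
    mm_assert(nrow(sc) == nrow(X), "refactor scores must align with samples")
    X <- cbind(X, sc)
  }
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    if (is.null(colnames(extra)))
      colnames(extra) <- paste0("extra_", seq_len(ncol(extra)))
    X <- cbind(X, extra)
  }
  rownames(X) <- cov$sample_id
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (collinear covariates)",
         call. = FALSE)
  attr(X, "cluster_cols") <- seq_len(k)
  X
}

#' Per-CpG robust linear model fits
#'
#' Fits every CpG's M values against the design by iteratively reweighted
#' least squares with Huber weights \eqn{w = \min(1, c/|r/\hat s|)}, where
#' \eqn{\hat s = 1.4826 \cdot \mathrm{median}|r|}, iterated to coefficient
#' convergence. With well-behaved (outlier-free) residuals all weights are 1
#' and the fit equals ordinary least squares. CpGs that fail to converge fall
#' back to OLS with a warning. Degrees of freedom are `n - p` (no
#' weight-based correction). Coefficient standard errors use Huber's robust
#' variance (the truncated-score form with the small-sample `K` correction,
#' as in classical robust regression), `SE = s_rob * sqrt(diag((X'X)^-1))`
#' with `s_rob^2 = K^2 * shat^2 * sum(psi^2)/(n-p) / mean(psi')^2`; it
#' reduces exactly to the OLS variance when no residual is truncated and
#' keeps null test statistics calibrated, where a naive MAD plug-in scale
#' does not.
#'
#' @param m CpG x samples matrix of M values.
#' @param design design matrix from [build_design()] (samples x predictors).
#' @param huber_c Huber tuning constant (1.345 gives 95% Gaussian efficiency).
#' @param max_iter,tol IRLS iteration cap and coefficient tolerance.
#' @return An `mm_ewas_fit`: coefficients, unscaled coefficient SDs, residual
#'   scale `sigma`, residual df, the unscaled covariance block of the cluster
#'   coefficients, per-CpG mean M, and a convergence flag.
#' @export
robust_fit <- function(m, design, huber_c = 1.345, max_iter = 50, tol = 1e-8) {
  m <- as.matrix(m)
  X <- as.matrix(design)
  mm_assert(ncol(m) == nrow(X), "samples of `m` and `design` must align")
  mm_assert(nrow(X) > ncol(X), "need more samples than predictors")
  cc <- attr(design, "cluster_cols") %||% seq_len(ncol(X))
  fit <- cpp_huber_fit(m, X, as.integer(cc - 1L), huber_c,
                       as.integer(max_iter), tol)
  if (!all(fit$converged))
    warning(sum(!fit$converged),
            " CpG(s) did not converge; ordinary least squares used for them")
  dimnames(fit$coefficients) <- list(rownames(m), colnames(X))
  dimnames(fit$stdev_unscaled) <- dimnames(fit$coefficients)
  structure(list(coefficients = fit$coefficients,
                 stdev_unscaled = fit$stdev_unscaled,
                 sigma = as.numeric(fit$sigma),
                 df_residual = fit$df_residual,
                 cov_unscaled = fit$cov_unscaled,
                 cluster_cols = cc,
                 mean_m = rowMeans(m),
                 cpg_ids = rownames(m) %||% as.character(seq_len(nrow(m))),
                 converged = fit$converged,
                 moderated = FALSE),
            class = "mm_ewas_fit")
}

#' @export
print.mm_ewas_fit <- function(x, ...) {
  cat(sprintf("<mm_ewas_fit> %d CpGs x %d coefficients, df = %d%s\n",
              nrow(x$coefficients), ncol(x$coefficients),
              as.integer(x$df_residual),
              if (x$moderated) sprintf(" (moderated: d0 = %.3g)", x$d0) else ""))
  invisible(x)
}

# Newton inversion of the trigamma function (for moment matching)
trigamma_inverse <- function(y) {
  out <- y
  out[y > 1e7] <- 1 / sqrt(y[y > 1e7])
  out[y < 1e-6] <- 1 / y[y < 1e-6]
  mid <- y <= 1e7 & y >= 1e-6
  x <- 0.5 + 1 / y[mid]
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(-dif / x) < 1e-8) break
  }
  out[mid] <- x
  out
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-CpG residual variances toward a common prior by the standard
#' scaled-inverse-chi-squared hierarchy: the prior df `d0` and scale `s0^2`
#' are estimated by method of moments on `log s^2` (digamma/trigamma
#' matching), and the posterior variance is
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)}; downstream t statistics
#' then use \eqn{\tilde s} with `d0 + d` degrees of freedom. When the
#' observed `log s^2` have no excess dispersion beyond the chi-squared
#' component, `d0` is infinite and all variances shrink to the common value.
#'
#' @param fit an `mm_ewas_fit` from [robust_fit()].
#' @param min_cpgs minimum number of CpGs required for stable hyperparameters;
#'   below it moderation is skipped with a warning.
#' @return The fit with `s2_post`, `d0`, `s02`, `df_total` and
#'   `moderated = TRUE`.
#' @export
ebayes_moderate <- function(fit, min_cpgs = 100) {
  mm_assert(inherits(fit, "mm_ewas_fit"), "`fit` must be an mm_ewas_fit")
  s2 <- fit$sigma^2
  if (length(s2) < min_cpgs) {
    warning("fewer than ", min_cpgs, " CpGs; moderation skipped")
    return(fit)
  }
  d <- fit$df_residual
  ok <- s2 > 0
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
  } else {
    # no excess dispersion beyond the chi-squared component
    d0 <- Inf
    s02 <- mean(s2[ok])
    s2_post <- rep(s02, length(s2))
  }
  fit$d0 <- d0
  fit$s02 <- s02
  fit$s2_post <- s2_post
  fit$df_total <- d0 + d
  fit$moderated <- TRUE
  fit
}

# all C(k,2) ordered pairs of cluster ids
pairwise_contrast_matrix <- function(k) {
  pairs <- utils::combn(k, 2)
  L <- matrix(0, k, ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    L[pairs[1, j], j] <- 1
    L[pairs[2, j], j] <- -1
  }
  colnames(L) <- paste0(pairs[1, ], "_vs_", pairs[2, ])
  L
}

#' All pairwise cluster contrasts
#'
#' Evaluates contrasts of the cluster (cell-means) coefficients for every
#' CpG: \eqn{\Delta M = c^\top \hat\beta}, standard errors from the fitted
#' covariance (moderated when [ebayes_moderate()] has been applied), two-sided
#' t p-values, and the Beta-scale effect via [delta_m_to_delta_beta()] at the
#' CpG's mean M. By default all \eqn{\binom{k}{2}} pairs are tested.
#'
#' @param fit an `mm_ewas_fit`.
#' @param contrast_matrix optional k x q matrix of contrasts over the cluster
#'   coefficients (columns are contrast vectors). Default: all pairwise
#'   differences.
#' @return An `mm_contrasts` tibble: `cpg_id`, `contrast`, `delta_m`, `se`,
#'   `t`, `df`, `p`, `delta_beta`, `delta_beta_pct`.
#' @export
pairwise_contrasts <- function(fit, contrast_matrix = NULL) {
  mm_assert(inherits(fit, "mm_ewas_fit"), "`fit` must be an mm_ewas_fit")
  k <- length(fit$cluster_cols)
  L <- contrast_matrix %||% pairwise_contrast_matrix(k)
  L <- as.matrix(L)
  mm_assert(nrow(L) == k,
            "contrast rows must match the number of cluster coefficients")
  if (is.null(colnames(L))) colnames(L) <- paste0("c", seq_len(ncol(L)))
  B <- fit$coefficients[, fit$cluster_cols, drop = FALSE]
  est <- B %*% L
  G <- nrow(est)
  # unscaled contrast variances from the stored covariance block
  vu <- matrix(0, G, ncol(L))
  for (g in seq_len(G)) {
    V <- fit$cov_unscaled[, , g]
    vu[g, ] <- colSums(L * (V %*% L))
  }
  mm_assert(all(vu >= -1e-12), "contrast variance must be non-negative")
  s <- if (fit$moderated) sqrt(fit$s2_post) else fit$sigma
  df <- if (fit$moderated) fit$df_total else fit$df_residual
  se <- sqrt(pmax(vu, 0)) * s
  tstat <- est / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  dbeta <- delta_m_to_delta_beta(matrix(fit$mean_m, G, ncol(L)), est)
  out <- tibble::tibble(
    cpg_id = rep(fit$cpg_ids, times = ncol(L)),
    contrast = rep(colnames(L), each = G),
    delta_m = as.numeric(est),
    se = as.numeric(se),
    t = as.numeric(tstat),
    df = df,
    p = pmin(pmax(as.numeric(p), .Machine$double.xmin), 1),
    delta_beta = as.numeric(dbeta),
    delta_beta_pct = 100 * as.numeric(dbeta))
  class(out) <- c("mm_contrasts", class(out))
  out
}

#' Global multiple-testing decision
#'
#' Bonferroni control over the full CpG x contrast family: a cell is flagged
#' when `p < alpha / (n_cpgs * n_contrasts)` (strict inequality). With
#' `method = "fdr"` Benjamini-Hochberg is applied over the pooled matrix. A
#' differentially methylated position (DMP) is a CpG significant in at least
#' one contrast.
#'
#' @param p matrix of raw p-values (CpGs x contrasts) or an `mm_contrasts`
#'   tibble (pivoted internally).
#' @param alpha family-wise error (or FDR) level.
#' @param method `"bonferroni"` or `"fdr"`.
#' @return A list: `flags` (logical matrix), `threshold` (raw-p cut for
#'   bonferroni; largest flagged raw p for fdr), `dmp` (per-CpG logical),
#'   `n_dmps`, `n_tests`, `method`, `alpha`.
#' @export
global_significance <- function(p, alpha = 0.05,
                                method = c("bonferroni", "fdr")) {
  method <- match.arg(method)
  if (inherits(p, "mm_contrasts")) {
    wide <- tidyr::pivot_wider(p[, c("cpg_id", "contrast", "p")],
                               names_from = "contrast", values_from = "p")
    pm <- as.matrix(wide[, -1])
    rownames(pm) <- wide$cpg_id
    p <- pm
  }
  p <- as.matrix(p)
  mm_assert(length(p) > 0, "empty p-value matrix")
  mm_assert(all(p > 0 & p <= 1), "p-values must lie in (0, 1]")
  n_tests <- length(p)
  if (method == "bonferroni") {
    threshold <- alpha / n_tests
    flags <- p < threshold
  } else {
    adj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
                  dimnames = dimnames(p))
    flags <- adj < alpha
    threshold <- if (any(flags)) max(p[flags]) else 0
  }
  dmp <- rowSums(flags) > 0
  list(flags = flags, threshold = threshold, dmp = dmp,
       n_dmps = sum(dmp), n_tests = n_tests, method = method, alpha = alpha)
}

#' Annotate contrasts with adjusted p-values
#'
#' Convenience wrapper adding `p_bonferroni` (capped at 1, over the full
#' CpG x contrast family), `p_fdr` (BH over the pooled family) and a
#' `significant` flag to a contrast table.
#'
#' @param contrasts an `mm_contrasts` tibble.
#' @param alpha significance level.
#' @param method family-wise (`"bonferroni"`) or `"fdr"` flagging.
#' @return The tibble with `p_bonferroni`, `p_fdr` and `significant` added.
#' @export
adjust_contrasts <- function(contrasts, alpha = 0.05,
                             method = c("bonferroni", "fdr")) {
  method <- match.arg(method)
  n_tests <- nrow(contrasts)
  contrasts$p_bonferroni <- pmin(1, contrasts$p * n_tests)
  contrasts$p_fdr <- stats::p.adjust(contrasts$p, method = "BH")
  contrasts$significant <- if (method == "bonferroni")
    contrasts$p < alpha / n_tests else contrasts$p_fdr < alpha
  contrasts
}

#' Test-statistic inflation diagnostics
#'
#' Per contrast: the genomic inflation factor
#' \eqn{\lambda = \mathrm{median}(z^2)/0.4549364} on probit-transformed
#' two-sided p-values (signed by the t statistic when available), plus an
#' empirical-null location/scale estimate in the spirit of the Bayesian
#' inflation factor: robust location = median(z), and scale = the median
#' absolute deviation of the central 90% of z rescaled by
#' \eqn{1/\Phi^{-1}(0.725)} so the estimator is consistent for the null SD
#' under a pure Gaussian null.
#'
#' @param p matrix of raw p-values (CpGs x contrasts).
#' @param t optional matrix of t statistics supplying the z signs.
#' @param min_tests minimum number of tests per contrast.
#' @return A tibble: `contrast`, `lambda`, `null_location`, `null_scale`.
#' @export
inflation_report <- function(p, t = NULL, min_tests = 1000) {
  p <- as.matrix(p)
  mm_assert(nrow(p) >= min_tests,
            sprintf("inflation diagnostics need >= %d tests", min_tests))
  cn <- colnames(p) %||% paste0("c", seq_len(ncol(p)))
  purrr::map_dfr(seq_len(ncol(p)), function(j) {
    z <- stats::qnorm(pmin(pmax(p[, j] / 2, 1e-300), 1), lower.tail = FALSE)
    if (!is.null(t)) z <- z * sign(t[, j])
    lambda <- stats::median(z^2) / stats::qchisq(0.5, 1)
    med <- stats::median(z)
    qs <- stats::quantile(z, c(0.05, 0.95), names = FALSE)
    ztrim <- z[z >= qs[1] & z <= qs[2]]
    scale <- stats::median(abs(ztrim - med)) / stats::qnorm(0.725)
    tibble::tibble(contrast = cn[j], lambda = lambda,
                   null_location = med, null_scale = scale)
  })
}

#' Empirical p-value from permutation counts
#'
#' The permutation formula with strict exceedance:
#' \eqn{(1 + \#\{b : \mathrm{count}_b > \mathrm{observed}\})/(B + 1)}.
#'
#' @param observed observed DMP count.
#' @param perm_counts vector of B permutation DMP counts.
#' @return The empirical p-value, in `[1/(B+1), 1]`.
#' @export
permutation_empirical_p <- function(observed, perm_counts) {
  mm_assert(length(perm_counts) >= 1, "need at least one permutation")
  (1 + sum(perm_counts > observed)) / (length(perm_counts) + 1)
}

#' Permutation empirical null for DMP counts
#'
#' Re-runs the full EWAS (robust fits, optional moderation, all pairwise
#' contrasts, global decision) under `B` uniform random permutations of the
#' cluster labels, holding all other covariates fixed, and compares the
#' observed DMP count against the permuted counts with
#' [permutation_empirical_p()].
#'
#' Counting rule: `rule = "bonferroni"` flags at `alpha/(n_cpgs * n_contrasts)`
#' as in the primary analysis; `rule = "nominal"` counts CpGs with raw
#' `p < nominal_p` in at least one contrast (useful for calibration studies,
#' where the strict-family count is nearly always zero and ties would make
#' the empirical p degenerate).
#'
#' @param m CpG x samples M-value matrix.
#' @param cov covariate table (see [build_design()]).
#' @param labels observed cluster labels.
#' @param refactor,extra passed to [build_design()].
#' @param B number of permutations.
#' @param seed integer seed for the permutation stream.
#' @param alpha significance level for the counting rule.
#' @param rule `"bonferroni"` or `"nominal"`.
#' @param nominal_p per-test threshold when `rule = "nominal"`.
#' @param moderate apply [ebayes_moderate()] within each EWAS.
#' @return An `mm_perm` list: `observed`, `perm_counts`, `B`, `empirical_p`.
#' @export
permutation_null <- function(m, cov, labels, refactor = NULL, extra = NULL,
                             B = 500, seed = NULL, alpha = 0.05,
                             rule = c("bonferroni", "nominal"),
                             nominal_p = 0.01, moderate = TRUE) {
  rule <- match.arg(rule)
  mm_assert(B >= 1, "`B` must be at least 1")
  count_dmps <- function(lab) {
    X <- build_design(cov, lab, refactor = refactor, extra = extra)
    fit <- robust_fit(m, X)
    if (moderate) fit <- suppressWarnings(ebayes_moderate(fit))
    ct <- pairwise_contrasts(fit)
    pm <- matrix(ct$p, nrow = nrow(m))
    if (rule == "bonferroni") sum(rowSums(pm < alpha / length(pm)) > 0)
    else sum(rowSums(pm < nominal_p) > 0)
  }
  observed <- count_dmps(labels)
  if (!is.null(seed)) set.seed(seed)
  perm_counts <- vapply(seq_len(B), function(b) count_dmps(sample(labels)),
                        numeric(1))
  structure(list(observed = observed, perm_counts = perm_counts, B = B,
                 empirical_p = permutation_empirical_p(observed, perm_counts)),
            class = "mm_perm")
}

#' @export
print.mm_perm <- function(x, ...) {
  cat(sprintf("<mm_perm> observed = %d DMPs, B = %d, empirical p = %.4g\n",
              x$observed, x$B, x$empirical_p))
  invisible(x)
}
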