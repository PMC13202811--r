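#' Bias-corrected log-linear differential abundance
#'
#' A simplified compositional differential-abundance model in the spirit of
#' bias-corrected log-linear frameworks: counts are log-transformed after
#' adding a pseudo-count, a per-sample sampling-fraction offset is estimated
#' as the median across taxa of the sample's deviation from taxon means, and
#' each taxon's offset-corrected log abundance is regressed on the exposure
#' plus covariates by least squares. The offset makes estimates invariant to
#' sample-specific scaling of the counts. (The original framework's iterative
#' bias correction, structural-zero detection and mixed directional FDR are
#' deliberately not reproduced; the estimand — covariate-adjusted
#' compositional log fold change — is the same.)
#'
#' @param cm genus-level, prevalence-filtered [count_matrix()] with integer
#'   counts (pre-rarefaction).
#' @param exposure per-sample numeric exposure. With
#'   `scale_exposure = TRUE` it is divided by its IQR so coefficients read as
#'   logFC per IQR increase.
#' @param covariates optional covariate matrix/data frame (an intercept is
#'   added automatically; cluster indicators are not expected here).
#' @param pseudo_count positive pseudo-count added before the log transform.
#' @param scale_exposure divide the exposure by its IQR.
#' @return A tibble: `taxon`, `logFC`, `se`, `t`, `df`, `p`, `pseudo_count`.
#' @export
fit_da <- function(cm, exposure, covariates = NULL, pseudo_count = 1,
                   scale_exposure = TRUE) {
  mm_assert(inherits(cm, "mm_counts"), "`cm` must be an mm_counts object")
  x <- cm$counts
  mm_assert(all(x == round(x)), "`fit_da` requires integer counts")
  mm_assert(pseudo_count > 0, "`pseudo_count` must be positive")
  mm_assert(length(exposure) == ncol(x),
            "`exposure` must align with the samples")
  if (scale_exposure) {
    iqr <- stats::IQR(exposure)
    mm_assert(iqr > 0, "exposure has zero IQR (constant exposure)")
    exposure <- exposure / iqr
  } else {
    mm_assert(stats::var(exposure) > 0, "exposure is constant")
  }
  y <- log(x + pseudo_count)
  offset <- apply(y - rowMeans(y), 2, stats::median)
  z <- sweep(y, 2, offset)
  X <- cbind(`(Intercept)` = 1, exposure = exposure)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  mm_assert(nrow(X) > ncol(X), "more predictors than samples")
  fit <- stats::lm.fit(X, t(z))
  df <- nrow(X) - fit$rank
  res <- as.matrix(fit$residuals)
  s2 <- colSums(res^2) / df
  XtXi <- chol2inv(qr.R(fit$qr))
  # column order after QR pivoting
  piv <- fit$qr$pivot
  epos <- which(piv == 2)
  se <- sqrt(s2 * XtXi[epos, epos])
  est <- coef(fit)["exposure", ]
  tstat <- est / se
  tibble::tibble(taxon = rownames(x), logFC = unname(est), se = unname(se),
                 t = unname(tstat), df = df,
                 p = unname(2 * stats::pt(-abs(tstat), df)),
                 pseudo_count = pseudo_count)
}

#' Pseudo-count sensitivity analysis
#'
#' Runs [fit_da()] at each pseudo-count; q-values are Benjamini-Hochberg over
#' taxa at the primary pseudo-count (the largest by default). A taxon passes
#' sensitivity when it is significant at the primary pseudo-count AND keeps
#' the same coefficient sign AND stays significant (within-run BH) at every
#' other pseudo-count.
#'
#' @param cm,exposure,covariates,scale_exposure as in [fit_da()].
#' @param pseudo_counts at least two positive pseudo-counts.
#' @param primary the primary pseudo-count (must be in `pseudo_counts`).
#' @param alpha FDR level.
#' @return A tibble at the primary pseudo-count with `q` and
#'   `sensitivity_pass` added; per-pseudo-count results are in
#'   `attr(, "by_pseudocount")`.
#' @export
pseudocount_sensitivity <- function(cm, exposure, covariates = NULL,
                                    pseudo_counts = c(0.1, 0.5, 1.0),
                                    primary = max(pseudo_counts),
                                    alpha = 0.05, scale_exposure = TRUE) {
  mm_assert(length(pseudo_counts) >= 2, "need at least two pseudo-counts")
  mm_assert(primary %in% pseudo_counts, "`primary` must be a pseudo-count")
  runs <- purrr::map(pseudo_counts, function(pc) {
    r <- fit_da(cm, exposure, covariates, pseudo_count = pc,
                scale_exposure = scale_exposure)
    r$q <- stats::p.adjust(r$p, method = "BH")
    r
  })
  names(runs) <- as.character(pseudo_counts)
  main <- runs[[as.character(primary)]]
  others <- runs[names(runs) != as.character(primary)]
  pass <- main$q < alpha
  for (r in others) {
    pass <- pass & (r$q < alpha) & (sign(r$logFC) == sign(main$logFC))
  }
  main$sensitivity_pass <- pass
  attr(main, "by_pseudocount") <- runs
  main
}

#' Differential abundance against each differentially methylated position
#'
#' For every CpG in `dmp_ids`, runs the pseudo-count sensitivity analysis
#' with that CpG's M values (IQR-scaled) as the exposure; BH correction is
#' applied within each DMP family (one test per taxon).
#'
#' @param cm genus-level, prevalence-filtered [count_matrix()].
#' @param m CpG x samples M-value matrix.
#' @param dmp_ids character vector of CpG ids present in `m`.
#' @param covariates optional covariates (no cluster columns).
#' @param pseudo_counts pseudo-count array.
#' @param alpha FDR level.
#' @return A long tibble with a `cpg_id` column; empty (with the right
#'   columns) when `dmp_ids` is empty.
#' @export
da_for_dmps <- function(cm, m, dmp_ids, covariates = NULL,
                        pseudo_counts = c(0.1, 0.5, 1.0), alpha = 0.05) {
  missing_ids <- setdiff(dmp_ids, rownames(m))
  mm_assert(length(missing_ids) == 0,
            paste("unknown CpG id(s):", paste(missing_ids, collapse = ", ")))
  if (length(dmp_ids) == 0) {
    return(tibble::tibble(cpg_id = character(), taxon = character(),
                          logFC = numeric(), se = numeric(), t = numeric(),
                          df = numeric(), p = numeric(),
                          pseudo_count = numeric(), q = numeric(),
                          sensitivity_pass = logical()))
  }
  purrr::map_dfr(dmp_ids, function(id) {
    r <- pseudocount_sensitivity(cm, exposure = m[id, ],
                                 covariates = covariates,
                                 pseudo_counts = pseudo_counts, alpha = alpha,
                                 scale_exposure = TRUE)
    attr(r, "by_pseudocount") <- NULL
    dplyr::bind_cols(tibble::tibble(cpg_id = id), r)
  })
}
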