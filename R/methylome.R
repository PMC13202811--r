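#' Beta / M value conversions
#'
#' Methylation proportions (Beta values, strictly inside (0,1)) map to the
#' variance-stabilised M scale by \eqn{M = \log_2(\beta/(1-\beta))} and back
#' by the logistic \eqn{\beta = 2^M/(1+2^M)}; the two are exact inverses.
#'
#' @param beta numeric vector/matrix of Beta values in (0,1).
#' @param m numeric vector/matrix of M values.
#' @return The converted vector/matrix (dimensions preserved).
#' @export
beta_to_m <- function(beta) {
  mm_assert(all(beta > 0 & beta < 1), "Beta values must lie strictly in (0,1)")
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  mm_assert(all(is.finite(m)), "M values must be finite")
  1 / (1 + 2^(-m))
}

#' Per-CpG winsorization of M values
#'
#' For each row, values below the 5th (above the 95th) linear-interpolation
#' quantile are replaced by the smallest observed value at or above (largest
#' at or below) that quantile — i.e. by the next closest retained value. The
#' operation is idempotent and preserves rank order among distinct values.
#'
#' @param m CpG x samples matrix of M values (or a numeric vector).
#' @param lower,upper quantile probabilities defining the winsorization band.
#' @return Matrix (or vector) of the same shape.
#' @export
winsorize_m <- function(m, lower = 0.05, upper = 0.95) {
  vecin <- is.null(dim(m))
  x <- if (vecin) matrix(m, nrow = 1) else as.matrix(m)
  mm_assert(ncol(x) >= 3, "winsorization needs at least 3 samples")
  out <- t(apply(x, 1, function(v) {
    q <- stats::quantile(v, c(lower, upper), type = 7, names = FALSE)
    lo_rep <- min(v[v >= q[1]])
    hi_rep <- max(v[v <= q[2]])
    v[v < q[1]] <- lo_rep
    v[v > q[2]] <- hi_rep
    v
  }))
  if (vecin) return(as.numeric(out))
  dimnames(out) <- dimnames(x)
  out
}

#' Reference-free cell-composition components (ReFACTor)
#'
#' Sparse-PCA surrogate for cell-type heterogeneity: each CpG row is
#' standardised, a rank-`k` approximation is formed from the top-k principal
#' components, CpGs are scored by the distance between their standardised row
#' and its low-rank reconstruction, and the `t` best-reconstructed (most
#' informative) sites are kept; the first `k` principal-component scores of
#' that submatrix are the returned components.
#'
#' @param beta CpG x samples Beta-value matrix.
#' @param k number of components (and the rank of the approximation).
#' @param t number of sites selected for the final PCA.
#' @return An `mm_refactor` list: `scores` (samples x k, zero-mean columns),
#'   `selected_sites`, `k`, `t`.
#' @export
refactor_components <- function(beta, k = 10, t = 500) {
  beta <- as.matrix(beta)
  n <- ncol(beta); g <- nrow(beta)
  mm_assert(k < n, "`k` must be smaller than the number of samples")
  t <- min(t, g)
  mm_assert(t >= k, "`t` must be at least `k`")
  sds <- apply(beta, 1, stats::sd)
  sds[sds == 0] <- 1
  Z <- (beta - rowMeans(beta)) / sds
  sv <- svd(Z, nu = k, nv = k)
  recon <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
  score <- sqrt(rowSums((Z - recon)^2))
  sel <- order(score)[seq_len(t)]
  Zs <- Z[sel, , drop = FALSE]
  svs <- svd(scale(t(Zs), center = TRUE, scale = FALSE), nu = k, nv = 0)
  comps <- svs$u %*% diag(svs$d[seq_len(k)], k)
  rownames(comps) <- colnames(beta)
  colnames(comps) <- paste0("refactor_", seq_len(k))
  structure(list(scores = comps,
                 selected_sites = rownames(beta)[sel] %||%
                   as.character(sel),
                 k = as.integer(k), t = as.integer(t)),
            class = "mm_refactor")
}

#' Convert an M-scale effect to the Beta scale
#'
#' M-model/M-mean conversion: the model is fitted on the M scale and the
#' effect is translated at the CpG's overall mean M value,
#' \eqn{\Delta\beta = \sigma(\bar M + \Delta M) - \sigma(\bar M)} with
#' \eqn{\sigma(m) = 2^m/(1+2^m)}. Multiply by 100 for percentage points.
#'
#' @param mean_m the CpG's mean M value (reference level).
#' @param delta_m the estimated M-scale effect.
#' @param centered if `TRUE`, use the symmetric variant
#'   \eqn{\sigma(\bar M + \Delta M/2) - \sigma(\bar M - \Delta M/2)}.
#' @return Effect on the Beta scale (proportion, not percent).
#' @export
delta_m_to_delta_beta <- function(mean_m, delta_m, centered = FALSE) {
  mm_assert(all(is.finite(mean_m)) && all(is.finite(delta_m)),
            "inputs must be finite")
  if (centered) m_to_beta(mean_m + delta_m / 2) - m_to_beta(mean_m - delta_m / 2)
  else m_to_beta(mean_m + delta_m) - m_to_beta(mean_m)
}

# deterministic 1-D k-means: centers initialised at the (2j-1)/(2k)
# quantiles, Lloyd iterations to convergence
kmeans_1d <- function(x, k) {
  centers <- stats::quantile(x, (2 * seq_len(k) - 1) / (2 * k),
                             type = 7, names = FALSE)
  assign <- NULL
  for (it in 1:200) {
    dmat <- abs(outer(x, centers, "-"))
    new_assign <- max.col(-dmat, ties.method = "first")
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(k)) {
      if (any(assign == j)) centers[j] <- mean(x[assign == j])
    }
  }
  ord <- order(centers)
  remap <- integer(k); remap[ord] <- seq_len(k)
  list(assign = remap[assign], centers = centers[ord])
}

#' Bimodality screen for genetically driven methylation groups
#'
#' Groups one CpG's Beta values with deterministic 1-D k-means (a proxy for
#' genotype classes at a methylation QTL) and tests independence of the
#' groups against the microbiome cluster labels with a Pearson chi-squared
#' test. A warning flags expected cells below 5.
#'
#' @param beta numeric vector of one CpG's Beta values.
#' @param cluster_labels per-sample cluster labels.
#' @param k_groups number of methylation groups (2 or 3).
#' @return An `mm_meqtl_screen` list: `groups`, `centers`, `statistic`, `df`,
#'   `p_value`, `table`, `skipped` (TRUE when all values are equal).
#' @export
genotype_group_screen <- function(beta, cluster_labels, k_groups = 2) {
  mm_assert(k_groups %in% c(2, 3), "`k_groups` must be 2 or 3")
  mm_assert(length(beta) == length(cluster_labels),
            "`beta` and `cluster_labels` must align")
  mm_assert(length(beta) >= 3 * k_groups, "too few samples for the screen")
  if (length(unique(beta)) == 1) {
    return(structure(list(skipped = TRUE, groups = NULL, centers = NULL,
                          statistic = NA_real_, df = NA_integer_,
                          p_value = NA_real_, table = NULL),
                     class = "mm_meqtl_screen"))
  }
  km <- kmeans_1d(beta, k_groups)
  tab <- table(group = km$assign, cluster = cluster_labels)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    warning("expected cell count below 5; chi-squared approximation is rough")
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  structure(list(skipped = FALSE, groups = km$assign, centers = km$centers,
                 statistic = stat, df = as.integer(df),
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 table = tab),
            class = "mm_meqtl_screen")
}
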