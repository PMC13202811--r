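#' Pairwise community distances
#'
#' Computes all-pairs dissimilarities between samples (columns) of a
#' relative-abundance matrix. Jensen-Shannon divergence uses natural
#' logarithms with the convention \eqn{0 \log 0 = 0} and is bounded by
#' \eqn{\ln 2}; `jsd_sqrt` (its square root) is a metric. Bray-Curtis is
#' \eqn{\sum|p - q| / \sum(p + q)} and Jaccard is computed on
#' presence/absence.
#'
#' @param ra taxa x samples matrix whose columns are probability vectors.
#' @param metric one of `"jsd"`, `"jsd_sqrt"`, `"bray_curtis"`, `"jaccard"`.
#' @param tol tolerance for checking that columns sum to one.
#' @return An `mm_dist`: a symmetric n x n matrix with attributes `metric`.
#' @export
pairwise_distance <- function(ra, metric = c("jsd", "jsd_sqrt", "bray_curtis",
                                             "jaccard"), tol = 1e-8) {
  metric <- match.arg(metric)
  ra <- as.matrix(ra)
  mm_assert(all(ra >= 0), "relative abundances must be non-negative")
  mm_assert(all(abs(colSums(ra) - 1) < tol),
            "columns of `ra` must sum to 1; call to_relative_abundance()")
  code <- switch(metric, jsd = 0L, jsd_sqrt = 0L, bray_curtis = 1L,
                 jaccard = 2L)
  d <- cpp_pairwise_distance(ra, code)
  if (metric == "jsd_sqrt") d <- sqrt(d)
  dimnames(d) <- list(colnames(ra), colnames(ra))
  structure(d, metric = metric, class = c("mm_dist", "matrix", "array"))
}

#' Partitioning around medoids
#'
#' Deterministic PAM on a precomputed dissimilarity matrix: the BUILD phase
#' greedily selects `k` medoids minimising total cost, then the SWAP phase
#' repeatedly applies the best strictly-improving medoid/non-medoid exchange.
#' All ties (including assignment of equidistant samples) are broken by the
#' smallest sample index, so the algorithm needs no random seed.
#'
#' @param d square dissimilarity matrix (e.g. from [pairwise_distance()]).
#' @param k number of clusters, `2 <= k <= n`.
#' @return An `mm_pam` list: `labels` (1..k, medoid-index order), `medoid_ids`,
#'   `k`, `metric`, `total_cost`.
#' @export
pam_cluster <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  mm_assert(k >= 2 && k <= n, "`k` must satisfy 2 <= k <= n")
  fit <- cpp_pam(d, as.integer(k))
  ids <- colnames(d) %||% as.character(seq_len(n))
  structure(list(labels = as.integer(fit$labels),
                 medoid_ids = ids[fit$medoids],
                 medoid_index = as.integer(fit$medoids),
                 k = as.integer(k),
                 metric = attr(d, "metric"),
                 total_cost = fit$cost,
                 sample_ids = ids),
            class = "mm_pam")
}

#' @export
print.mm_pam <- function(x, ...) {
  cat(sprintf("<mm_pam> k = %d, n = %d, total cost = %.4g\n",
              x$k, length(x$labels), x$total_cost))
  print(table(cluster = x$labels))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean silhouette width
#'
#' \eqn{s(i) = (b_i - a_i)/\max(a_i, b_i)} with \eqn{a_i} the mean distance
#' to the sample's own cluster (excluding itself) and \eqn{b_i} the smallest
#' mean distance to another cluster. Members of singleton clusters contribute
#' \eqn{s(i) = 0}, and the degenerate case \eqn{a_i = b_i = 0} (duplicated
#' points split across clusters) also scores 0.
#'
#' @param d square dissimilarity matrix.
#' @param labels integer cluster labels.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
mean_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  mm_assert(length(labels) == n, "`labels` must have one entry per sample")
  sizes <- table(labels)
  mm_assert(length(sizes) >= 2, "silhouette needs at least two clusters")
  # cluster-wise mean distances: k x n matrix of sums, then divide
  sums <- rowsum(d, group = labels)            # k x n
  lev <- rownames(sums)
  nsz <- as.numeric(sizes[lev])
  s <- numeric(n)
  for (i in seq_len(n)) {
    li <- as.character(labels[i])
    own <- sizes[[li]]
    if (own <= 1) { s[i] <- 0; next }
    a <- sums[li, i] / (own - 1)
    other <- lev[lev != li]
    b <- min(sums[other, i] / nsz[match(other, lev)])
    denom <- max(a, b)
    s[i] <- if (denom > 0) (b - a) / denom else 0
  }
  mean(s)
}

#' Calinski-Harabasz index on a dissimilarity matrix
#'
#' The dissimilarities are embedded by classical principal coordinates
#' (double-centred Gram matrix \eqn{-\frac{1}{2} J d^2 J}; axes with positive
#' eigenvalues kept) and the standard CHI,
#' \eqn{[B/(k-1)]/[W/(n-k)]}, is evaluated on the embedded coordinates. For
#' Euclidean input distances this equals CHI computed directly on the
#' original coordinates.
#'
#' @param d square dissimilarity matrix.
#' @param labels integer cluster labels (at least 2, fewer than n, clusters).
#' @return The Calinski-Harabasz statistic.
#' @export
calinski_harabasz <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  mm_assert(length(labels) == n, "`labels` must have one entry per sample")
  k <- length(unique(labels))
  mm_assert(k >= 2, "CHI needs at least two clusters")
  mm_assert(k < n, "CHI undefined for k = n (zero within-group df)")
  G <- -0.5 * d^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))  # row- then column-centering double-centres
  eg <- eigen(G, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-10
  if (!any(pos)) return(0)
  X <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), sum(pos))
  grand <- colMeans(X)
  W <- 0; B <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    cen <- colMeans(X[idx, , drop = FALSE])
    W <- W + sum(sweep(X[idx, , drop = FALSE], 2, cen)^2)
    B <- B + length(idx) * sum((cen - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Scan candidate cluster numbers
#'
#' Runs [pam_cluster()] for each `k` in `k_range`, recording the mean
#' silhouette and CHI. The chosen `k` maximises the silhouette (ties to the
#' smaller `k`); CHI is reported for inspection.
#'
#' @param d square dissimilarity matrix.
#' @param k_range integer vector of cluster numbers to scan.
#' @return An `mm_kselect` list: `report` tibble (`k`, `silhouette`, `chi`)
#'   and `chosen_k`.
#' @export
select_k <- function(d, k_range = 2:10) {
  d <- as.matrix(d)
  n <- nrow(d)
  k_range <- sort(unique(as.integer(k_range)))
  mm_assert(all(k_range > 1 & k_range < n), "`k_range` must lie in (1, n)")
  rows <- purrr::map_dfr(k_range, function(k) {
    sol <- pam_cluster(d, k)
    tibble::tibble(k = k,
                   silhouette = mean_silhouette(d, sol$labels),
                   chi = calinski_harabasz(d, sol$labels))
  })
  chosen <- rows$k[which.max(rows$silhouette)]
  structure(list(report = rows, chosen_k = chosen), class = "mm_kselect")
}

#' @export
print.mm_kselect <- function(x, ...) {
  cat(sprintf("<mm_kselect> chosen k = %d (max silhouette)\n", x$chosen_k))
  print(x$report)
  invisible(x)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions under the permutation
#' model; 1 for identical partitions up to relabelling, approximately 0 for
#' independent labelings.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  mm_assert(length(labels_a) == length(labels_b) && length(labels_a) >= 2,
            "label vectors must have equal length >= 2")
  tab <- table(labels_a, labels_b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maximum - expected)
}

#' Leave-one-out cluster stability
#'
#' For each sample: drop it, re-select `k` by maximum silhouette, re-run PAM,
#' assign the held-out sample to its minimum-distance medoid (ties to the
#' smallest medoid index), and compare the resulting full-length labelling
#' against the all-sample solution with the ARI (held-out sample included
#' with its assigned label).
#'
#' @param d square dissimilarity matrix.
#' @param full an `mm_pam` solution on all samples.
#' @param k_range candidate cluster numbers per iteration.
#' @return An `mm_stability` list: `iterations` tibble (`held_out`,
#'   `selected_k`, `ari`, `assigned_label`) and `summary` (min/median ARI and
#'   fraction of iterations agreeing with the full solution's k).
#' @export
loo_stability <- function(d, full, k_range = 2:10) {
  d <- as.matrix(d)
  n <- nrow(d)
  mm_assert(n >= 4, "leave-one-out stability needs n >= 4")
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    dsub <- d[-i, -i, drop = FALSE]
    ks <- select_k(dsub, k_range[k_range < n - 1])
    sol <- pam_cluster(dsub, ks$chosen_k)
    # assign the held-out sample to the nearest medoid of the reduced fit
    med_global <- seq_len(n)[-i][sol$medoid_index]
    dist_to_med <- d[i, med_global]
    assigned <- which(dist_to_med == min(dist_to_med))[1]
    lab_full <- integer(n)
    lab_full[-i] <- sol$labels
    lab_full[i] <- assigned
    tibble::tibble(held_out = i, selected_k = ks$chosen_k,
                   assigned_label = as.integer(assigned),
                   ari = adjusted_rand_index(full$labels, lab_full))
  })
  structure(list(
    iterations = rows,
    summary = tibble::tibble(
      min_ari = min(rows$ari),
      median_ari = stats::median(rows$ari),
      k_agreement = mean(rows$selected_k == full$k))),
    class = "mm_stability")
}

#' @export
print.mm_stability <- function(x, ...) {
  cat("<mm_stability>\n")
  print(x$summary)
  invisible(x)
}

#' Rename clusters by decreasing size
#'
#' Re-indexes cluster ids so cluster 1 is the largest; size ties are ordered
#' by the smallest original medoid sample index.
#'
#' @param sol an `mm_pam` solution.
#' @return The solution with relabelled clusters (and reordered medoids).
#' @export
rename_by_size <- function(sol) {
  mm_assert(inherits(sol, "mm_pam"), "`sol` must be an mm_pam object")
  sizes <- tabulate(sol$labels, nbins = sol$k)
  ord <- order(-sizes, sol$medoid_index)
  remap <- integer(sol$k)
  remap[ord] <- seq_len(sol$k)
  sol$labels <- remap[sol$labels]
  sol$medoid_ids <- sol$medoid_ids[ord]
  sol$medoid_index <- sol$medoid_index[ord]
  sol
}
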