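#' Drop samples with low sequencing depth
#'
#' Retains samples whose library size (column sum) is at least `min_reads`,
#' preserving sample order. The default mirrors the common 16S QC cut of
#' 10,000 reads per sample.
#'
#' @param cm an [count_matrix()] object.
#' @param min_reads minimum library size kept (inclusive).
#' @return An `mm_counts` with low-depth samples removed.
#' @export
filter_samples_by_depth <- function(cm, min_reads = 10000) {
  mm_assert(inherits(cm, "mm_counts"), "`cm` must be an mm_counts object")
  mm_assert(min_reads >= 1, "`min_reads` must be >= 1")
  keep <- colSums(cm$counts) >= min_reads
  if (!any(keep)) warning("all samples fall below `min_reads`")
  cm$counts <- cm$counts[, keep, drop = FALSE]
  cm
}

#' Zero out low-abundance cells
#'
#' Per-cell QC: entries with `0 < count < min_copies` are set to zero (a
#' within-sample rule; a taxon kept in one sample may be zeroed in another).
#' Taxa that become all-zero are dropped. With `mode = "drop_taxa"` the whole
#' taxon row is removed whenever any sample has `0 < count < min_copies`.
#'
#' @param cm an [count_matrix()] with integer counts.
#' @param min_copies minimum copies a nonzero cell must have to be kept.
#' @param mode `"zero_cells"` (default) or `"drop_taxa"`.
#' @return An `mm_counts`.
#' @export
zero_low_abundance <- function(cm, min_copies = 10,
                               mode = c("zero_cells", "drop_taxa")) {
  mm_assert(inherits(cm, "mm_counts"), "`cm` must be an mm_counts object")
  mode <- match.arg(mode)
  x <- cm$counts
  mm_assert(all(x == round(x)), "`zero_low_abundance` requires integer counts")
  low <- x > 0 & x < min_copies
  if (mode == "zero_cells") {
    x[low] <- 0
    cm$counts <- x
    subset_taxa(cm, rowSums(x) > 0)
  } else {
    subset_taxa(cm, rowSums(low) == 0)
  }
}

# genus label with "unclassified <lowest resolved rank>" fallback
genus_labels <- function(taxonomy) {
  ranks <- c("family", "order", "class", "phylum", "kingdom")
  out <- as.character(taxonomy$genus)
  for (i in which(is.na(out) | out == "")) {
    lowest <- NA_character_
    for (r in ranks) {
      v <- taxonomy[[r]][i]
      if (!is.na(v) && nzchar(v)) { lowest <- v; break }
    }
    out[i] <- paste("unclassified", ifelse(is.na(lowest), "taxon", lowest))
  }
  out
}

#' Merge OTU rows to the genus level
#'
#' Rows sharing the same genus label are summed; OTUs with no resolved genus
#' are pooled under `"unclassified <lowest resolved rank>"` (for example
#' `"unclassified Neisseriaceae"`). Column sums are unchanged.
#'
#' @param cm an [count_matrix()] with taxonomy.
#' @return An `mm_counts` with one row per genus label and a genus-level
#'   taxonomy (rank columns below genus collapsed to the merged label).
#' @export
merge_to_genus <- function(cm) {
  mm_assert(inherits(cm, "mm_counts"), "`cm` must be an mm_counts object")
  mm_assert(!is.null(cm$taxonomy), "`merge_to_genus` requires taxonomy")
  lab <- genus_labels(cm$taxonomy)
  merged <- rowsum(cm$counts, group = lab, reorder = FALSE)
  tax <- cm$taxonomy
  tax$taxon_id <- lab
  tax$genus <- lab
  tax <- dplyr::distinct(tax, .data$taxon_id, .keep_all = TRUE)
  count_matrix(merged, tax)
}

#' Iterated rarefaction
#'
#' Each iteration draws `L` reads without replacement from every sample
#' (multivariate hypergeometric), where `L` is the minimum library size; the
#' result is the per-cell mean across iterations, so every column sums to `L`
#' while per-cell values are real numbers. Iterating and averaging avoids the
#' extra sampling noise a single rarefaction draw would introduce.
#'
#' @param cm an [count_matrix()] with integer counts.
#' @param iterations number of resampling iterations.
#' @param seed optional integer seed for reproducibility.
#' @return An `mm_counts` of per-cell means.
#' @export
iterated_rarefaction <- function(cm, iterations = 1000, seed = NULL) {
  mm_assert(inherits(cm, "mm_counts"), "`cm` must be an mm_counts object")
  mm_assert(ncol(cm$counts) >= 1, "need at least one sample")
  mm_assert(iterations >= 1, "`iterations` must be >= 1")
  x <- cm$counts
  mm_assert(all(x == round(x)), "rarefaction requires integer counts")
  L <- min(colSums(x))
  mm_assert(L > 0, "minimum library size is zero")
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_rarefy_mean(matrix(as.integer(x), nrow(x), ncol(x)),
                         as.integer(L), as.integer(iterations))
  dimnames(out) <- dimnames(x)
  cm$counts <- out
  cm
}

#' Convert counts to relative abundance
#'
#' @param cm an [count_matrix()] or bare matrix with positive column sums.
#' @return A taxa x samples matrix whose columns sum to one.
#' @export
to_relative_abundance <- function(cm) {
  x <- if (inherits(cm, "mm_counts")) cm$counts else as.matrix(cm)
  cs <- colSums(x)
  mm_assert(all(cs > 0), "all samples must have positive total counts")
  sweep(x, 2, cs, "/")
}

#' Per-sample alpha diversity
#'
#' Richness is the number of taxa with nonzero count; Shannon entropy
#' \eqn{H = -\sum p_i \ln p_i} is reported in nats; Simpson is the
#' Gini-Simpson index \eqn{1 - \sum p_i^2}. Computed on the counts as given
#' (conventionally before rarefaction).
#'
#' @param cm an [count_matrix()].
#' @return A tibble with `sample_id`, `richness`, `shannon`, `simpson`.
#' @export
alpha_diversity <- function(cm) {
  x <- if (inherits(cm, "mm_counts")) cm$counts else as.matrix(cm)
  mm_assert(all(colSums(x) > 0), "all-zero sample in `alpha_diversity`")
  p <- sweep(x, 2, colSums(x), "/")
  shannon <- apply(p, 2, function(q) { q <- q[q > 0]; -sum(q * log(q)) })
  tibble::tibble(
    sample_id = colnames(x),
    richness = as.integer(colSums(x > 0)),
    shannon = unname(shannon),
    simpson = unname(1 - colSums(p^2))
  )
}

#' Prevalence filter
#'
#' Retains taxa detected (nonzero) in at least `ceiling(min_prevalence * n)`
#' samples; the boundary is inclusive, so a taxon present in exactly 15% of
#' samples passes the default filter.
#'
#' @param cm an [count_matrix()].
#' @param min_prevalence required fraction of samples with nonzero count.
#' @return An `mm_counts`.
#' @export
prevalence_filter <- function(cm, min_prevalence = 0.15) {
  mm_assert(inherits(cm, "mm_counts"), "`cm` must be an mm_counts object")
  mm_assert(min_prevalence > 0 && min_prevalence <= 1,
            "`min_prevalence` must be in (0, 1]")
  need <- ceiling(min_prevalence * ncol(cm$counts))
  subset_taxa(cm, rowSums(cm$counts > 0) >= need)
}

#' Per-cluster median relative abundance
#'
#' Summarises community profiles by cluster: the median across samples of
#' each taxon's relative abundance, optionally aggregated to a higher rank
#' (per-sample proportions are summed within the rank before taking medians).
#'
#' @param ra taxa x samples relative-abundance matrix
#'   (see [to_relative_abundance()]).
#' @param labels per-sample cluster labels aligned with `ra` columns.
#' @param taxonomy optional taxonomy table (`taxon_id` plus rank columns) used
#'   for the higher-rank aggregation.
#' @param higher_rank rank to aggregate to when taxonomy is given.
#' @return A tibble with `cluster`, `rank`, `taxon`, `median_ra`.
#' @export
cluster_profile_summary <- function(ra, labels, taxonomy = NULL,
                                    higher_rank = "phylum") {
  ra <- as.matrix(ra)
  mm_assert(length(labels) == ncol(ra),
            "`labels` must align with the samples of `ra`")
  per_rank <- function(mat, rank_name) {
    purrr::map_dfr(split(seq_along(labels), labels), function(idx) {
      med <- apply(mat[, idx, drop = FALSE], 1, stats::median)
      tibble::tibble(cluster = labels[idx[1]], rank = rank_name,
                     taxon = rownames(mat), median_ra = unname(med))
    })
  }
  out <- per_rank(ra, "taxon")
  if (!is.null(taxonomy)) {
    grp <- taxonomy[[higher_rank]][match(rownames(ra), taxonomy$taxon_id)]
    grp[is.na(grp)] <- "unclassified"
    hi <- rowsum(ra, group = grp, reorder = FALSE)
    out <- dplyr::bind_rows(out, per_rank(hi, higher_rank))
  }
  out
}
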