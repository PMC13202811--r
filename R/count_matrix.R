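#' Taxa-by-sample count container
#'
#' Bundles a taxa x samples count matrix with an optional taxonomy table.
#' Counts are integers before rarefaction and reals after iterated
#' rarefaction (per-cell means are not re-rounded).
#'
#' @param counts numeric matrix, taxa in rows, samples in columns. Row and
#'   column names are used as taxon and sample identifiers.
#' @param taxonomy optional data frame with a `taxon_id` column plus rank
#'   columns `kingdom`, `phylum`, `class`, `order`, `family`, `genus`
#'   (unresolved ranks as `NA`).
#' @return An object of class `mm_counts`.
#' @export
count_matrix <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  mm_assert(is.numeric(counts), "`counts` must be a numeric matrix")
  mm_assert(all(counts >= 0), "`counts` must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("taxon_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  mm_assert(!anyDuplicated(rownames(counts)), "taxon ids must be unique")
  mm_assert(!anyDuplicated(colnames(counts)), "sample ids must be unique")
  if (!is.null(taxonomy)) {
    taxonomy <- tibble::as_tibble(taxonomy)
    mm_assert("taxon_id" %in% names(taxonomy),
              "`taxonomy` must have a `taxon_id` column")
    taxonomy <- taxonomy[match(rownames(counts), taxonomy$taxon_id), ]
    mm_assert(!anyNA(taxonomy$taxon_id),
              "all count rows must appear in `taxonomy`")
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "mm_counts")
}

#' @export
print.mm_counts <- function(x, ...) {
  cat(sprintf("<mm_counts> %d taxa x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "" else " (with taxonomy)"))
  invisible(x)
}

#' @export
dim.mm_counts <- function(x) dim(x$counts)

sample_ids <- function(cm) colnames(cm$counts)
taxon_ids <- function(cm) rownames(cm$counts)

# keep taxonomy aligned after subsetting rows
subset_taxa <- function(cm, keep) {
  cm$counts <- cm$counts[keep, , drop = FALSE]
  if (!is.null(cm$taxonomy))
    cm$taxonomy <- cm$taxonomy[match(rownames(cm$counts), cm$taxonomy$taxon_id), ]
  cm
}
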