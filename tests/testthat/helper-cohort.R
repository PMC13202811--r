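# shared fixture builders (generated in code; nothing is stored on disk)

# tiny deterministic count matrix with taxonomy for prep-level tests
tiny_counts <- function() {
  x <- matrix(c(30, 5, 0,
                12, 40, 9,
                0, 11, 25,
                3, 0, 18), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("otu", 1:4), paste0("s", 1:3)))
  tax <- tibble::tibble(
    taxon_id = paste0("otu", 1:4),
    kingdom = "Bacteria",
    phylum = c("Actinobacteria", "Actinobacteria", "Firmicutes",
               "Proteobacteria"),
    class = NA_character_, order = NA_character_,
    family = c(NA, NA, NA, "Neisseriaceae"),
    genus = c("Corynebacterium", "Corynebacterium", "Staphylococcus", NA))
  count_matrix(x, tax)
}

# well-separated two-blob distance matrix (two tight pairs)
two_pairs_dist <- function() {
  x <- rbind(c(0, 0), c(0, 0.1), c(10, 10), c(10, 10.1))
  as.matrix(dist(x))
}

# small cohort for integration-style tests
small_cohort <- function(seed = 1, n = 120, n_cpgs = 400, ...) {
  simulate_cohort(cohort_params(seed = seed, n_samples = n, n_cpgs = n_cpgs,
                                ...))
}

# a strictly null cohort: no planted effects anywhere (the clock's taxon
# effect is zeroed so no CpG carries cluster-correlated signal)
null_cohort <- function(seed = 1, n = 120, n_cpgs = 400) {
  simulate_cohort(cohort_params(seed = seed, n_samples = n, n_cpgs = n_cpgs,
                                planted_dmps = NULL, taxon_links = NULL,
                                ead_taxon_slope = 0))
}

genus_labels_for_test <- function(cm) micromethyl:::genus_labels(cm$taxonomy)

# genus-level prevalence-filtered counts + design covariates from a cohort
cohort_da_inputs <- function(coh, refactor = FALSE) {
  cm <- zero_low_abundance(filter_samples_by_depth(coh$counts))
  gen <- prevalence_filter(merge_to_genus(cm))
  rf <- if (refactor) refactor_components(coh$beta, k = 5, t = 200) else NULL
  X <- build_design(coh$covariates, coh$truth$labels, refactor = rf)
  list(genus = gen, design = X,
       covs = X[, -attr(X, "cluster_cols"), drop = FALSE])
}
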