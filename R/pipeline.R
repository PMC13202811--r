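#' Pipeline configuration
#'
#' Collects input paths and analysis switches for [run_pipeline()]. Any
#' switch left at its default mirrors the package's standard workflow:
#' JSD-based PAM with k = 6, 1,000 rarefaction iterations, empirical-Bayes
#' moderated robust EWAS with Bonferroni control over all CpG x contrast
#' tests, 500 label permutations, pseudo-counts {0.1, 0.5, 1}.
#'
#' @param counts,taxonomy,beta,covariates,clock input file paths (TSV/CSV, see
#'   [read_inputs()]).
#' @param out_dir output directory for [write_results()]; `NULL` to skip
#'   writing.
#' @param seed integer seed driving every stochastic stage.
#' @param k number of microbiome clusters.
#' @param metric beta-diversity metric for clustering.
#' @param rarefaction_iterations iterations of resampling at minimum depth.
#' @param min_reads,min_copies,min_prevalence QC thresholds.
#' @param n_refactor,refactor_t ReFACTor components and selected sites.
#' @param alpha significance level.
#' @param permutations EWAS label permutations (0 to skip).
#' @param pseudo_counts pseudo-count array for differential abundance.
#' @param winsorize run the winsorized EWAS sensitivity re-run.
#' @param moderate empirical-Bayes moderation on/off.
#' @param loo run leave-one-out cluster stability (expensive).
#' @param k_range k-selection scan range.
#' @param extra_covariates optional extra design columns (e.g. medication).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, taxonomy = NULL, beta = NULL,
                            covariates = NULL, clock = NULL, out_dir = NULL,
                            seed = 1L, k = 6, metric = "jsd",
                            rarefaction_iterations = 1000,
                            min_reads = 10000, min_copies = 10,
                            min_prevalence = 0.15, n_refactor = 10,
                            refactor_t = 500, alpha = 0.05,
                            permutations = 500,
                            pseudo_counts = c(0.1, 0.5, 1.0),
                            winsorize = TRUE, moderate = TRUE, loo = FALSE,
                            k_range = 2:10, extra_covariates = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read the pipeline inputs
#'
#' Reads the counts TSV (first column `taxon_id`), taxonomy TSV, Beta TSV
#' (first column `cpg_id`), covariates CSV and clock CSV, validates types
#' (integer counts, Beta strictly in (0,1)), and intersects sample ids across
#' inputs (dropped samples are reported with a message; an empty intersection
#' is an error).
#'
#' @param config a [pipeline_config()] with file paths set.
#' @return A list: `counts` ([count_matrix()]), `beta` (matrix),
#'   `covariates` (tibble), `clock` (`mm_clock` or `NULL`).
#' @export
read_inputs <- function(config) {
  counts_df <- readr::read_tsv(config$counts, show_col_types = FALSE)
  x <- as.matrix(counts_df[, -1])
  rownames(x) <- counts_df[[1]]
  mm_assert(all(x == round(x)) && all(x >= 0),
            "counts must be non-negative integers")
  if (max(x) < .Machine$integer.max) storage.mode(x) <- "integer"
  taxonomy <- if (!is.null(config$taxonomy))
    readr::read_tsv(config$taxonomy, show_col_types = FALSE) else NULL
  beta_df <- readr::read_tsv(config$beta, show_col_types = FALSE)
  b <- as.matrix(beta_df[, -1])
  rownames(b) <- beta_df[[1]]
  bad <- which(!(b > 0 & b < 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("Beta value out of (0,1) at CpG %s, sample %s",
                 rownames(b)[bad[1, 1]], colnames(b)[bad[1, 2]]),
         call. = FALSE)
  cov <- readr::read_csv(config$covariates, show_col_types = FALSE)
  cov$race <- factor(cov$race)
  cov$batch <- factor(cov$batch)
  clock <- NULL
  if (!is.null(config$clock)) {
    cdf <- readr::read_csv(config$clock, show_col_types = FALSE)
    ic <- cdf$weight[cdf$cpg_id == "(Intercept)"]
    aa <- cdf$weight[cdf$cpg_id == "(AdultAge)"]
    w <- cdf[!cdf$cpg_id %in% c("(Intercept)", "(AdultAge)"), ]
    clock <- clock_definition(ic, stats::setNames(w$weight, w$cpg_id),
                              adult_age = if (length(aa)) aa else 20)
  }
  ids <- Reduce(intersect, list(colnames(x), colnames(b), cov$sample_id))
  mm_assert(length(ids) > 0, "no samples shared across inputs")
  dropped <- length(union(colnames(x), union(colnames(b), cov$sample_id))) -
    length(ids)
  if (dropped > 0)
    message(dropped, " sample(s) dropped when intersecting inputs")
  list(counts = count_matrix(x[, ids, drop = FALSE], taxonomy),
       beta = b[, ids, drop = FALSE],
       covariates = cov[match(ids, cov$sample_id), ],
       clock = clock)
}

#' Run the full integration pipeline
#'
#' Executes, in order: depth/abundance QC, alpha diversity (pre-rarefaction),
#' iterated rarefaction, genus merging, beta-diversity distances, PAM
#' clustering with size-ranked naming (and optional k-selection scan and
#' leave-one-out stability), ReFACTor components, the moderated robust EWAS
#' with all pairwise cluster contrasts, global significance and inflation
#' diagnostics, a winsorized sensitivity re-run, the permutation empirical
#' null, differential abundance for each DMP, and the epigenetic-clock /
#' age-deviation analyses.
#'
#' @param config a [pipeline_config()]; either file paths or an `inputs` list
#'   as returned by [read_inputs()] must be supplied.
#' @param inputs optional pre-loaded inputs (bypasses file reading).
#' @return An `mm_results` list of per-stage results plus a `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL) {
  t0 <- Sys.time()
  if (is.null(inputs)) inputs <- read_inputs(config)
  set.seed(config$seed)
  log_lines <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  cm <- inputs$counts
  note("input: %d taxa x %d samples", nrow(cm$counts), ncol(cm$counts))
  cm <- filter_samples_by_depth(cm, config$min_reads)
  cm <- zero_low_abundance(cm, config$min_copies)
  ids <- sample_ids(cm)
  beta <- inputs$beta[, ids, drop = FALSE]
  cov <- inputs$covariates[match(ids, inputs$covariates$sample_id), ]
  note("post-QC: %d taxa x %d samples", nrow(cm$counts), ncol(cm$counts))

  alpha_div <- alpha_diversity(cm)
  rare <- iterated_rarefaction(cm, config$rarefaction_iterations,
                               seed = config$seed + 1L)
  genus_rare <- merge_to_genus(rare)
  ra <- to_relative_abundance(genus_rare)
  d <- pairwise_distance(ra, config$metric)

  kreport <- select_k(d, config$k_range)
  sol <- rename_by_size(pam_cluster(d, config$k))
  note("PAM k = %d (silhouette-chosen k = %d)", config$k, kreport$chosen_k)
  stability <- if (config$loo) loo_stability(d, sol, config$k_range) else NULL
  profile <- cluster_profile_summary(ra, sol$labels,
                                     taxonomy = genus_rare$taxonomy)

  refactor <- refactor_components(beta, k = config$n_refactor,
                                  t = config$refactor_t)
  design <- build_design(cov, sol$labels, refactor = refactor,
                         extra = config$extra_covariates)
  m <- beta_to_m(beta)
  fit <- robust_fit(m, design)
  if (config$moderate) fit <- ebayes_moderate(fit)
  contrasts <- adjust_contrasts(pairwise_contrasts(fit), config$alpha)
  pm <- matrix(contrasts$p, nrow = nrow(m),
               dimnames = list(fit$cpg_ids, unique(contrasts$contrast)))
  tm <- matrix(contrasts$t, nrow = nrow(m))
  global <- global_significance(pm, config$alpha)
  note("EWAS: %d DMPs at Bonferroni %.3g", global$n_dmps, global$threshold)
  inflation <- if (nrow(pm) >= 1000) inflation_report(pm, tm) else NULL

  winsor <- NULL
  if (config$winsorize) {
    fit_w <- robust_fit(winsorize_m(m), design)
    if (config$moderate) fit_w <- ebayes_moderate(fit_w)
    winsor <- adjust_contrasts(pairwise_contrasts(fit_w), config$alpha)
  }

  perm <- NULL
  if (config$permutations > 0) {
    perm <- permutation_null(m, cov, sol$labels, refactor = refactor,
                             extra = config$extra_covariates,
                             B = config$permutations,
                             seed = config$seed + 2L, alpha = config$alpha)
    note("permutation null: empirical p = %.4g", perm$empirical_p)
  }

  genus_cm <- prevalence_filter(merge_to_genus(cm), config$min_prevalence)
  note("differential abundance over %d taxa", nrow(genus_cm$counts))
  da_covariates <- design[, -attr(design, "cluster_cols"), drop = FALSE]
  dmp_ids <- fit$cpg_ids[global$dmp]
  da <- da_for_dmps(genus_cm, m, dmp_ids, covariates = da_covariates,
                    pseudo_counts = config$pseudo_counts,
                    alpha = config$alpha)

  epiage <- ead_contrasts <- ead_taxa <- NULL
  if (!is.null(inputs$clock)) {
    ages <- apply_clock(beta, inputs$clock)
    epiage <- compute_ead(ages, cov$age)
    # EAD models adjust for the covariates but not cell-composition surrogates
    ead_design <- build_design(cov, sol$labels,
                               extra = config$extra_covariates)
    ead_cov <- ead_design[, -attr(ead_design, "cluster_cols"), drop = FALSE]
    ead_contrasts <- ead_cluster_contrasts(epiage, sol$labels, ead_cov)
    ead_taxa <- ead_taxa_association(genus_cm, epiage, covariates = ead_cov,
                                     pseudo_counts = config$pseudo_counts,
                                     alpha = config$alpha)
  }

  manifest <- list(
    seed = config$seed, k = config$k, metric = config$metric,
    n_samples = ncol(beta), n_taxa = nrow(cm$counts),
    n_genera_tested = nrow(genus_cm$counts), n_cpgs = nrow(m),
    bonferroni_threshold = global$threshold, n_dmps = global$n_dmps,
    chosen_k = kreport$chosen_k,
    permutation_p = if (!is.null(perm)) perm$empirical_p else NA,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    log = log_lines)

  res <- structure(list(
    alpha_diversity = alpha_div, k_selection = kreport, clusters = sol,
    stability = stability, cluster_profiles = profile, refactor = refactor,
    ewas_fit = fit, contrasts = contrasts, global = global,
    inflation = inflation, winsorized_contrasts = winsor, permutation = perm,
    da = da, epiage = epiage, ead_contrasts = ead_contrasts,
    ead_taxa = ead_taxa, manifest = manifest), class = "mm_results")
  if (!is.null(config$out_dir)) write_results(res, config$out_dir)
  res
}

#' @export
print.mm_results <- function(x, ...) {
  cat("<mm_results>\n")
  for (l in x$manifest$log) cat(" ", l, "\n")
  invisible(x)
}

fmt_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, format = "g", digits = 6))
  readr::write_tsv(df, path)
}

#' Write pipeline results as TSV tables and a JSON manifest
#'
#' @param res an `mm_results` from [run_pipeline()].
#' @param out_dir output directory (created if needed). Numeric columns are
#'   written with a fixed `%.6g` format so re-runs diff cleanly.
#' @return Invisibly, the files written.
#' @export
write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  fmt_tsv(tibble::tibble(sample_id = res$clusters$sample_ids,
                         cluster = res$clusters$labels),
          p("cluster_assignments.tsv"))
  fmt_tsv(res$k_selection$report, p("k_selection.tsv"))
  fmt_tsv(res$alpha_diversity, p("alpha_diversity.tsv"))
  fmt_tsv(res$cluster_profiles, p("cluster_profiles.tsv"))
  fmt_tsv(res$contrasts, p("ewas_contrasts.tsv"))
  if (!is.null(res$inflation)) fmt_tsv(res$inflation, p("inflation.tsv"))
  if (!is.null(res$stability))
    fmt_tsv(res$stability$iterations, p("loo_stability.tsv"))
  if (!is.null(res$winsorized_contrasts))
    fmt_tsv(res$winsorized_contrasts, p("ewas_contrasts_winsorized.tsv"))
  if (!is.null(res$permutation))
    fmt_tsv(tibble::tibble(observed = res$permutation$observed,
                           B = res$permutation$B,
                           empirical_p = res$permutation$empirical_p),
            p("permutation_summary.tsv"))
  fmt_tsv(res$da, p("da_results.tsv"))
  if (!is.null(res$epiage)) {
    fmt_tsv(res$epiage$table, p("epigenetic_age.tsv"))
    fmt_tsv(res$ead_contrasts, p("ead_cluster_contrasts.tsv"))
    fmt_tsv(res$ead_taxa, p("ead_taxa.tsv"))
  }
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list.files(out_dir, full.names = TRUE))
}
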