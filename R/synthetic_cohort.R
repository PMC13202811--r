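#' Built-in nasal community archetypes
#'
#' Six genus-level mean relative-abundance profiles emulating the common
#' anterior-nares community types of adolescents: (1) Corynebacterium
#' dominant, (2) Propionibacterium dominant, (3) Staphylococcus dominant,
#' (4) mixed Staphylococcus/Streptococcus with high diversity, (5)
#' unclassified Neisseriaceae dominant, (6) Moraxella dominant. Twenty named
#' genera carry the archetype-defining mass; thirty minor genera share the
#' remaining mass with geometrically decaying weights.
#'
#' @return A list with `profiles` (genus x 6 matrix, columns summing to 1)
#'   and `taxonomy` (genus-level tibble; unresolved genera have `NA` genus).
#' @export
nasal_archetypes <- function() {
  major <- c("Corynebacterium", "Propionibacterium", "Staphylococcus",
             "Streptococcus", "uncl_Neisseriaceae", "Moraxella",
             "Dolosigranulum", "Haemophilus", "Peptoniphilus", "Anaerococcus",
             "uncl_Actinomycetales", "Lactobacillus", "Prevotella",
             "Veillonella", "Neisseria", "Finegoldia", "Micrococcus",
             "Gemella", "Pseudomonas", "Alloiococcus")
  P <- matrix(c(
    # C1     C2     C3     C4     C5     C6
    0.670, 0.180, 0.080, 0.050, 0.060, 0.080,  # Corynebacterium
    0.080, 0.550, 0.060, 0.040, 0.040, 0.040,  # Propionibacterium
    0.070, 0.060, 0.650, 0.140, 0.060, 0.060,  # Staphylococcus
    0.030, 0.020, 0.050, 0.160, 0.080, 0.030,  # Streptococcus
    0.005, 0.005, 0.005, 0.020, 0.380, 0.040,  # uncl Neisseriaceae
    0.010, 0.005, 0.010, 0.020, 0.050, 0.570,  # Moraxella
    0.040, 0.010, 0.020, 0.060, 0.020, 0.020,  # Dolosigranulum
    0.005, 0.005, 0.010, 0.050, 0.060, 0.050,  # Haemophilus
    0.010, 0.020, 0.010, 0.020, 0.010, 0.005,  # Peptoniphilus
    0.010, 0.020, 0.010, 0.020, 0.010, 0.005,  # Anaerococcus
    0.010, 0.040, 0.010, 0.020, 0.010, 0.005,  # uncl Actinomycetales
    0.005, 0.005, 0.005, 0.015, 0.010, 0.005,  # Lactobacillus
    0.005, 0.005, 0.005, 0.040, 0.020, 0.010,  # Prevotella
    0.005, 0.005, 0.005, 0.040, 0.020, 0.010,  # Veillonella
    0.002, 0.002, 0.005, 0.030, 0.040, 0.020,  # Neisseria
    0.008, 0.010, 0.008, 0.015, 0.008, 0.005,  # Finegoldia
    0.005, 0.020, 0.005, 0.010, 0.005, 0.005,  # Micrococcus
    0.005, 0.003, 0.007, 0.040, 0.020, 0.010,  # Gemella
    0.002, 0.002, 0.002, 0.010, 0.020, 0.010,  # Pseudomonas
    0.013, 0.008, 0.013, 0.020, 0.007, 0.005), # Alloiococcus
    nrow = 20, byrow = TRUE, dimnames = list(major, paste0("C", 1:6)))
  minor <- c("Rothia", "Fusobacterium", "Porphyromonas", "Actinomyces",
             "Granulicatella", "Kocuria", "Enhydrobacter", "Acinetobacter",
             "Sphingomonas", "Bacillus", "Abiotrophia", "Leptotrichia",
             "Capnocytophaga", "Bergeyella", "Campylobacter", "Selenomonas",
             "Atopobium", "Bifidobacterium", "Brevibacterium", "Dermacoccus",
             "Enterococcus", "Escherichia", "Klebsiella", "Megasphaera",
             "Mogibacterium", "Oribacterium", "Parvimonas", "Solobacterium",
             "Stenotrophomonas", "Lachnoanaerobaculum")
  tailw <- 0.85^seq_along(minor)
  tailw <- tailw / sum(tailw)
  Pm <- outer(tailw, 1 - colSums(P))
  rownames(Pm) <- minor
  profiles <- rbind(P, Pm)

  phylum <- c(
    Corynebacterium = "Actinobacteria", Propionibacterium = "Actinobacteria",
    Staphylococcus = "Firmicutes", Streptococcus = "Firmicutes",
    uncl_Neisseriaceae = "Proteobacteria", Moraxella = "Proteobacteria",
    Dolosigranulum = "Firmicutes", Haemophilus = "Proteobacteria",
    Peptoniphilus = "Firmicutes", Anaerococcus = "Firmicutes",
    uncl_Actinomycetales = "Actinobacteria", Lactobacillus = "Firmicutes",
    Prevotella = "Bacteroidetes", Veillonella = "Firmicutes",
    Neisseria = "Proteobacteria", Finegoldia = "Firmicutes",
    Micrococcus = "Actinobacteria", Gemella = "Firmicutes",
    Pseudomonas = "Proteobacteria", Alloiococcus = "Firmicutes",
    Rothia = "Actinobacteria", Fusobacterium = "Fusobacteria",
    Porphyromonas = "Bacteroidetes", Actinomyces = "Actinobacteria",
    Granulicatella = "Firmicutes", Kocuria = "Actinobacteria",
    Enhydrobacter = "Proteobacteria", Acinetobacter = "Proteobacteria",
    Sphingomonas = "Proteobacteria", Bacillus = "Firmicutes",
    Abiotrophia = "Firmicutes", Leptotrichia = "Fusobacteria",
    Capnocytophaga = "Bacteroidetes", Bergeyella = "Bacteroidetes",
    Campylobacter = "Proteobacteria", Selenomonas = "Firmicutes",
    Atopobium = "Actinobacteria", Bifidobacterium = "Actinobacteria",
    Brevibacterium = "Actinobacteria", Dermacoccus = "Actinobacteria",
    Enterococcus = "Firmicutes", Escherichia = "Proteobacteria",
    Klebsiella = "Proteobacteria", Megasphaera = "Firmicutes",
    Mogibacterium = "Firmicutes", Oribacterium = "Firmicutes",
    Parvimonas = "Firmicutes", Solobacterium = "Firmicutes",
    Stenotrophomonas = "Proteobacteria", Lachnoanaerobaculum = "Firmicutes")
  gn <- rownames(profiles)
  taxonomy <- tibble::tibble(
    taxon_id = gn,
    kingdom = "Bacteria",
    phylum = unname(phylum[gn]),
    class = NA_character_,
    order = ifelse(gn == "uncl_Actinomycetales", "Actinomycetales",
                   NA_character_),
    family = ifelse(gn == "uncl_Neisseriaceae", "Neisseriaceae",
                    NA_character_),
    genus = ifelse(grepl("^uncl_", gn), NA_character_, gn))
  list(profiles = profiles, taxonomy = taxonomy)
}

#' Parameters for a synthetic microbiome-methylome cohort
#'
#' Defaults encode the emulated study population: 372 adolescents in six
#' community clusters with relative sizes 120/83/79/41/33/16, library sizes
#' log-uniform between 10,000 and 50,000 reads, Dirichlet-multinomial
#' within-cluster dispersion (concentration 50), and covariate moments
#' matching the cohort table (age 13.0 (0.7) years, BMI z 0.44 (1.10), 51%
#' female, 69% college-educated mothers).
#'
#' @param n_samples cohort size.
#' @param cluster_weights six non-negative weights summing to 1.
#' @param dirichlet_concentration within-cluster Dirichlet concentration.
#' @param depth_range (min, max) library size.
#' @param n_cpgs number of simulated CpGs.
#' @param planted_dmps data frame (`cpg`, `cluster_a`, `cluster_b`,
#'   `delta_m`): cluster `cluster_a` is shifted by `delta_m` at that CpG (its
#'   contrast against `cluster_b` is the recorded target). `NULL` for none.
#' @param taxon_links data frame (`cpg`, `genus`, `slope`): M values gain
#'   `slope * x` with `x` the centered `log(relative abundance + 1e-6)` of
#'   the genus. `NULL` for none.
#' @param noise_sd residual SD of M values.
#' @param baseline_means,baseline_sds,baseline_weights the 3-component
#'   (hypo/hemi/hyper-methylated) baseline mixture on the M scale.
#' @param cell_factor_prop,cell_factor_sd fraction of CpGs loading on the
#'   latent cell-composition factor, and the loading SD.
#' @param clock_sites number of CpGs carrying the synthetic epigenetic clock.
#' @param ead_noise_sd SD (years) of the epigenetic-age deviation noise.
#' @param ead_taxon_genus,ead_taxon_slope genus whose centered log relative
#'   abundance shifts epigenetic age, and the slope (years per log unit).
#' @param adult_age the clock transform's knot (years).
#' @param seed integer seed; all generation is reproducible given it.
#' @return An object of class `mm_cohort_params`.
#' @export
cohort_params <- function(n_samples = 372,
                          cluster_weights = c(120, 83, 79, 41, 33, 16) / 372,
                          dirichlet_concentration = 50,
                          depth_range = c(10000, 50000),
                          n_cpgs = 2000,
                          planted_dmps = NULL,
                          taxon_links = NULL,
                          noise_sd = 0.3,
                          baseline_means = c(-3, 0, 3),
                          baseline_sds = c(1, 0.5, 1),
                          baseline_weights = c(0.4, 0.2, 0.4),
                          cell_factor_prop = 0.2,
                          cell_factor_sd = 0.5,
                          clock_sites = 30,
                          ead_noise_sd = 3.5,
                          ead_taxon_genus = "Corynebacterium",
                          ead_taxon_slope = -2,
                          adult_age = 20,
                          seed = 1L) {
  mm_assert(n_samples > 0, "`n_samples` must be positive")
  mm_assert(length(cluster_weights) == 6 && all(cluster_weights >= 0),
            "`cluster_weights` must be 6 non-negative reals")
  mm_assert(abs(sum(cluster_weights) - 1) < 1e-12,
            "`cluster_weights` must sum to 1")
  mm_assert(dirichlet_concentration > 0,
            "`dirichlet_concentration` must be positive")
  mm_assert(depth_range[1] >= 1 && depth_range[2] >= depth_range[1],
            "`depth_range` must be increasing positive integers")
  mm_assert(clock_sites >= 1, "`clock_sites` must be >= 1")
  mm_assert(clock_sites <= n_cpgs, "`clock_sites` cannot exceed `n_cpgs`")
  if (!is.null(planted_dmps)) {
    planted_dmps <- tibble::as_tibble(planted_dmps)
    mm_assert(all(c("cpg", "cluster_a", "cluster_b", "delta_m") %in%
                    names(planted_dmps)), "malformed `planted_dmps`")
    mm_assert(all(planted_dmps$cpg >= 1 & planted_dmps$cpg <= n_cpgs),
              "planted CpG index out of range")
    mm_assert(all(is.finite(planted_dmps$delta_m)),
              "planted delta_m must be finite")
  }
  if (!is.null(taxon_links)) {
    taxon_links <- tibble::as_tibble(taxon_links)
    mm_assert(all(c("cpg", "genus", "slope") %in% names(taxon_links)),
              "malformed `taxon_links`")
    mm_assert(all(taxon_links$cpg >= 1 & taxon_links$cpg <= n_cpgs),
              "taxon-link CpG index out of range")
  }
  structure(list(
    n_samples = as.integer(n_samples), cluster_weights = cluster_weights,
    dirichlet_concentration = dirichlet_concentration,
    depth_range = as.integer(depth_range), n_cpgs = as.integer(n_cpgs),
    planted_dmps = planted_dmps, taxon_links = taxon_links,
    noise_sd = noise_sd, baseline_means = baseline_means,
    baseline_sds = baseline_sds, baseline_weights = baseline_weights,
    cell_factor_prop = cell_factor_prop, cell_factor_sd = cell_factor_sd,
    clock_sites = as.integer(clock_sites), ead_noise_sd = ead_noise_sd,
    ead_taxon_genus = ead_taxon_genus, ead_taxon_slope = ead_taxon_slope,
    adult_age = adult_age, seed = as.integer(seed)),
    class = "mm_cohort_params")
}

#' Simulate the covariate table
#'
#' Sex ~ Bernoulli(0.511), age ~ Normal(13.0, 0.7) years, BMI z-score ~
#' Normal(0.44, 1.10), race/ethnicity categorical with cohort proportions,
#' maternal education ~ Bernoulli(0.694), collection day-of-year uniform on
#' 1..365, and four sequencing batches.
#'
#' @param params an [cohort_params()] object.
#' @return A tibble with one row per sample.
#' @export
generate_covariates <- function(params) {
  n <- params$n_samples
  mm_assert(n > 0, "`n_samples` must be positive")
  if (n < 12) warning("fewer than 12 samples; clusters may be empty")
  race_levels <- c("Asian", "Black", "Hispanic", "White", "Other")
  race_probs <- c(0.019, 0.153, 0.094, 0.669, 0.065)
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    sex = stats::rbinom(n, 1, 0.511),
    age = stats::rnorm(n, 13.0, 0.7),
    bmi_z = stats::rnorm(n, 0.44, 1.10),
    race = factor(sample(race_levels, n, TRUE, race_probs / sum(race_probs)),
                  levels = race_levels),
    education = stats::rbinom(n, 1, 0.694),
    day_of_year = sample.int(365, n, replace = TRUE),
    batch = factor(sample(paste0("B", 1:4), n, TRUE)))
}

# split a genus count vector into its OTUs with fixed within-genus weights
otu_layout <- function(profiles) {
  mx <- apply(profiles, 1, max)
  n_otus <- ifelse(mx >= 0.10, 3L, ifelse(mx >= 0.02, 2L, 1L))
  splits <- list(`1` = 1, `2` = c(0.7, 0.3), `3` = c(0.6, 0.3, 0.1))
  genus <- rep(rownames(profiles), n_otus)
  w <- unlist(splits[as.character(n_otus)], use.names = FALSE)
  tibble::tibble(otu_id = sprintf("OTU_%03d", seq_along(genus)),
                 genus_row = genus, weight = w)
}

#' Simulate OTU counts with cluster structure
#'
#' Each sample is assigned a community archetype with the configured cluster
#' weights; its genus proportions are drawn from a Dirichlet with
#' concentration x archetype means, its library size from a discrete
#' log-uniform over `depth_range`, and reads from a multinomial. Genus counts
#' are then split over 1-3 OTUs with fixed within-genus weights so the OTU
#' table exercises genus merging downstream.
#'
#' @param cov covariate table from [generate_covariates()].
#' @param params an [cohort_params()] object.
#' @return A list: `counts` (OTU-level [count_matrix()] with taxonomy) and
#'   `labels` (true archetype per sample).
#' @export
generate_otu_counts <- function(cov, params) {
  mm_assert(params$dirichlet_concentration > 0,
            "`dirichlet_concentration` must be positive")
  arch <- nasal_archetypes()
  n <- nrow(cov)
  labels <- sample.int(6, n, replace = TRUE, prob = params$cluster_weights)
  depths <- round(exp(stats::runif(n, log(params$depth_range[1]),
                                   log(params$depth_range[2]))))
  G <- nrow(arch$profiles)
  genus_counts <- matrix(0L, G, n,
                         dimnames = list(rownames(arch$profiles),
                                         cov$sample_id))
  conc <- params$dirichlet_concentration
  for (i in seq_len(n)) {
    alpha <- conc * arch$profiles[, labels[i]]
    g <- stats::rgamma(G, shape = alpha)
    if (sum(g) == 0) g[which.max(alpha)] <- 1
    genus_counts[, i] <- stats::rmultinom(1, depths[i], g / sum(g))
  }
  layout <- otu_layout(arch$profiles)
  otu_counts <- matrix(0L, nrow(layout), n,
                       dimnames = list(layout$otu_id, cov$sample_id))
  for (g in rownames(arch$profiles)) {
    rows <- which(layout$genus_row == g)
    if (length(rows) == 1) {
      otu_counts[rows, ] <- genus_counts[g, ]
    } else {
      w <- layout$weight[rows]
      for (i in seq_len(n)) {
        cnt <- genus_counts[g, i]
        if (cnt > 0) otu_counts[rows, i] <- stats::rmultinom(1, cnt, w)
      }
    }
  }
  tax <- arch$taxonomy[match(layout$genus_row, arch$taxonomy$taxon_id), ]
  tax$taxon_id <- layout$otu_id
  list(counts = count_matrix(otu_counts, tax), labels = labels)
}

# centered log relative abundance of one genus (after genus merging)
centered_log_ra <- function(counts, genus) {
  genus_cm <- merge_to_genus(counts)
  ra <- to_relative_abundance(genus_cm)
  lab <- rownames(ra)
  # generator genera with unresolved genus rank merge under their label
  hit <- match(genus, lab)
  if (is.na(hit) && grepl("^uncl_", genus))
    hit <- match(sub("^uncl_", "unclassified ", genus), lab)
  mm_assert(!is.na(hit), paste("genus", genus, "not present in counts"))
  x <- log(ra[hit, ] + 1e-6)
  x - mean(x)
}

#' Simulate methylation with planted structure
#'
#' Baseline per-CpG M means come from a hypo/hemi/hyper-methylated mixture;
#' CpGs carrying planted effects are drawn from the hemi component so
#' Beta-scale effect sizes are interpretable. Sample-level M values add the
#' planted cluster shifts, taxon-linked terms (slope x centered log relative
#' abundance), a latent cell-composition factor, and Gaussian noise; Beta
#' values are the inverse logit2 and are strictly inside (0,1). A synthetic
#' linear clock is written into `clock_sites` CpGs such that applying it
#' recovers `age + noise + taxon effect` exactly (see the returned truth).
#'
#' @param cov covariate table.
#' @param labels true cluster labels.
#' @param counts OTU-level [count_matrix()] (used for taxon links and the
#'   epigenetic-age taxon effect).
#' @param params an [cohort_params()] object.
#' @return A list: `beta` (CpG x samples matrix), `annotation` (tibble with
#'   `cpg_id`, `chr`, `pos`, `gene`), `clock` (an `mm_clock`), and `truth`
#'   (planted labels, DMP table with Beta-scale effects, taxon-link table,
#'   cell-factor scores, and the epigenetic-age construction).
#' @export
generate_methylation <- function(cov, labels, counts, params) {
  n <- length(labels)
  mm_assert(nrow(cov) == n, "`labels` must match `cov`")
  G <- params$n_cpgs
  comp <- sample.int(3, G, replace = TRUE, prob = params$baseline_weights)
  planted_idx <- unique(c(params$planted_dmps$cpg, params$taxon_links$cpg))
  comp[planted_idx] <- 2L  # hemi-methylated baseline for planted sites
  baseline <- stats::rnorm(G, params$baseline_means[comp],
                           params$baseline_sds[comp])
  M <- matrix(baseline, G, n) +
    matrix(stats::rnorm(G * n, 0, params$noise_sd), G, n)

  # latent cell-composition factor
  f <- stats::rnorm(n)
  loads <- numeric(G)
  hit <- sample.int(G, round(params$cell_factor_prop * G))
  loads[hit] <- stats::rnorm(length(hit), 0, params$cell_factor_sd)
  M <- M + outer(loads, f)

  dmp_table <- NULL
  if (!is.null(params$planted_dmps)) {
    pd <- params$planted_dmps
    mm_assert(all(pd$cpg <= G), "planted CpG index out of range")
    for (r in seq_len(nrow(pd)))
      M[pd$cpg[r], labels == pd$cluster_a[r]] <-
        M[pd$cpg[r], labels == pd$cluster_a[r]] + pd$delta_m[r]
    dmp_table <- dplyr::mutate(
      pd,
      cpg_id = sprintf("cg%07d", .data$cpg),
      delta_beta = delta_m_to_delta_beta(baseline[.data$cpg], .data$delta_m))
  }
  link_table <- NULL
  if (!is.null(params$taxon_links)) {
    tl <- params$taxon_links
    for (r in seq_len(nrow(tl))) {
      x <- centered_log_ra(counts, tl$genus[r])
      M[tl$cpg[r], ] <- M[tl$cpg[r], ] + tl$slope[r] * x
    }
    link_table <- dplyr::mutate(tl, cpg_id = sprintf("cg%07d", .data$cpg))
  }

  cpg_ids <- sprintf("cg%07d", seq_len(G))
  rownames(M) <- cpg_ids
  colnames(M) <- cov$sample_id
  beta <- m_to_beta(M)

  # synthetic clock: betas at the clock sites are affine in the transformed
  # target age, with weights scaled so the linear predictor equals it exactly
  avoid <- planted_idx
  free <- setdiff(seq_len(G), avoid)
  mm_assert(length(free) >= params$clock_sites,
            "not enough CpGs left for the clock sites")
  sites <- sort(sample(free, params$clock_sites))
  x_ead <- centered_log_ra(counts, params$ead_taxon_genus)
  age_target <- cov$age + stats::rnorm(n, 0, params$ead_noise_sd) +
    params$ead_taxon_slope * x_ead
  # the calibrated transform is defined for age > -1 year; clamp rare
  # extreme draws just inside the domain (the clamped value is the truth)
  age_target <- pmax(age_target, -0.95)
  Tj <- horvath_forward(age_target, params$adult_age)
  rng <- range(Tj)
  span <- max(rng[2] - rng[1], 1e-8)
  A <- rng[1] - 0.05 * span
  B <- rng[2] + 0.05 * span
  s <- (Tj - A) / (B - A)
  ns <- params$clock_sites
  l <- stats::runif(ns, 0.10, 0.30)
  h <- stats::runif(ns, 0.70, 0.90)
  w <- stats::runif(ns, 0.5, 1.5)
  w <- w * (B - A) / sum(w * (h - l))
  clock_beta <- l + (h - l) %o% s
  # per-site noise projected orthogonally to the weight vector: clock sites
  # look like ordinary variable CpGs while the weighted sum stays exact
  E <- matrix(stats::rnorm(ns * n, 0, 0.01), ns, n)
  E <- E - w %o% (as.numeric(w %*% E) / sum(w^2))
  beta[sites, ] <- pmin(pmax(clock_beta + E, 1e-6), 1 - 1e-6)
  intercept <- A - sum(w * l)
  clock <- clock_definition(intercept = intercept,
                            weights = stats::setNames(w, cpg_ids[sites]),
                            adult_age = params$adult_age)

  annotation <- tibble::tibble(
    cpg_id = cpg_ids,
    chr = sample(1:22, G, replace = TRUE),
    pos = sample.int(2e8, G, replace = TRUE),
    gene = ifelse(stats::runif(G) < 0.6,
                  sprintf("GENE%04d", sample.int(5000, G, replace = TRUE)),
                  NA_character_))

  truth <- list(labels = labels, dmp_table = dmp_table,
                taxon_link_table = link_table,
                cell_factor = f, cell_loadings = loads,
                clock_sites = cpg_ids[sites],
                age_target = age_target,
                ead = list(genus = params$ead_taxon_genus,
                           slope = params$ead_taxon_slope,
                           noise_sd = params$ead_noise_sd))
  list(beta = beta, annotation = annotation, clock = clock, truth = truth)
}

#' Simulate a complete cohort
#'
#' Runs [generate_covariates()], [generate_otu_counts()] and
#' [generate_methylation()] under a single seed, returning the data a real
#' study would supply (counts + taxonomy, Beta matrix + annotation,
#' covariates, clock coefficients) together with the ground truth.
#'
#' @param params an [cohort_params()] object.
#' @return An `mm_cohort` list: `covariates`, `counts`, `beta`, `annotation`,
#'   `clock`, `truth`, `params`.
#' @export
simulate_cohort <- function(params = cohort_params()) {
  mm_assert(inherits(params, "mm_cohort_params"),
            "`params` must come from cohort_params()")
  set.seed(params$seed)
  cov <- generate_covariates(params)
  oc <- generate_otu_counts(cov, params)
  meth <- generate_methylation(cov, oc$labels, oc$counts, params)
  structure(list(covariates = cov, counts = oc$counts, beta = meth$beta,
                 annotation = meth$annotation, clock = meth$clock,
                 truth = meth$truth, params = params),
            class = "mm_cohort")
}

#' @export
print.mm_cohort <- function(x, ...) {
  cat(sprintf("<mm_cohort> %d samples, %d OTUs, %d CpGs (seed %d)\n",
              nrow(x$covariates), nrow(x$counts$counts), nrow(x$beta),
              x$params$seed))
  invisible(x)
}

#' Write a cohort as plain-text fixture files
#'
#' Writes `counts.tsv`, `taxonomy.tsv`, `beta.tsv`, `covariates.csv`,
#' `clock.csv`, `truth_labels.tsv` and (when present) `truth_effects.tsv`
#' into `path`. The files round-trip through [read_inputs()] bit-identically
#' for integers and to full double precision for reals.
#'
#' @param cohort an `mm_cohort` from [simulate_cohort()].
#' @param path output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_fixture_bundle <- function(cohort, path) {
  mm_assert(inherits(cohort, "mm_cohort"), "`cohort` must be an mm_cohort")
  mm_assert(nrow(cohort$covariates) > 0, "cohort is empty")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(path, f)
  counts_df <- tibble::as_tibble(cohort$counts$counts, rownames = "taxon_id")
  readr::write_tsv(counts_df, p("counts.tsv"))
  readr::write_tsv(cohort$counts$taxonomy, p("taxonomy.tsv"))
  beta_df <- tibble::as_tibble(cohort$beta, rownames = "cpg_id")
  readr::write_tsv(beta_df, p("beta.tsv"))
  readr::write_csv(cohort$covariates, p("covariates.csv"))
  clock_df <- tibble::tibble(
    cpg_id = c("(Intercept)", "(AdultAge)", names(cohort$clock$weights)),
    weight = c(cohort$clock$intercept, cohort$clock$adult_age,
               unname(cohort$clock$weights)))
  readr::write_csv(clock_df, p("clock.csv"))
  readr::write_tsv(tibble::tibble(sample_id = cohort$covariates$sample_id,
                                  cluster = cohort$truth$labels),
                   p("truth_labels.tsv"))
  files <- c("counts.tsv", "taxonomy.tsv", "beta.tsv", "covariates.csv",
             "clock.csv", "truth_labels.tsv")
  if (!is.null(cohort$truth$dmp_table)) {
    readr::write_tsv(cohort$truth$dmp_table, p("truth_effects.tsv"))
    files <- c(files, "truth_effects.tsv")
  }
  readr::write_tsv(cohort$annotation, p("annotation.tsv"))
  files <- c(files, "annotation.tsv")
  invisible(p(files))
}
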