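# micromethyl

Cross-sectional integration of the upper-airway (nasal) microbiome with
nasal-cell DNA methylation measured in the same individuals.

The nasal cavity hosts a small number of recurring bacterial community
types — dominated by *Corynebacterium*, *Propionibacterium* (*Cutibacterium*),
*Staphylococcus*, mixed *Staphylococcus*/*Streptococcus*, *Neisseriaceae*, or
*Moraxella* — and interactions between these communities and the host
epithelium are thought to act partly through the epigenome. `micromethyl` is
for epidemiologists and computational biologists who have a 16S rRNA count
table and an array-based methylation matrix from the same swabs and want to
ask, end to end: *do samples fall into distinct community types; is
methylation different between them; which genera drive those differences;
and is microbial abundance associated with epigenetic aging?*

## What it implements

* **Community typing.** QC (library-size filter, per-cell low-abundance
  zeroing), iterated rarefaction (mean over repeated subsampling at the
  minimum depth), genus merging, then partitioning around medoids on the
  Jensen–Shannon divergence, JSD(P,Q) = ½KL(P‖A) + ½KL(Q‖A), A = (P+Q)/2.
  The number of clusters k maximises the mean silhouette
  s(i) = (bᵢ − aᵢ)/max(aᵢ, bᵢ) over k = 2..10 (Calinski–Harabasz reported
  alongside); stability is assessed by leave-one-out re-clustering and the
  adjusted Rand index. Alpha diversity (richness, Shannon H = −Σ pᵢ ln pᵢ,
  Gini–Simpson 1 − Σ pᵢ²) is computed pre-rarefaction.
* **Multi-group EWAS.** Per-CpG Huber robust regression of M-values
  (M = log₂(β/(1−β))) on cell-means cluster indicators plus sex, age, BMI
  z-score, race/ethnicity, maternal education, annual + biannual season
  harmonics, sequencing batch and 10 reference-free cell-composition
  (ReFACTor) components; optional empirical-Bayes variance moderation; all
  C(k,2) pairwise contrasts with a global Bonferroni rule
  p < α/(n_CpGs × n_contrasts); genomic inflation λ and an empirical-null
  location/scale diagnostic; and a label-permutation empirical null for the
  number of differentially methylated positions,
  p = (1 + #{permuted count > observed})/(B + 1). Effects are reported on
  the Beta scale via Δβ = σ(M̄ + ΔM) − σ(M̄), σ(m) = 2ᵐ/(1+2ᵐ).
* **Differential abundance.** For each DMP, a simplified bias-corrected
  log-linear model: y = ln(count + pseudo-count), a per-sample
  sampling-fraction offset (median over taxa of y minus taxon means), least
  squares on the IQR-scaled exposure plus covariates, BH correction within
  each DMP across taxa, and a pseudo-count sensitivity analysis
  ({0.1, 0.5, 1}).
* **Epigenetic aging.** A user-supplied linear clock with the calibrated
  age transform (log below adult age, linear above); epigenetic age
  deviation (EAD) = residuals of epigenetic on chronological age; cluster
  contrasts of EAD and EAD–taxa differential abundance (per year of EAD).
* **Synthetic cohorts.** `simulate_cohort()` generates a full study —
  Dirichlet-multinomial communities with six nasal archetypes, methylation
  with planted cluster effects, taxon–CpG links, a latent cell factor, and
  an exactly invertible synthetic clock — with the ground truth recorded,
  for calibration, power and recovery studies.

## Worked example

```r
library(micromethyl)

params <- cohort_params(
  n_samples = 372, seed = 42,
  planted_dmps = data.frame(cpg = 1:3, cluster_a = 2, cluster_b = 3,
                            delta_m = c(0.6, -0.5, 0.8)),
  taxon_links = data.frame(cpg = 4, genus = "Propionibacterium",
                           slope = -0.15))
cohort <- simulate_cohort(params)

# --- community typing -----------------------------------------------------
cm <- cohort$counts |> filter_samples_by_depth() |> zero_low_abundance()
ra <- cm |> iterated_rarefaction(iterations = 100, seed = 1) |>
  merge_to_genus() |> to_relative_abundance()
d  <- pairwise_distance(ra, "jsd")
select_k(d, 2:10)
#> <mm_kselect> chosen k = 6 (max silhouette)
#> # A tibble: 9 × 3
#>       k silhouette   chi
#>   <int>      <dbl> <dbl>
#> 1     2      0.456 176.
#> ...
#> 5     6      0.688 171.
sol <- rename_by_size(pam_cluster(d, 6))
adjusted_rand_index(sol$labels, cohort$truth$labels)
#> [1] 1
```

The silhouette peaks at k = 6 (0.688) and PAM recovers the six planted
community types exactly (ARI = 1 against the generator's truth).

```r
# --- EWAS with all pairwise cluster contrasts -----------------------------
m   <- beta_to_m(cohort$beta)
X   <- build_design(cohort$covariates, sol$labels,
                    refactor = refactor_components(cohort$beta, k = 10))
fit <- ebayes_moderate(robust_fit(m, X))
contrasts <- adjust_contrasts(pairwise_contrasts(fit))
g <- global_significance(matrix(contrasts$p, nrow = nrow(m)))
g$n_dmps
#> [1] 4
```

Four CpGs are differentially methylated between at least two clusters at
the global Bonferroni threshold (α divided by 2,000 CpGs × 15 contrasts):
the three planted cluster effects plus the taxon-linked CpG, whose
methylation tracks *Propionibacterium* abundance and therefore also differs
between clusters.

```r
# --- which genera drive the DMPs? -----------------------------------------
gen <- prevalence_filter(merge_to_genus(cm))
da  <- da_for_dmps(gen, m, rownames(m)[g$dmp], covariates = X[, -(1:6)])
dplyr::arrange(da, p)[1:3, c("cpg_id", "taxon", "logFC", "q",
                             "sensitivity_pass")]
#>      cpg_id             taxon logFC        q sensitivity_pass
#> 1 cg0000004 Propionibacterium -1.09 8.15e-11             TRUE
#> 2 cg0000001 Propionibacterium  1.24 5.33e-10             TRUE
#> 3 cg0000003 Propionibacterium  0.89 1.09e-09             TRUE
```

The planted link is the top hit in its family: one IQR higher methylation
at cg0000004 corresponds to a natural-log fold change of −1.09 in
*Propionibacterium* abundance, stable across pseudo-counts
(`sensitivity_pass`).

```r
# --- epigenetic aging ------------------------------------------------------
ead <- compute_ead(apply_clock(cohort$beta, cohort$clock),
                   cohort$covariates$age)
ead
#> <mm_epiage> n = 372, r = 0.144, MAE = 3.15 years
ead_cluster_contrasts(ead, sol$labels, X[, -(1:6)])   # 15 pairwise tests
ead_taxa_association(gen, ead, covariates = X[, -(1:6)])
```

Epigenetic age correlates weakly with chronological age in this narrow age
band (r = 0.14, median absolute error 3.2 years), as expected when the
cohort spans only a few years; EAD is then tested against clusters and
against genus abundance (logFC per year of EAD).

Every result object is a tibble or has `tidy()`/`glance()` methods, and
`plot_k_selection()`, `plot_cluster_profiles()`, `plot_volcano()` and
`plot_epi_age()` (plus `autoplot()`) produce ggplot figures.
`run_pipeline(pipeline_config(...))` executes the whole workflow from
TSV/CSV inputs and writes diff-stable result tables plus a JSON manifest;
`write_fixture_bundle()` round-trips a synthetic cohort through those
readers.

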