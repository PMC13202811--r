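test_that("covariate generation matches the cohort moments and reproduces", {
  p <- cohort_params(n_samples = 372, seed = 42)
  set.seed(p$seed)
  cov <- generate_covariates(p)
  expect_equal(nrow(cov), 372)
  # sample mean age within 3 SE of 13.0
  expect_lt(abs(mean(cov$age) - 13.0), 3 * 0.7 / sqrt(372))
  expect_lt(abs(mean(cov$bmi_z) - 0.44), 3 * 1.10 / sqrt(372))
  expect_true(all(cov$day_of_year %in% 1:365))
  expect_equal(nlevels(cov$batch), 4)
  expect_error(cohort_params(n_samples = 0), "positive")
  # same seed twice -> identical tables
  set.seed(7); a <- generate_covariates(p)
  set.seed(7); b <- generate_covariates(p)
  expect_identical(a, b)
})

test_that("count generation respects depths and archetype dominance", {
  p <- cohort_params(n_samples = 150, seed = 3)
  set.seed(p$seed)
  cov <- generate_covariates(p)
  oc <- generate_otu_counts(cov, p)
  depths <- colSums(oc$counts$counts)
  expect_true(all(depths >= p$depth_range[1] & depths <= p$depth_range[2]))
  expect_true(all(oc$counts$counts == round(oc$counts$counts)))
  # cluster-1 samples: median Corynebacterium relative abundance near 0.67
  ra <- to_relative_abundance(merge_to_genus(oc$counts))
  c1 <- oc$labels == 1
  expect_gt(sum(c1), 20)
  expect_lt(abs(median(ra["Corynebacterium", c1]) - 0.67), 0.10)
  expect_error(cohort_params(dirichlet_concentration = 0), "positive")
})

test_that("large concentration and depth drive proportions to the archetype", {
  p <- cohort_params(n_samples = 30, seed = 4, dirichlet_concentration = 1e6,
                     depth_range = c(2e6, 2e6))
  set.seed(p$seed)
  cov <- generate_covariates(p)
  oc <- generate_otu_counts(cov, p)
  ra <- to_relative_abundance(merge_to_genus(oc$counts))
  prof <- nasal_archetypes()$profiles
  lab_map <- rownames(prof)
  lab_map[grepl("^uncl_", lab_map)] <-
    sub("^uncl_", "unclassified ", lab_map[grepl("^uncl_", lab_map)])
  for (i in seq_len(ncol(ra))) {
    expect_lt(max(abs(ra[lab_map, i] - prof[, oc$labels[i]])), 0.02)
  }
})

test_that("methylation generation plants effects on the M scale", {
  # planted delta giving delta-beta ~ 2% at a hemi-methylated site
  dm <- log2(0.52 / 0.48)
  p <- cohort_params(n_samples = 300, n_cpgs = 200, seed = 5,
                     planted_dmps = data.frame(cpg = 1, cluster_a = 1,
                                               cluster_b = 2, delta_m = dm),
                     noise_sd = 0.3)
  coh <- simulate_cohort(p)
  expect_true(all(coh$beta > 0 & coh$beta < 1))
  lab <- coh$truth$labels
  obs <- mean(coh$beta[1, lab == 1]) - mean(coh$beta[1, lab == 2])
  planted <- coh$truth$dmp_table$delta_beta[1]
  expect_lt(abs(obs - planted), 0.02)  # Monte-Carlo agreement
  expect_error(
    simulate_cohort(cohort_params(n_cpgs = 10, clock_sites = 2,
                                  planted_dmps = data.frame(
      cpg = 11, cluster_a = 1, cluster_b = 2, delta_m = 1))),
    "out of range")
  expect_error(cohort_params(n_cpgs = 10, clock_sites = 11), "exceed")
})

test_that("planted delta-beta is accurate at a larger Monte-Carlo size", {
  dm <- log2(0.52 / 0.48)
  devs <- vapply(1:6, function(s) {
    coh <- simulate_cohort(cohort_params(
      n_samples = 400, n_cpgs = 60, seed = s, ead_taxon_slope = 0,
      planted_dmps = data.frame(cpg = 1, cluster_a = 1, cluster_b = 2,
                                delta_m = dm)))
    lab <- coh$truth$labels
    (mean(coh$beta[1, lab == 1]) - mean(coh$beta[1, lab == 2])) -
      coh$truth$dmp_table$delta_beta[1]
  }, numeric(1))
  expect_lt(abs(mean(devs)), 0.005)
})

test_that("null cohorts carry no planted structure", {
  coh <- null_cohort(seed = 6, n = 100, n_cpgs = 150)
  expect_null(coh$truth$dmp_table)
  expect_null(coh$truth$taxon_link_table)
  # group differences consistent with noise at non-clock CpGs
  lab <- coh$truth$labels
  free <- setdiff(rownames(coh$beta), coh$truth$clock_sites)
  m <- beta_to_m(coh$beta[free, ])
  t_stats <- apply(m, 1, function(v)
    t.test(v[lab == 1], v[lab == 2])$statistic)
  expect_lt(mean(abs(t_stats) > 2), 0.12)
})

test_that("synthetic clock recovers target ages exactly without noise", {
  coh <- simulate_cohort(cohort_params(seed = 7, n_cpgs = 200,
                                       ead_noise_sd = 0, ead_taxon_slope = 0))
  ages <- apply_clock(coh$beta, coh$clock)
  expect_lt(max(abs(ages - coh$covariates$age)), 1e-6)
  # with noise/taxon effect the clock reproduces the recorded target exactly
  coh2 <- simulate_cohort(cohort_params(seed = 8, n_cpgs = 200))
  ages2 <- apply_clock(coh2$beta, coh2$clock)
  expect_lt(max(abs(ages2 - coh2$truth$age_target)), 1e-8)
})

test_that("fixture bundles round-trip through the readers", {
  coh <- small_cohort(seed = 9, n = 40, n_cpgs = 60,
                      planted_dmps = data.frame(cpg = 1, cluster_a = 1,
                                                cluster_b = 2, delta_m = 0.5))
  dir <- withr::local_tempdir()
  write_fixture_bundle(coh, dir)
  cfg <- pipeline_config(counts = file.path(dir, "counts.tsv"),
                         taxonomy = file.path(dir, "taxonomy.tsv"),
                         beta = file.path(dir, "beta.tsv"),
                         covariates = file.path(dir, "covariates.csv"),
                         clock = file.path(dir, "clock.csv"))
  inp <- read_inputs(cfg)
  expect_identical(unname(inp$counts$counts), unname(coh$counts$counts))
  expect_equal(unname(inp$beta), unname(coh$beta), tolerance = 1e-12)
  expect_equal(inp$clock$intercept, coh$clock$intercept, tolerance = 1e-12)
  expect_equal(inp$clock$weights, coh$clock$weights, tolerance = 1e-12)
  expect_equal(inp$clock$adult_age, coh$clock$adult_age)
  # same seed twice -> identical bundles
  dir2 <- withr::local_tempdir()
  write_fixture_bundle(simulate_cohort(coh$params), dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})

test_that("generation is deterministic under a fixed seed", {
  a <- small_cohort(seed = 10, n = 50, n_cpgs = 80)
  b <- small_cohort(seed = 10, n = 50, n_cpgs = 80)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$beta, b$beta)
  expect_identical(a$truth$labels, b$truth$labels)
})
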