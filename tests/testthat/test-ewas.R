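test_that("design matrix encodes the covariate plan", {
  coh <- small_cohort(seed = 1, n = 372, n_cpgs = 60)
  expect_equal(nlevels(droplevels(coh$covariates$race)), 5)
  rf <- refactor_components(coh$beta, k = 10, t = 60)
  X <- build_design(coh$covariates, coh$truth$labels, refactor = rf)
  # 6 clusters + sex/age/bmi + 4 race + education + 4 season + 3 batch + 10
  expect_equal(ncol(X), 31)
  expect_equal(qr(X)$rank, 31)
  expect_equal(attr(X, "cluster_cols"), 1:6)
  # cluster indicators partition samples
  expect_true(all(rowSums(X[, 1:6]) == 1))
  # season periodicity: day 0 and day 365.25 encode identically
  cov2 <- coh$covariates
  cov2$day_of_year[1:2] <- c(0, 365.25)
  X2 <- build_design(cov2, coh$truth$labels)
  season_cols <- grep("season", colnames(X2))
  expect_equal(X2[1, season_cols], X2[2, season_cols], tolerance = 1e-12)
  # annual-only variant has two season columns
  X1 <- build_design(coh$covariates, coh$truth$labels, harmonics = 1)
  expect_equal(length(grep("season", colnames(X1))), 2)
  # collinear extra covariate is rejected
  expect_error(build_design(coh$covariates, coh$truth$labels,
                            extra = cbind(dup = coh$covariates$age)),
               "rank deficient")
})

test_that("robust fit equals OLS without outliers and resists one outlier", {
  set.seed(2)
  n <- 100
  X <- cbind(g1 = rep(c(1, 0), each = n / 2), g2 = rep(c(0, 1), each = n / 2),
             x = rnorm(n))
  attr(X, "cluster_cols") <- 1:2
  beta_true <- c(1, 2, 0.5)
  # bounded (two-point) noise keeps every |r| below the Huber threshold,
  # so all weights are 1 and the IRLS solution is exactly OLS
  e <- 0.1 * sample(c(-1, 1), n, replace = TRUE)
  y <- matrix(X %*% beta_true + e, nrow = 1)
  fit <- robust_fit(y, X)
  ols <- lm.fit(X, y[1, ])
  expect_equal(unname(fit$coefficients[1, ]), unname(ols$coefficients),
               tolerance = 1e-8)
  # Normal noise: mild tail downweighting moves coefficients only slightly
  y2 <- matrix(X %*% beta_true + rnorm(n, 0, 0.2), nrow = 1)
  expect_equal(unname(robust_fit(y2, X)$coefficients[1, ]),
               unname(lm.fit(X, y2[1, ])$coefficients), tolerance = 0.01)
  # one gross outlier: robust bias is a small fraction of the OLS bias
  set.seed(3)
  bias_r <- bias_o <- numeric(40)
  for (r in 1:40) {
    e <- rnorm(n, 0, 0.2); e[1] <- 30
    y2 <- matrix(X %*% beta_true + e, nrow = 1)
    bias_r[r] <- robust_fit(y2, X)$coefficients[1, "x"] - 0.5
    bias_o[r] <- lm.fit(X, y2[1, ])$coefficients["x"] - 0.5
  }
  expect_lt(mean(abs(bias_r)), 0.2 * mean(abs(bias_o)))
})

test_that("robust fit recovers a planted cluster difference", {
  set.seed(4)
  est <- replicate(60, {
    coh_lab <- sample(1:2, 372, TRUE)
    X <- cbind(g1 = as.numeric(coh_lab == 1), g2 = as.numeric(coh_lab == 2))
    attr(X, "cluster_cols") <- 1:2
    y <- matrix(0.5 * X[, 1] + rnorm(372, 0, 0.3), nrow = 1)
    fit <- robust_fit(y, X)
    pairwise_contrasts(fit)$delta_m
  })
  expect_equal(mean(est), 0.5, tolerance = 0.05)
})

test_that("variance moderation matches the reference empirical Bayes", {
  skip_if_not_installed("limma")
  set.seed(5)
  coh <- small_cohort(seed = 5, n = 100, n_cpgs = 500)
  X <- build_design(coh$covariates, coh$truth$labels)
  fit <- suppressWarnings(robust_fit(beta_to_m(coh$beta), X))
  mod <- ebayes_moderate(fit)
  sq <- limma::squeezeVar(fit$sigma^2, df = fit$df_residual)
  expect_equal(mod$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(mod$s02, sq$var.prior, tolerance = 1e-6)
  expect_equal(mod$s2_post, sq$var.post, tolerance = 1e-8)
})

test_that("moderation hyperparameters are recovered from simulated variances", {
  set.seed(6)
  d <- 50; d0 <- 8; s02 <- 0.04
  s2 <- s02 * d0 / rchisq(1e5, d0) * rchisq(1e5, d) / d
  fake <- structure(list(sigma = sqrt(s2), df_residual = d, moderated = FALSE),
                    class = "mm_ewas_fit")
  mod <- ebayes_moderate(fake)
  expect_equal(mod$d0, d0, tolerance = 0.1 * d0)
  expect_equal(mod$s02, s02, tolerance = 0.1 * s02)
  # degenerate: equal variances -> all posteriors equal the common value
  fake2 <- structure(list(sigma = rep(0.3, 200), df_residual = d,
                          moderated = FALSE), class = "mm_ewas_fit")
  mod2 <- ebayes_moderate(fake2)
  expect_equal(unique(round(mod2$s2_post, 12)), 0.09)
  expect_warning(ebayes_moderate(structure(
    list(sigma = rep(1, 10), df_residual = d, moderated = FALSE),
    class = "mm_ewas_fit")), "skipped")
})

test_that("pairwise contrasts: count, linearity, sign flip", {
  set.seed(7)
  coh <- small_cohort(seed = 7, n = 120, n_cpgs = 150)
  X <- build_design(coh$covariates, coh$truth$labels)
  fit <- robust_fit(beta_to_m(coh$beta), X)
  ct <- pairwise_contrasts(fit)
  expect_equal(length(unique(ct$contrast)), choose(6, 2))
  expect_equal(nrow(ct), 150 * 15)
  # contrast values are coefficient differences
  L <- micromethyl:::pairwise_contrast_matrix(6)
  expect_equal(ct$delta_m[ct$contrast == "1_vs_2"],
               unname(fit$coefficients[, 1] - fit$coefficients[, 2]))
  # sign flip negates the estimate, keeps the p-value
  flip <- pairwise_contrasts(fit, contrast_matrix = -L[, 1, drop = FALSE])
  expect_equal(flip$delta_m, -ct$delta_m[ct$contrast == "1_vs_2"])
  expect_equal(flip$p, ct$p[ct$contrast == "1_vs_2"], tolerance = 1e-12)
  # linearity: contrast of a sum equals sum of contrasts
  Lsum <- L[, 1] + L[, 2]
  both <- pairwise_contrasts(fit, contrast_matrix = cbind(Lsum))
  expect_equal(both$delta_m,
               ct$delta_m[ct$contrast == "1_vs_2"] +
                 ct$delta_m[ct$contrast == "1_vs_3"], tolerance = 1e-10)
  # delta_beta has the sign of delta_m
  expect_true(all(sign(ct$delta_beta) == sign(ct$delta_m)))
  expect_error(pairwise_contrasts(fit, contrast_matrix = matrix(1, 3, 1)),
               "cluster coefficients")
})

test_that("global significance reproduces the published threshold rule", {
  # 0.05 / (715,023 CpGs x 15 contrasts) rounds to 4.66e-9
  thr <- 0.05 / (715023 * 15)
  expect_equal(signif(thr, 3), 4.66e-9)
  # strict inequality at the boundary
  p <- matrix(1, 100, 15)
  p[1, 1] <- 0.05 / length(p)   # exactly at the threshold: not flagged
  p[2, 1] <- 0.04 / length(p)   # below: flagged
  g <- global_significance(p, alpha = 0.05, method = "bonferroni")
  expect_false(g$flags[1, 1])
  expect_true(g$flags[2, 1])
  expect_equal(g$n_dmps, 1)
  expect_equal(g$threshold, 0.05 / 1500)
  # all p = 1 -> no DMPs
  expect_equal(global_significance(matrix(1, 10, 15))$n_dmps, 0)
  expect_error(global_significance(matrix(numeric(0), 0, 0)), "empty")
  # fdr flags match p.adjust
  set.seed(8)
  pm <- matrix(runif(1500)^3, 100, 15)
  gf <- global_significance(pm, method = "fdr")
  expect_equal(unname(gf$flags),
               matrix(p.adjust(pm, "BH") < 0.05, 100, 15))
})

test_that("inflation diagnostics are calibrated on simulated nulls", {
  set.seed(9)
  z1 <- rnorm(1e5); z2 <- rnorm(1e5, 0, 1.3)
  p <- cbind(a = 2 * pnorm(-abs(z1)), b = 2 * pnorm(-abs(z2)))
  ir <- inflation_report(p, t = cbind(z1, z2))
  expect_equal(ir$lambda[1], 1, tolerance = 0.03)
  expect_equal(ir$null_scale[1], 1, tolerance = 0.03)
  expect_equal(ir$lambda[2], 1.69, tolerance = 0.07)
  expect_equal(ir$null_scale[2], 1.3, tolerance = 0.03)
  expect_error(inflation_report(matrix(0.5, 10, 2)), "1000")
  # all z = 0 -> lambda = 0
  ir0 <- inflation_report(matrix(1, 2000, 1), t = matrix(0, 2000, 1))
  expect_equal(ir0$lambda, 0)
})

test_that("permutation empirical p follows the printed formula", {
  expect_equal(round(permutation_empirical_p(45, c(rep(10, 498), 50, 60)), 3),
               0.006)
  expect_equal(permutation_empirical_p(100, rep(0, 500)), 1 / 501)
  expect_equal(permutation_empirical_p(0, rep(5, 500)), 1)
  # strict inequality: ties do not count as exceedances
  expect_equal(permutation_empirical_p(5, c(5, 5, 6)), 2 / 4)
})

test_that("permutation null machinery counts DMPs per rule", {
  set.seed(10)
  coh <- null_cohort(seed = 10, n = 90, n_cpgs = 120)
  m <- beta_to_m(coh$beta)
  pn <- suppressWarnings(
    permutation_null(m, coh$covariates, coh$truth$labels, B = 5, seed = 1,
                     rule = "nominal", nominal_p = 0.01, moderate = FALSE))
  expect_length(pn$perm_counts, 5)
  expect_gte(pn$empirical_p, 1 / 6)
  expect_lte(pn$empirical_p, 1)
  expect_error(permutation_null(m, coh$covariates, coh$truth$labels, B = 0),
               "B")
})
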