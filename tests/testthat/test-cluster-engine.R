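test_that("distance metrics match hand-computed values and bounds", {
  ra <- cbind(P = c(0.5, 0.5), Q = c(0.25, 0.75))
  expect_equal(pairwise_distance(ra, "jsd")[1, 2], 0.03382, tolerance = 1e-4)
  same <- cbind(a = c(0.3, 0.7), b = c(0.3, 0.7))
  for (m in c("jsd", "jsd_sqrt", "bray_curtis", "jaccard"))
    expect_equal(pairwise_distance(same, m)[1, 2], 0)
  disj <- cbind(a = c(1, 0), b = c(0, 1))
  expect_equal(pairwise_distance(disj, "jsd")[1, 2], log(2), tolerance = 1e-12)
  expect_equal(pairwise_distance(disj, "bray_curtis")[1, 2], 1)
  expect_equal(pairwise_distance(disj, "jaccard")[1, 2], 1)
  expect_error(pairwise_distance(cbind(c(0.5, 0.4))), "sum to 1")
})

test_that("jsd stays below ln 2 and jsd_sqrt satisfies triangle inequality", {
  set.seed(11)
  n <- 40
  ra <- matrix(rgamma(8 * n, 0.5), 8)
  ra <- sweep(ra, 2, colSums(ra), "/")
  d <- pairwise_distance(ra, "jsd")
  expect_true(all(d <= log(2) + 1e-12))
  ds <- pairwise_distance(ra, "jsd_sqrt")
  trips <- t(replicate(3000, sample(n, 3)))
  lhs <- ds[cbind(trips[, 1], trips[, 3])]
  rhs <- ds[cbind(trips[, 1], trips[, 2])] + ds[cbind(trips[, 2], trips[, 3])]
  expect_true(all(lhs <= rhs + 1e-12))
})

test_that("PAM recovers tight pairs and matches brute force on small data", {
  d <- two_pairs_dist()
  sol <- pam_cluster(d, 2)
  expect_equal(sort(unname(tapply(1:4, sol$labels, length))), c(2, 2))
  expect_true(all(sol$labels[1:2] == sol$labels[1]))
  expect_true(all(sol$labels[3:4] == sol$labels[3]))
  # brute-force oracle on a battery of well-separated small instances
  set.seed(1)
  for (rep in 1:25) {
    k <- sample(2:3, 1)
    n <- sample((2 * k):8, 1)
    cen <- matrix(rnorm(k * 2, sd = 5), k)
    idx <- c(seq_len(k), sample(k, n - k, replace = TRUE))
    x <- cen[idx, ] + matrix(rnorm(n * 2, sd = 0.3), n)
    dm <- as.matrix(dist(x))
    sol <- pam_cluster(dm, k)
    best <- min(vapply(utils::combn(n, k, simplify = FALSE),
                       function(m) sum(apply(dm[, m, drop = FALSE], 1, min)),
                       numeric(1)))
    expect_equal(sol$total_cost, best, tolerance = 1e-10)
  }
})

test_that("PAM edge cases: k = n, duplicate tie rule, cost consistency", {
  d <- two_pairs_dist()
  all_meds <- pam_cluster(d, 4)
  expect_equal(all_meds$total_cost, 0)
  expect_equal(length(unique(all_meds$labels)), 4)
  # duplicated points: medoid is the lowest-index duplicate
  dd <- matrix(0, 4, 4)
  dd[1:2, 3:4] <- 1; dd[3:4, 1:2] <- 1
  sol <- pam_cluster(dd, 2)
  expect_equal(sol$medoid_index, c(1, 3))
  # total_cost equals sum of distances to nearest medoid
  set.seed(2)
  dm <- as.matrix(dist(matrix(rnorm(40), 20)))
  s <- pam_cluster(dm, 3)
  expect_equal(s$total_cost,
               sum(apply(dm[, s$medoid_index, drop = FALSE], 1, min)))
})

test_that("PAM agrees with the reference implementation on real-size data", {
  skip_if_not_installed("cluster")
  set.seed(3)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 4), ncol = 2),
             matrix(rnorm(60, c(0, 8)), ncol = 2))
  dm <- as.matrix(dist(x))
  mine <- pam_cluster(dm, 3)
  ref <- cluster::pam(stats::as.dist(dm), 3)
  expect_equal(adjusted_rand_index(mine$labels, ref$clustering), 1)
  expect_equal(mine$total_cost, unname(ref$objective["swap"]) * nrow(x),
               tolerance = 1e-8)
})

test_that("mean silhouette matches a hand-computed 4-point configuration", {
  # points on a line at 0, 1, 10, 12; clusters {1,2}, {3,4}
  x <- c(0, 1, 10, 12)
  d <- abs(outer(x, x, "-"))
  lab <- c(1, 1, 2, 2)
  # a = within-pair distance; b = mean distance to the other pair
  s <- c((11 - 1) / 11, (10 - 1) / 10, (9.5 - 2) / 9.5, (11.5 - 2) / 11.5)
  expect_equal(mean_silhouette(d, lab), mean(s), tolerance = 1e-12)
  # two clusters of exact duplicates -> 1
  dd <- matrix(0, 4, 4); dd[1:2, 3:4] <- 1; dd[3:4, 1:2] <- 1
  expect_equal(mean_silhouette(dd, c(1, 1, 2, 2)), 1)
  # all-identical points split in two -> 0 by convention
  expect_equal(mean_silhouette(matrix(0, 4, 4), c(1, 1, 2, 2)), 0)
  expect_error(mean_silhouette(two_pairs_dist(), rep(1, 4)), "two clusters")
})

test_that("CHI on a PCoA embedding equals CHI on the raw coordinates", {
  set.seed(4)
  x <- rbind(matrix(rnorm(30, 0), ncol = 2), matrix(rnorm(30, 3), ncol = 2))
  lab <- rep(1:2, each = 15)
  d <- as.matrix(dist(x))
  chi_direct <- function(x, lab) {
    n <- nrow(x); k <- length(unique(lab)); grand <- colMeans(x)
    W <- 0; B <- 0
    for (g in unique(lab)) {
      cen <- colMeans(x[lab == g, , drop = FALSE])
      W <- W + sum(sweep(x[lab == g, , drop = FALSE], 2, cen)^2)
      B <- B + sum(lab == g) * sum((cen - grand)^2)
    }
    (B / (k - 1)) / (W / (n - k))
  }
  expect_equal(calinski_harabasz(d, lab), chi_direct(x, lab),
               tolerance = 1e-8)
  # monotone in separation
  x2 <- x; x2[lab == 2, ] <- x2[lab == 2, ] + 50
  expect_gt(calinski_harabasz(as.matrix(dist(x2)), lab),
            calinski_harabasz(d, lab))
  expect_error(calinski_harabasz(d, seq_len(nrow(d))), "k = n")
})

test_that("CHI under random labels on structureless data centers near 1", {
  set.seed(5)
  vals <- replicate(40, {
    x <- matrix(rnorm(60), ncol = 2)
    calinski_harabasz(as.matrix(dist(x)), sample(1:3, 30, TRUE))
  })
  expect_gt(mean(vals), 0.7)
  expect_lt(mean(vals), 1.4)
})

test_that("adjusted Rand index: identity, relabeling, hand value, null mean", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  set.seed(6)
  m <- mean(replicate(1000,
    adjusted_rand_index(sample(1:3, 30, TRUE), sample(1:3, 30, TRUE))))
  expect_lt(abs(m), 0.02)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
  skip_if_not_installed("mclust")
  set.seed(7)
  a <- sample(1:4, 50, TRUE); b <- sample(1:3, 50, TRUE)
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
})

test_that("select_k scans the range and picks the silhouette maximum", {
  d <- two_pairs_dist()
  ks <- select_k(d, 2:3)
  expect_equal(ks$report$k, 2:3)
  expect_equal(ks$chosen_k, 2)
  expect_error(select_k(d, 2:5), "k_range")
})

test_that("leave-one-out stability is exact on duplicate pairs", {
  d <- two_pairs_dist()
  full <- pam_cluster(d, 2)
  st <- loo_stability(d, full, k_range = 2)
  expect_equal(nrow(st$iterations), 4)
  expect_true(all(st$iterations$ari == 1))
  expect_true(all(st$iterations$selected_k == 2))
  st2 <- loo_stability(d, full, k_range = 2)
  expect_identical(st$iterations, st2$iterations)  # deterministic
})

test_that("rename_by_size makes cluster 1 the largest and is idempotent", {
  set.seed(8)
  x <- c(rnorm(3, 0, .1), rnorm(10, 5, .1), rnorm(6, 10, .1))
  d <- abs(outer(x, x, "-"))
  sol <- rename_by_size(pam_cluster(d, 3))
  sizes <- tabulate(sol$labels)
  expect_equal(sizes, sort(sizes, decreasing = TRUE))
  expect_equal(sizes[1], 10)
  expect_equal(rename_by_size(sol)$labels, sol$labels)
})
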