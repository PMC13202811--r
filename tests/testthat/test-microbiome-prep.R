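test_that("depth filter keeps samples at or above the threshold", {
  x <- matrix(c(9999, 10000, 20000), nrow = 1,
              dimnames = list("t1", paste0("s", 1:3)))
  cm <- count_matrix(x)
  kept <- filter_samples_by_depth(cm, 10000)
  expect_equal(colnames(kept$counts), c("s2", "s3"))
  expect_identical(filter_samples_by_depth(kept, 10000)$counts, kept$counts)
  expect_warning(filter_samples_by_depth(cm, 1e9), "below")
})

test_that("low-abundance zeroing is per cell with boundary at min_copies", {
  x <- matrix(c(9, 10, 0,
                1, 2, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:3)))
  out <- zero_low_abundance(count_matrix(x), 10)
  expect_equal(unname(out$counts["a", ]), c(0, 10, 0))
  expect_false("b" %in% rownames(out$counts))  # all cells < 10 -> dropped
  ident <- zero_low_abundance(count_matrix(x), 1)
  expect_equal(ident$counts, x)
  expect_error(zero_low_abundance(count_matrix(x / 2)), "integer")
})

test_that("genus merging sums rows, conserves columns, labels unresolved", {
  cm <- tiny_counts()
  g <- merge_to_genus(cm)
  expect_equal(unname(g$counts["Corynebacterium", ]),
               unname(cm$counts[1, ] + cm$counts[2, ]))
  expect_equal(colSums(g$counts), colSums(cm$counts))
  expect_true("unclassified Neisseriaceae" %in% rownames(g$counts))
  cm$taxonomy <- NULL
  expect_error(merge_to_genus(cm), "taxonomy")
})

test_that("genus merge commutes with relative abundance", {
  cm <- tiny_counts()
  a <- to_relative_abundance(merge_to_genus(cm))
  b <- rowsum(to_relative_abundance(cm), genus_labels_for_test(cm))
  expect_equal(a[rownames(b), ], b, tolerance = 1e-12)
})

test_that("iterated rarefaction matches hypergeometric expectations", {
  # sample already at minimum depth is returned unchanged
  x <- cbind(s1 = c(80, 20), s2 = c(30, 20))
  rownames(x) <- c("a", "b")
  r <- iterated_rarefaction(count_matrix(x), iterations = 5, seed = 1)
  expect_equal(unname(r$counts[, "s2"]), c(30, 20))
  expect_true(all(abs(colSums(r$counts) - 50) < 1e-9))
  # mean over many iterations approaches L * p
  r2 <- iterated_rarefaction(count_matrix(x), iterations = 4000, seed = 2)
  expect_equal(unname(r2$counts[, "s1"]), c(40, 10), tolerance = 0.5)
  # determinism
  r3 <- iterated_rarefaction(count_matrix(x), iterations = 7, seed = 3)
  r4 <- iterated_rarefaction(count_matrix(x), iterations = 7, seed = 3)
  expect_identical(r3$counts, r4$counts)
  expect_error(iterated_rarefaction(count_matrix(cbind(s1 = c(0, 0)))), "zero")
})

test_that("relative abundance normalises columns and is idempotent", {
  ra <- to_relative_abundance(cbind(s1 = c(10, 30, 60)))
  expect_equal(unname(ra[, 1]), c(0.1, 0.3, 0.6))
  expect_equal(to_relative_abundance(ra), ra)
  expect_error(to_relative_abundance(cbind(s1 = c(0, 0))), "positive")
})

test_that("alpha diversity matches closed forms and vegan", {
  x <- cbind(u = c(5, 5, 0), s = c(10, 0, 0), m = c(50, 25, 25))
  rownames(x) <- paste0("t", 1:3)
  ad <- alpha_diversity(count_matrix(x))
  expect_equal(ad$richness, c(2L, 1L, 3L))
  expect_equal(ad$shannon[1], log(2), tolerance = 1e-12)
  expect_equal(ad$simpson[1], 0.5, tolerance = 1e-12)
  expect_equal(ad$shannon[2], 0)
  expect_equal(ad$simpson[2], 0)
  expect_equal(ad$shannon[3], 1.5 * log(2), tolerance = 1e-12)
  expect_equal(ad$simpson[3], 0.625, tolerance = 1e-12)
  skip_if_not_installed("vegan")
  expect_equal(ad$shannon, unname(vegan::diversity(t(x), "shannon")),
               tolerance = 1e-12)
  expect_equal(ad$simpson, unname(vegan::diversity(t(x), "simpson")),
               tolerance = 1e-12)
})

test_that("prevalence filter boundary is inclusive", {
  x <- matrix(0L, 2, 100, dimnames = list(c("in15", "in14"), NULL))
  x[1, 1:15] <- 1L
  x[2, 1:14] <- 1L
  colnames(x) <- paste0("s", 1:100)
  kept <- prevalence_filter(count_matrix(x), 0.15)
  expect_equal(rownames(kept$counts), "in15")
  expect_identical(prevalence_filter(kept, 0.15)$counts, kept$counts)
})

test_that("cluster profile medians reproduce per-sample values", {
  ra <- cbind(a = c(0.7, 0.3), b = c(0.7, 0.3), c = c(0.2, 0.8))
  rownames(ra) <- c("X", "Y")
  prof <- cluster_profile_summary(ra, c(1, 1, 2))
  expect_equal(prof$median_ra[prof$cluster == 1 & prof$taxon == "X"], 0.7)
  expect_equal(prof$median_ra[prof$cluster == 2 & prof$taxon == "Y"], 0.8)
  expect_error(cluster_profile_summary(ra, c(1, 2)), "align")
})
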