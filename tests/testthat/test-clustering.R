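test_that("pearson distance matches its definition", {
  set.seed(3)
  x <- matrix(rnorm(60), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  d <- pearson_distance(x)
  ## brute force from the definition
  for (i in 1:6) for (j in 1:6) {
    expected <- if (i == j) 0 else
      1 - sum(scale(x[, i]) * scale(x[, j])) / (nrow(x) - 1)
    expect_equal(d[i, j], expected, tolerance = 1e-12)
  }

  ## identical samples and perfectly anti-correlated samples
  y <- cbind(a = x[, 1], b = x[, 1], c = -x[, 1] + 2 * mean(x[, 1]))
  dy <- pearson_distance(y)
  expect_equal(dy["a", "b"], 0)
  expect_equal(dy["a", "c"], 2)

  z <- x; z[, 2] <- 5
  expect_error(pearson_distance(z), "zero-variance")
})

test_that("average linkage reproduces a worked UPGMA example", {
  ## hand computation: merge(A,B)@2, merge(C,D)@4, then
  ## d(AB,CD) = (6+10+5+9)/4 = 7.5
  d <- matrix(c(0, 2, 6, 10,
                2, 0, 5, 9,
                6, 5, 0, 4,
                10, 9, 4, 0), nrow = 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  h <- average_linkage(d)
  expect_equal(h$height, c(2, 4, 7.5))
  expect_equal(sort(cutree(h, 2)), sort(c(A = 1, B = 1, C = 2, D = 2)))

  ## two samples: a single merge at their distance
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  h2 <- average_linkage(d2)
  expect_equal(h2$height, 0.3)

  expect_error(average_linkage(matrix(1:6, 2, 3)), "symmetric")
})

test_that("top split recovers two well-separated blobs", {
  blobs <- blob_expression(300, c(5, 6), module_size = 100, effect = 4,
                           seed = 10)
  d <- pearson_distance(blobs$expr - rowMeans(blobs$expr))
  grp <- cutree(average_linkage(d), k = 2)
  expect_equal(length(unique(grp[blobs$cluster == 1])), 1)
  expect_equal(length(unique(grp[blobs$cluster == 2])), 1)
  expect_false(grp[1] == grp[11])
})

test_that("the SD sweep picks an anti-correlated split on structured data", {
  blobs <- blob_expression(600, c(6, 6), module_size = 200, effect = 4,
                           seed = 12)
  sel <- select_sd_cutoff(blobs$expr, min_genes = 100, n_cutoffs = 20)
  expect_equal(sel$status, "ok")
  chosen <- sel$sweep[sel$sweep$cutoff == sel$chosen_cutoff, ]
  expect_lte(chosen$anticorrelation, -0.5)
  expect_gte(chosen$genes_retained, 100)
  expect_gte(length(sel$chosen_genes), 100)
  ## chosen anticorrelation is the minimum among eligible cutoffs
  expect_equal(chosen$anticorrelation,
               min(sel$sweep$anticorrelation[sel$sweep$eligible]))
  ## top split equals the true blocks
  expect_equal(length(unique(sel$top_split[blobs$cluster == 1])), 1)
  expect_false(sel$top_split[1] == sel$top_split[12])
})

test_that("structureless data yield the no-structure status", {
  ## identical samples: no split can be anti-correlated
  x <- matrix(rep(rnorm(200), 6), ncol = 6,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  sel <- select_sd_cutoff(x, min_genes = 50, n_cutoffs = 10)
  expect_equal(sel$status, "no_structure")
  expect_true(is.na(sel$chosen_cutoff))

  expect_error(select_sd_cutoff(x[1:30, ], min_genes = 50), "min_genes")
})

test_that("consensus clustering saturates on perfectly separated blocks", {
  blobs <- blob_expression(300, c(5, 5, 6), module_size = 80, effect = 5,
                           seed = 14)
  cc <- consensus_cluster(blobs$expr, k = 3, n_iterations = 300,
                          subsample_fraction = 0.6, seed = 2)
  within <- outer(blobs$cluster, blobs$cluster, "==")
  off <- !diag(nrow(within))
  expect_true(all(cc$consensus[within & off] == 1))
  expect_true(all(cc$consensus[!within] == 0))
  ## assignments recover the blocks exactly (up to label permutation)
  expect_equal(length(unique(paste(cc$assignments, blobs$cluster))), 3)

  ## matrix invariants
  expect_true(isSymmetric(cc$consensus))
  expect_true(all(cc$consensus >= 0 & cc$consensus <= 1))
  expect_true(all(diag(cc$consensus)[diag(cc$co_sampled) > 0] == 1))
  ## co-sampling counts concentrate near n * P(i and j both drawn)
  n <- ncol(blobs$expr); m <- ceiling(0.6 * n)
  p2 <- m / n * (m - 1) / (n - 1)
  cs_off <- cc$co_sampled[upper.tri(cc$co_sampled)]
  expect_lt(abs(mean(cs_off) / 300 - p2), 4 * sqrt(p2 * (1 - p2) / 300))
})

test_that("degenerate consensus settings behave as documented", {
  blobs <- blob_expression(100, c(4, 4), module_size = 30, effect = 4,
                           seed = 5)
  ## fraction 1.0: every iteration identical, consensus entries in {0,1}
  cc <- consensus_cluster(blobs$expr, k = 2, n_iterations = 3,
                          subsample_fraction = 1.0, seed = 1)
  expect_true(all(cc$consensus %in% c(0, 1)))

  cc1 <- consensus_cluster(blobs$expr, k = 2, n_iterations = 50, seed = 9)
  cc2 <- consensus_cluster(blobs$expr, k = 2, n_iterations = 50, seed = 9)
  expect_identical(cc1$consensus, cc2$consensus)
  expect_identical(cc1$assignments, cc2$assignments)

  expect_error(consensus_cluster(blobs$expr, k = 2, n_iterations = 0, seed = 1),
               "n_iterations")
  expect_error(consensus_cluster(blobs$expr, k = 2, subsample_fraction = 1.2,
                                 seed = 1), "subsample_fraction")
  expect_error(consensus_cluster(blobs$expr, k = 7, subsample_fraction = 0.8,
                                 seed = 1), "largest k")
})
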