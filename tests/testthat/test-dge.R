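test_that("logCPM matches its definition", {
  ## count 0 at library size 999,999: offsets cancel to exactly -1
  m <- matrix(c(0, 999999), nrow = 2,
              dimnames = list(c("g1", "g2"), "s1"))
  e <- logcpm(count_matrix(m))
  expect_equal(e["g1", "s1"], log2(0.5 / 1e6 * 1e6))
  expect_equal(e["g1", "s1"], -1.0)

  ## general entries follow the formula with the stored library sizes
  cm <- random_counts(50, 4, seed = 2)
  e <- logcpm(cm)
  expected <- log2(t(t(cm$counts + 0.5) / (cm$library_sizes + 1)) * 1e6)
  expect_equal(e, expected, ignore_attr = TRUE)

  ## scale invariance: equal offset ratios (c+0.5)/(R+1) give equal logCPM,
  ## checked via explicit library-size overrides
  m3 <- matrix(c(3, 10), nrow = 1, dimnames = list("g1", c("a", "b")))
  e3 <- logcpm(count_matrix(m3), lib_sizes = c(999, 2999))
  expect_equal(e3["g1", "a"], e3["g1", "b"])  # 3.5/1000 == 10.5/3000

  expect_error(logcpm(count_matrix(m), lib_sizes = c(0)), "positive")
})

test_that("BH adjustment follows the step-up rule and matches brute force", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  bh_brute <- function(p) {
    m <- length(p); o <- order(p); ps <- p[o]
    adj <- vapply(seq_len(m), function(i) min(ps[i:m] * m / (i:m)), numeric(1))
    out <- numeric(m); out[o] <- pmin(adj, 1); out
  }
  set.seed(17)
  for (i in 1:200) {
    p <- runif(sample(1:60, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("with constant weights the log2FC is exactly the group mean difference", {
  set.seed(5)
  y <- matrix(rnorm(40), nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  w <- matrix(1, 8, 5)
  grp <- factor(c("x", "x", "x", "y", "y"))
  fit <- fit_moderated_t(list(logcpm = y, weights = w), grp)
  diff <- rowMeans(y[, 4:5]) - rowMeans(y[, 1:3])
  expect_equal(fit$log2fc, unname(diff))
})

test_that("with the prior disabled the statistic is the ordinary two-sample t", {
  set.seed(6)
  y <- matrix(rnorm(200), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  grp <- factor(rep(c("a", "b"), each = 5))
  fit <- fit_moderated_t(list(logcpm = y, weights = matrix(1, 20, 10)), grp,
                         prior = "none")
  ref <- t(apply(y, 1, function(v) {
    tt <- t.test(v[6:10], v[1:5], var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  }))
  expect_equal(fit$t, unname(ref[, 1]), tolerance = 1e-10)
  expect_equal(fit$p_value, unname(ref[, 2]), tolerance = 1e-10)
})

test_that("single contrived gene gives log2FC exactly 1", {
  y <- rbind(g1 = c(0, 0, 1, 1), g2 = c(5, 6, 5, 6))
  colnames(y) <- paste0("s", 1:4)
  grp <- factor(c("lo", "lo", "hi", "hi"), levels = c("lo", "hi"))
  fit <- fit_moderated_t(list(logcpm = y, weights = matrix(1, 2, 4)), grp,
                         prior = "none")
  expect_equal(fit$log2fc[fit$gene_id == "g1"], 1.0)
})

test_that("voom weights are positive, finite and flat for homoscedastic data", {
  set.seed(8)
  cm <- count_matrix(matrix(rpois(400 * 10, 1000), nrow = 400,
                            dimnames = list(paste0("g", 1:400),
                                            paste0("s", 1:10))))
  v <- voom_weights(cm, rep(c("a", "b"), each = 5))
  expect_true(all(is.finite(v$weights)) && all(v$weights > 0))
  expect_lt(sd(v$weights) / mean(v$weights), 0.2)

  ## degenerate gene with identical counts everywhere: no infinite weight
  m <- matrix(rpois(50 * 6, 40), nrow = 50)
  m[1, ] <- 25
  dimnames(m) <- list(paste0("g", 1:50), paste0("s", 1:6))
  ## equalize library sizes so the constant gene has zero residual SD
  v2 <- voom_weights(count_matrix(m), rep(c("a", "b"), each = 3))
  expect_true(all(is.finite(v2$weights)))

  expect_error(voom_weights(cm, rep(c("a", "b"), c(9, 1))), "at least 2")
})

test_that("the voom chain matches the reference weighted-limma pipeline", {
  library(limma)
  sim <- simulate_counts(sim_config(n_genes = 1500, seed = 21))
  keep <- sim$metadata$true_cluster %in% c("A", "C")
  cnt <- sim$counts$counts[, keep]
  cnt <- cnt[rowSums(cnt) > 0, ]
  grp <- factor(sim$metadata$true_cluster[keep])

  v <- voom_weights(count_matrix(cnt), grp)
  fit <- fit_moderated_t(v)

  design <- stats::model.matrix(~grp)
  lv <- limma::voom(cnt, design, lib.size = colSums(cnt), span = 0.5)
  lf <- limma::eBayes(limma::lmFit(lv, design))

  expect_equal(v$logcpm, lv$E, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(v$weights, lv$weights, ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(fit$log2fc, unname(lf$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(attr(fit, "df_prior"), lf$df.prior, tolerance = 1e-6)
  expect_equal(attr(fit, "s2_prior"), lf$s2.prior, tolerance = 1e-6)
  expect_equal(fit$t, unname(lf$t[, 2]), tolerance = 1e-8)
  expect_equal(fit$p_value, unname(lf$p.value[, 2]), tolerance = 1e-8)
})

test_that("null data give approximately uniform p-values", {
  set.seed(12)
  cnt <- matrix(rnbinom(5000 * 12, mu = rep(exp(rnorm(5000, 4, 1.5)), 12),
                        size = 1 / 0.15), nrow = 5000)
  dimnames(cnt) <- list(paste0("g", 1:5000), paste0("s", 1:12))
  grp <- sample(rep(c("a", "b"), each = 6))
  fit <- fit_moderated_t(voom_weights(count_matrix(cnt), grp))
  ks <- suppressWarnings(ks.test(fit$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("DE calling applies the FDR and fold-change rule jointly", {
  dge <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(0.9, -1.2, 3, 0.2),
                    p_adj = c(0.04, 0.04, 0.2, 0.001))
  res <- call_de(dge, fdr = 0.05, min_fc = 2)
  expect_false("a" %in% res$de_genes)   # FC 1.87 < 2
  expect_true("b" %in% res$down)        # |log2fc| 1.2 >= 1, p_adj < 0.05
  expect_false("c" %in% res$de_genes)   # p_adj above threshold
  expect_false("d" %in% res$de_genes)
  expect_equal(res$table$is_de, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("variance squeezing falls back to an infinite prior on constant variances", {
  ## at high residual df the log-scale moment correction is negligible and
  ## the shared prior variance recovers the common value
  s2 <- rep(2, 50) * exp(rnorm(50, 0, 1e-8))
  sq <- squeeze_var(s2, df = 200)
  expect_true(is.infinite(sq$df_prior))
  expect_equal(unname(sq$var_post[1]), 2, tolerance = 0.01)
  expect_equal(length(unique(sq$var_post)), 1)
})
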