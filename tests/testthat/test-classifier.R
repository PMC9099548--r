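test_that("at delta = 0 NSC equals brute-force nearest-centroid classification", {
  set.seed(20)
  for (rep in 1:20) {
    G <- sample(10:40, 1); n <- sample(8:16, 1)
    x <- matrix(rnorm(G * n), G,
                dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
    labels <- sample(rep(c("u", "v"), c(ceiling(n / 2), floor(n / 2))))
    m <- fit_shrunken_centroids(x, labels, delta = 0)
    new <- matrix(rnorm(G * 5), G)
    expect_equal(as.character(predict(m, new)$class),
                 unname(oracle_nearest_centroid(x, labels, new)))
    ## delta = 0: shrunken centroids equal class centroids
    expect_equal(m$shrunken_centroids, m$class_centroids, tolerance = 1e-12)
  }
})

test_that("the signature shrinks monotonically and vanishes at full shrinkage", {
  set.seed(22)
  x <- matrix(rnorm(100 * 12), 100,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:12)))
  labels <- rep(c("p", "q"), c(7, 5))
  x[1:10, labels == "p"] <- x[1:10, labels == "p"] + 3
  grid <- seq(0, 8, by = 0.5)
  sizes <- vapply(grid, function(d) {
    length(fit_shrunken_centroids(x, labels, delta = d)$surviving_genes)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))

  m0 <- fit_shrunken_centroids(x, labels, delta = 0)
  dmax <- max(abs(m0$dprime))
  mfull <- fit_shrunken_centroids(x, labels, delta = dmax + 0.1)
  expect_length(mfull$surviving_genes, 0)
  ## everything classified to the largest-prior class
  pred <- predict(mfull, x)$class
  expect_true(all(pred == "p"))

  expect_error(fit_shrunken_centroids(x, labels, delta = -1), "non-negative")
  expect_error(fit_shrunken_centroids(x, rep("p", 12), 0), "two classes")
})

test_that("informative genes survive moderate shrinkage", {
  set.seed(23)
  G <- 500
  x <- matrix(rnorm(G * 20), G,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:20)))
  labels <- rep(c("a", "b"), each = 10)
  inf <- paste0("g", 1:50)
  x[1:50, labels == "a"] <- x[1:50, labels == "a"] + 4
  m <- fit_shrunken_centroids(x, labels, delta = 2)
  expect_true(all(inf %in% m$surviving_genes))
  expect_lt(length(m$surviving_genes), G)
})

test_that("cross-validation is perfect on separable data and deterministic", {
  set.seed(24)
  G <- 200
  x <- matrix(rnorm(G * 15), G,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:15)))
  labels <- rep(c("Npos", "Nneg"), c(7, 8))
  x[1:40, labels == "Npos"] <- x[1:40, labels == "Npos"] + 5
  cv <- cross_validate_nsc(x, labels, delta_grid = seq(0, 6, by = 0.5),
                           seed = 3)
  expect_equal(cv$accuracy, 1.0)
  ## an interval of deltas achieves zero CV error
  expect_gte(sum(cv$cv_table$cv_error == 0), 2)
  ## ties broken toward the larger delta / smaller signature
  expect_equal(cv$best_delta,
               max(cv$cv_table$delta[cv$cv_table$cv_error == min(cv$cv_table$cv_error)]))
  expect_true(all(paste0("g", 1:40) %in% rownames(x)))
  expect_equal(cv$sensitivity, 1.0)
  expect_equal(cv$specificity, 1.0)

  cv2 <- cross_validate_nsc(x, labels, delta_grid = seq(0, 6, by = 0.5),
                            seed = 3)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$cv_table, cv2$cv_table)
})

test_that("permuted labels drop CV accuracy to the majority-class frequency", {
  set.seed(25)
  G <- 100
  x <- matrix(rnorm(G * 16), G,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:16)))
  accs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    labels <- sample(rep(c("Npos", "Nneg"), c(9, 7)))
    cross_validate_nsc(x, labels, delta_grid = seq(0, 3, by = 0.5),
                       seed = s)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 9 / 16), 0.15)
})

test_that("centroid validator scores, ties and exact randomization p-values", {
  set.seed(26)
  sig <- paste0("g", 1:4)
  tr <- matrix(rnorm(4 * 10), 4, dimnames = list(sig, paste0("t", 1:10)))
  labels <- rep(c("Nneg", "Npos"), each = 5)
  centA <- rowMeans(tr[, labels == "Nneg"])

  ## validation sample exactly at the Nneg centroid
  va <- cbind(v1 = centA)
  rep_ <- centroid_validator(tr, labels, va, "Nneg", sig,
                             n_randomizations = 1000, seed = 1)
  expect_equal(rep_$samples$mse_Nneg, 0)
  expect_equal(rep_$samples$predicted, "Nneg")
  expect_true(rep_$exact)  # 4! = 24 <= 1000 permutations enumerated
  ## only permutations reproducing the zero score count; p is tiny
  expect_lte(rep_$samples$p_rand, 1 / 24 + 1e-12)

  ## exhaustive-permutation oracle for the randomization p
  va2 <- cbind(v2 = rnorm(4, mean = centA, sd = 0.5))
  rownames(va2) <- sig
  rep2 <- centroid_validator(tr, labels, va2, "Nneg", sig,
                             n_randomizations = 1000, seed = 2)
  cents <- cbind(Nneg = rowMeans(tr[, 1:5]), Npos = rowMeans(tr[, 6:10]))
  perms <- oracle_permutations(4)
  null_best <- apply(perms, 1, function(pm) {
    min(colMeans((va2[pm, 1] - cents)^2))
  })
  obs <- min(colMeans((va2[, 1] - cents)^2))
  expect_equal(rep2$samples$p_rand, mean(null_best <= obs + 1e-12))

  ## tie between identical centroids goes to the first sorted label, flagged
  tr_tie <- rbind(tr, tr)
  rownames(tr_tie) <- paste0("g", 1:8)
  tr_same <- tr_tie
  tr_same[, labels == "Npos"] <- tr_tie[, labels == "Nneg"]
  va3 <- matrix(rnorm(8), 8, 1, dimnames = list(paste0("g", 1:8), "v3"))
  rep3 <- centroid_validator(tr_same, labels, va3, "Npos", paste0("g", 1:8),
                             n_randomizations = 50, seed = 3)
  expect_true(rep3$samples$tie)
  expect_equal(rep3$samples$predicted, "Nneg")

  ## Monte-Carlo path uses the add-one estimate
  rep4 <- centroid_validator(tr_tie, labels, va3, "Npos", paste0("g", 1:8),
                             n_randomizations = 50, seed = 4)
  expect_false(rep4$exact)  # 8! > 50
  expect_gte(rep4$samples$p_rand, 1 / 51)

  expect_error(centroid_validator(tr, labels, va, "Nneg", character(0)),
               "empty")
  expect_error(centroid_validator(tr, labels, va, "unknown", sig),
               "labels")
})

test_that("a single-gene signature is validated without error", {
  set.seed(28)
  tr <- matrix(rnorm(3 * 8), 3, dimnames = list(paste0("g", 1:3),
                                                paste0("t", 1:8)))
  labels <- rep(c("Nneg", "Npos"), each = 4)
  tr["g1", labels == "Npos"] <- tr["g1", labels == "Npos"] + 5
  va <- matrix(c(0, 0, 0, 5, 0, 0), 3,
               dimnames = list(paste0("g", 1:3), c("v1", "v2")))
  rep_ <- centroid_validator(tr, labels, va, c("Nneg", "Npos"), "g1",
                             n_randomizations = 100, seed = 1)
  expect_equal(rep_$samples$predicted, c("Nneg", "Npos"))
  expect_true(rep_$exact)  # 1! = 1 permutation
  expect_equal(rep_$samples$p_rand, c(1, 1))
})

test_that("validator confusion matrix and performance summaries are coherent", {
  set.seed(27)
  G <- 30
  tr <- matrix(rnorm(G * 12), G, dimnames = list(paste0("g", 1:G),
                                                 paste0("t", 1:12)))
  labels <- rep(c("Nneg", "Npos"), each = 6)
  tr[1:10, labels == "Npos"] <- tr[1:10, labels == "Npos"] + 4
  va <- matrix(rnorm(G * 8), G, dimnames = list(paste0("g", 1:G),
                                                paste0("v", 1:8)))
  vlab <- rep(c("Nneg", "Npos"), each = 4)
  va[1:10, vlab == "Npos"] <- va[1:10, vlab == "Npos"] + 4
  rep_ <- centroid_validator(tr, labels, va, vlab, paste0("g", 1:10),
                             n_randomizations = 200, seed = 5)
  expect_equal(sum(rep_$confusion), 8)
  cm <- rep_$confusion
  expect_equal(rep_$accuracy, sum(diag(cm)) / sum(cm))
  tp <- cm["Npos", "Npos"]; fn <- cm["Nneg", "Npos"]
  tn <- cm["Nneg", "Nneg"]; fp <- cm["Npos", "Nneg"]
  expect_equal(rep_$sensitivity, tp / (tp + fn))
  expect_equal(rep_$specificity, tn / (tn + fp))
})
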