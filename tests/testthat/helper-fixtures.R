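## Shared fixture builders. Everything is generated in code at test time.

## Small random count matrix with dimnames.
random_counts <- function(n_genes, n_samples, mu = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, mu), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  count_matrix(m)
}

## Gaussian expression with block cluster structure: each cluster gets its
## own up-shifted gene module, so clusters are separable by correlation.
blob_expression <- function(n_genes, cluster_sizes, module_size, effect,
                            seed = 1) {
  set.seed(seed)
  n <- sum(cluster_sizes)
  x <- matrix(rnorm(n_genes * n), nrow = n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  cl <- rep(seq_along(cluster_sizes), cluster_sizes)
  for (k in seq_along(cluster_sizes)) {
    rows <- ((k - 1) * module_size + 1):(k * module_size)
    x[rows, cl == k] <- x[rows, cl == k] + effect
  }
  list(expr = x, cluster = cl)
}

## Independent 2x2 Fisher oracle: enumerate the free cell with dhyper.
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Brute-force diagonal-covariance nearest-centroid classifier, written from
## the discriminant definition independently of the package internals.
oracle_nearest_centroid <- function(expr, labels, newdata, priors = NULL) {
  labels <- droplevels(as.factor(labels))
  lev <- levels(labels)
  n <- ncol(expr); K <- length(lev)
  cent <- sapply(lev, function(l) rowMeans(expr[, labels == l, drop = FALSE]))
  ss <- rowSums(sapply(seq_len(n), function(j) {
    (expr[, j] - cent[, as.character(labels[j])])^2
  }))
  s <- sqrt(ss / (n - K))
  s0 <- median(s)
  if (is.null(priors)) priors <- table(labels) / n
  apply(newdata, 2, function(x) {
    disc <- vapply(lev, function(l) {
      sum((x - cent[, l])^2 / (s + s0)^2) - 2 * log(priors[[l]])
    }, numeric(1))
    lev[which.min(disc)]
  })
}

## All permutations of seq_len(n), independent of the package's generator
## (iterative insertion rather than recursion) - oracle for randomization p.
oracle_permutations <- function(n) {
  perms <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- matrix(0L, nrow(perms) * k, k)
    r <- 0L
    for (i in seq_len(nrow(perms))) for (pos in seq_len(k)) {
      r <- r + 1L
      out[r, ] <- append(perms[i, ], k, after = pos - 1L)
    }
    perms <- out
  }
  perms
}
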