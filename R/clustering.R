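#' 1 - Pearson correlation sample distance
#'
#' @param expr Numeric matrix, genes x samples; every sample must have
#'   nonzero variance across genes.
#' @return Symmetric distance matrix in \[0, 2\] with zero diagonal.
#' @export
pearson_distance <- function(expr) {
  if (!is.matrix(expr) || ncol(expr) < 2L) {
    stop("'expr' must be a matrix with at least 2 samples", call. = FALSE)
  }
  v <- apply(expr, 2, stats::var)
  if (any(v == 0)) {
    stop(sprintf("zero-variance sample(s): %s",
                 paste(colnames(expr)[v == 0], collapse = ", ")), call. = FALSE)
  }
  d <- 1 - stats::cor(expr)
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Thin wrapper over `stats::hclust(method = "average")` taking a symmetric
#' distance matrix; cutting the tree at the final merge yields the two
#' top-level sample groups used by the SD-cutoff sweep.
#'
#' @param dist_mat Symmetric distance matrix (or a `dist` object).
#' @return An `hclust` object.
#' @export
average_linkage <- function(dist_mat) {
  if (!inherits(dist_mat, "dist")) {
    if (!is.matrix(dist_mat) || nrow(dist_mat) != ncol(dist_mat) ||
        max(abs(dist_mat - t(dist_mat))) > 1e-8) {
      stop("'dist_mat' must be a symmetric square matrix", call. = FALSE)
    }
    dist_mat <- stats::as.dist(dist_mat)
  }
  stats::hclust(dist_mat, method = "average")
}

## Mean pairwise Pearson correlation between samples in different top-level
## groups of the dendrogram — the anti-correlation score of the SD sweep.
top_split_anticorrelation <- function(expr) {
  d <- pearson_distance(expr)
  h <- average_linkage(d)
  grp <- stats::cutree(h, k = 2)
  r <- stats::cor(expr)
  cross <- outer(grp, grp, FUN = "!=")
  list(score = mean(r[cross]), split = grp)
}

#' Iterative SD-cutoff selection for clustering
#'
#' Genes with weak variability can bias sample clustering through spurious
#' random correlations. The sweep evaluates a grid of candidate SD cutoffs
#' (empirical quantiles of the gene-wise SDs): for each cutoff it retains the
#' genes whose SD exceeds the cutoff, clusters the samples (1 - Pearson,
#' average linkage), cuts the hierarchy into its two top-level groups, and
#' scores the cutoff by the mean pairwise correlation between samples in
#' different top groups (the anti-correlation `A`). Splits with `A` close to
#' zero are treated as chance groupings; the chosen cutoff minimizes `A`
#' subject to `A < 0` and at least `min_genes` genes retained.
#'
#' @param expr Numeric matrix, genes x samples (typically logCPM).
#' @param min_genes Floor on the retained gene count (default 3000).
#' @param n_cutoffs Number of evenly spaced SD quantiles to sweep
#'   (default 40).
#' @param center Subtract each gene's mean before computing sample
#'   correlations (default TRUE). Without centering, the shared
#'   gene-abundance profile forces all sample correlations toward +1 and no
#'   split can ever show anti-correlation.
#' @return list of class `sd_selection`: `sweep` (data.frame with `cutoff`,
#'   `genes_retained`, `anticorrelation`, `eligible`), `status` (`"ok"` or
#'   `"no_structure"`), `chosen_cutoff`, `chosen_genes` (gene ids), and
#'   `top_split` (two-group sample assignment at the chosen cutoff).
#' @export
select_sd_cutoff <- function(expr, min_genes = 3000L, n_cutoffs = 40L,
                             center = TRUE) {
  if (!is.matrix(expr)) stop("'expr' must be a matrix", call. = FALSE)
  if (nrow(expr) < min_genes) {
    stop(sprintf("only %d genes available but min_genes = %d",
                 nrow(expr), min_genes), call. = FALSE)
  }
  sds <- row_sds(expr)
  if (center) expr <- expr - rowMeans(expr)
  cutoffs <- unique(stats::quantile(sds, probs = seq(0, 1, length.out = n_cutoffs + 1L),
                                    names = FALSE)[seq_len(n_cutoffs)])
  sweep <- data.frame(cutoff = cutoffs, genes_retained = NA_integer_,
                      anticorrelation = NA_real_)
  splits <- vector("list", length(cutoffs))
  for (i in seq_along(cutoffs)) {
    keep <- sds > cutoffs[i]
    ## quantile 0 can leave zero-SD genes out only if their SD == min; keep
    ## the ">=" semantics of "genes above the cutoff" strict throughout.
    if (i == 1L && sum(keep) < nrow(expr)) keep <- sds >= cutoffs[i]
    sweep$genes_retained[i] <- sum(keep)
    if (sum(keep) < 2L) next
    sub <- expr[keep, , drop = FALSE]
    if (any(apply(sub, 2, stats::var) == 0)) next
    ts <- top_split_anticorrelation(sub)
    sweep$anticorrelation[i] <- ts$score
    splits[[i]] <- ts$split
  }
  sweep$eligible <- !is.na(sweep$anticorrelation) &
    sweep$anticorrelation < 0 & sweep$genes_retained >= min_genes
  if (!any(sweep$eligible)) {
    return(structure(list(sweep = sweep, status = "no_structure",
                          chosen_cutoff = NA_real_, chosen_genes = character(),
                          top_split = NULL),
                     class = "sd_selection"))
  }
  best <- which(sweep$eligible)[which.min(sweep$anticorrelation[sweep$eligible])]
  keep <- sds > sweep$cutoff[best]
  if (best == 1L && sum(keep) < sweep$genes_retained[1L]) keep <- sds >= sweep$cutoff[best]
  structure(list(sweep = sweep, status = "ok",
                 chosen_cutoff = sweep$cutoff[best],
                 chosen_genes = rownames(expr)[keep],
                 top_split = splits[[best]]),
            class = "sd_selection")
}

#' Subsampled consensus clustering
#'
#' Estimates cluster stability by repeated subsampling: each iteration draws
#' `ceiling(subsample_fraction * n)` samples without replacement, clusters
#' them (1 - Pearson distance, average linkage) and cuts into `k` clusters.
#' `consensus(i, j)` is the fraction of iterations sampling both i and j in
#' which they co-clustered. Final assignments come from average-linkage
#' clustering of `1 - consensus` cut at `k`. When `k_range` covers several
#' values the full sweep is reported with consensus-CDF areas (and the
#' between-k delta areas) so the cluster count can be judged; `k` itself
#' defaults to 3, the number of expression groups the workflow targets.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param k Number of clusters for the reported assignment (default 3).
#' @param k_range Integer vector of cluster counts to sweep (default `k`).
#' @param n_iterations Subsampling iterations (default 10000).
#' @param subsample_fraction Fraction of samples kept per iteration
#'   (default 0.6, i.e. leave-out 40%).
#' @param seed Integer seed (mandatory: the procedure is stochastic).
#' @param center Subtract each gene's mean before computing sample
#'   correlations (default TRUE; see [select_sd_cutoff()]).
#' @return list of class `consensus_result`: `consensus` (samples x samples,
#'   in \[0, 1\]), `co_sampled` (integer denominators), `assignments` (named
#'   integer vector), `k`, `n_iterations`, `subsample_fraction`, `seed`, and
#'   `sweep` (per-k list with consensus matrix, assignments and CDF area).
#' @export
consensus_cluster <- function(expr, k = 3L, k_range = k,
                              n_iterations = 10000L,
                              subsample_fraction = 0.6, seed,
                              center = TRUE) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (center) expr <- expr - rowMeans(expr)
  stopifnot_scalar_count(n_iterations, "n_iterations")
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop("'subsample_fraction' must lie in (0, 1]", call. = FALSE)
  }
  n <- ncol(expr)
  m <- ceiling(subsample_fraction * n)
  if (m <= max(k_range)) {
    stop("subsample must keep more samples than the largest k", call. = FALSE)
  }
  sample_ids <- colnames(expr)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))

  sweep <- with_seed(derive_seed(seed, "consensus"), {
    lapply(k_range, function(kk) {
      conn <- matrix(0, n, n); cs <- matrix(0, n, n)
      for (it in seq_len(n_iterations)) {
        idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
        sub <- expr[, idx, drop = FALSE]
        lab <- stats::cutree(average_linkage(1 - stats::cor(sub)), k = kk)
        cs[idx, idx] <- cs[idx, idx] + 1
        for (c in unique(lab)) {
          ic <- idx[lab == c]
          conn[ic, ic] <- conn[ic, ic] + 1
        }
      }
      cons <- conn / pmax(cs, 1)
      dimnames(cons) <- list(sample_ids, sample_ids)
      assign <- stats::cutree(average_linkage(1 - cons), k = kk)
      vals <- cons[upper.tri(cons)]
      cdf_area <- mean(stats::ecdf(vals)(seq(0, 1, by = 0.01)))
      list(k = kk, consensus = cons, co_sampled = cs, assignments = assign,
           cdf_area = cdf_area)
    })
  })
  names(sweep) <- paste0("k", k_range)
  chosen <- sweep[[match(k, k_range)]]
  if (is.null(chosen)) stop("'k' must be an element of 'k_range'", call. = FALSE)
  structure(list(consensus = chosen$consensus, co_sampled = chosen$co_sampled,
                 assignments = chosen$assignments, k = k,
                 n_iterations = as.integer(n_iterations),
                 subsample_fraction = subsample_fraction, seed = seed,
                 sweep = sweep),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d samples, k = %d, %d iterations (%.0f%% subsampling)\n",
              nrow(x$consensus), x$k, x$n_iterations, 100 * x$subsample_fraction))
  print(table(x$assignments))
  invisible(x)
}
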