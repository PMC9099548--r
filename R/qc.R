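#' Sample-level quality filter
#'
#' Applies the cohort inclusion rule to a count matrix: a sample is kept if
#' and only if its total count of aligned sequences is strictly greater than
#' `min_aligned` AND its number of zero-count genes is strictly lower than
#' `max_zero_genes`. Both inequalities are strict: a sample at exactly the
#' threshold is excluded. The rule guards against normalization bias from an
#' imbalanced number of zero-count genes, the typical failure mode of
#' degraded FFPE libraries.
#'
#' @param counts A [count_matrix()] or coercible matrix.
#' @param min_aligned Minimum aligned-sequence total (default 5,000,000,
#'   interpreted as counted fragments).
#' @param max_zero_genes Maximum tolerated number of zero-count genes per
#'   sample (default 3500).
#' @param aligned_totals Optional named numeric vector of per-sample aligned
#'   totals overriding the column sums (useful when raw alignment totals are
#'   known separately from the counted matrix).
#' @return list with `counts` (the filtered [count_matrix()], possibly with
#'   zero samples) and `report` (data.frame, one row per input sample:
#'   `sample_id`, `aligned_total`, `zero_gene_count`, `included`, `reason`).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, seed = 3))
#' qc <- sample_qc(sim$counts, min_aligned = 0, max_zero_genes = 200)
#' qc$report
#' @export
sample_qc <- function(counts, min_aligned = 5e6, max_zero_genes = 3500,
                      aligned_totals = NULL) {
  x <- as_count_matrix(counts)
  totals <- x$library_sizes
  if (!is.null(aligned_totals)) {
    if (is.null(names(aligned_totals)) ||
        !all(x$sample_ids %in% names(aligned_totals))) {
      stop("'aligned_totals' must be named with all sample ids", call. = FALSE)
    }
    totals <- aligned_totals[x$sample_ids]
  }
  zeros <- colSums(x$counts == 0)
  pass_reads <- totals > min_aligned
  pass_zeros <- zeros < max_zero_genes
  included <- pass_reads & pass_zeros
  reason <- rep("ok", length(included))
  reason[!pass_reads & pass_zeros] <- "low_aligned_total"
  reason[pass_reads & !pass_zeros] <- "too_many_zero_genes"
  reason[!pass_reads & !pass_zeros] <- "low_aligned_total;too_many_zero_genes"
  report <- data.frame(sample_id = x$sample_ids,
                       aligned_total = as.numeric(totals),
                       zero_gene_count = as.integer(zeros),
                       included = included,
                       reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  if (!any(included)) warning("all samples excluded by QC", call. = FALSE)
  list(counts = count_matrix(x$counts[, included, drop = FALSE]),
       report = report)
}
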