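#' Gene-by-sample count matrix
#'
#' Light container for the pipeline's central object: a non-negative integer
#' matrix of read counts with genes in rows and samples in columns.
#' Library sizes are always the column sums of the counts, recomputed at
#' construction so the two can never drift apart.
#'
#' @param counts Non-negative integer matrix, genes x samples. Row names are
#'   taken as gene identifiers and column names as sample identifiers; both
#'   must be present and unique.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `gene_ids`, `sample_ids` and `library_sizes`.
#' @examples
#' m <- matrix(rpois(20, 10), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' cm <- count_matrix(m)
#' cm$library_sizes
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("'counts' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(counts) < 1L) {
    stop("'counts' must have at least one gene", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("'counts' must be finite and non-negative", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("'counts' must be integer-valued", call. = FALSE)
  }
  gid <- rownames(counts); sid <- colnames(counts)
  if (is.null(gid) || anyDuplicated(gid)) {
    stop("row names (gene ids) must be present and unique", call. = FALSE)
  }
  if (ncol(counts) == 0L) {
    sid <- character(0)  # QC may legitimately exclude every sample
  } else if (is.null(sid) || anyDuplicated(sid)) {
    stop("column names (sample ids) must be present and unique", call. = FALSE)
  }
  structure(
    list(counts = counts, gene_ids = gid, sample_ids = sid,
         library_sizes = colSums(counts)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  cat(sprintf("library sizes: %s .. %s\n",
              format(min(x$library_sizes), big.mark = ","),
              format(max(x$library_sizes), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

## Accept either a count_matrix or a bare matrix in user-facing entry points.
as_count_matrix <- function(x) {
  if (inherits(x, "count_matrix")) return(x)
  count_matrix(x)
}

#' Read / write count matrices as TSV
#'
#' Counts are stored with genes in rows; the first column holds gene ids and
#' the header holds sample ids. Gzipped files are handled transparently by
#' extension.
#'
#' @param path File path.
#' @return `read_counts_tsv()` returns a [count_matrix()];
#'   `write_counts_tsv()` returns `path` invisibly.
#' @export
read_counts_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  storage.mode(m) <- "double"
  count_matrix(m)
}

#' @param x A [count_matrix()] or coercible matrix.
#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(x, path) {
  x <- as_count_matrix(x)
  dt <- data.table::data.table(gene_id = x$gene_ids)
  dt <- cbind(dt, data.table::as.data.table(x$counts))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read / write sample metadata as TSV
#'
#' @param path File path.
#' @return A `data.frame` with one row per sample.
#' @export
read_metadata_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

#' @param meta A data.frame of per-sample metadata.
#' @rdname read_metadata_tsv
#' @export
write_metadata_tsv <- function(meta, path) {
  data.table::fwrite(meta, path, sep = "\t")
  invisible(path)
}
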