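#' Read a GMT gene-set collection
#'
#' Parses the tab-separated MSigDB exchange format: one set per line with
#' fields name, description, then member genes. Empty lines are skipped;
#' case is preserved; duplicate members within a line are removed with a
#' warning.
#'
#' @param path GMT file path.
#' @return list of class `gene_set_collection` with `sets` (named list of
#'   character vectors) and `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- list(); descs <- character()
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    nm <- fields[1]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate members in set '%s' (line %d); deduplicated",
                      nm, i), call. = FALSE)
      genes <- unique(genes)
    }
    if (nm %in% names(sets)) {
      stop(sprintf("duplicate set name '%s' (line %d)", nm, i), call. = FALSE)
    }
    sets[[nm]] <- genes
    descs[nm] <- fields[2]
  }
  structure(list(sets = sets, descriptions = descs),
            class = "gene_set_collection")
}

#' @param collection A `gene_set_collection`.
#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]] %||% "", collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene list
#'
#' For each set, tests whether the query list overlaps the set more than
#' expected by chance when drawing `n` genes from the universe of `N`:
#' `p = P(X >= k)` under Hypergeometric(N, K, n), with Benjamini-Hochberg
#' adjustment across sets. The query is intersected with the universe first;
#' set members outside the universe are ignored.
#'
#' @param query Character vector of genes of interest (e.g. a DE list).
#' @param universe Character vector of all assayed genes (typically the
#'   genes surviving QC).
#' @param collection A `gene_set_collection` from [read_gmt()].
#' @return data.frame sorted by `q`: `set`, `overlap` (k), `set_size` (K),
#'   `query_size` (n), `universe_size` (N), `p`, `q`, `genes`
#'   (semicolon-joined overlap members).
#' @export
ora <- function(query, universe, collection) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- intersect(unique(as.character(query)), universe)
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    K <- length(members)
    hit <- intersect(query, members)
    k <- length(hit)
    p <- if (K == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p,
               genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), p = numeric(),
                      q = numeric(), genes = character()))
  }
  out$q <- bh_adjust(out$p)
  out <- out[order(out$q, out$p, out$set), ]
  rownames(out) <- NULL
  out[, c("set", "overlap", "set_size", "query_size", "universe_size",
          "p", "q", "genes")]
}
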