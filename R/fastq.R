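## FASTQ records travel as a data.frame with columns read_id, sequence,
## qualities (Phred+33). Reading validates the 4-line block structure and
## reports the index of the first malformed record; reverse-complementation
## and string reversal are delegated to Biostrings.

fastq_connection <- function(path, open = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path; ".gz" handled by extension.
#' @return data.frame with columns `read_id` (without the leading `@`),
#'   `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  con <- fastq_connection(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      qualities = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ: record %d is not a complete 4-line block",
                 length(lines) %/% 4L + 1L), call. = FALSE)
  }
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad) > 0L) {
    stop(sprintf("malformed FASTQ: record %d is invalid", bad[1L]), call. = FALSE)
  }
  data.frame(read_id = sub("^@", "", hdr), sequence = seqs, qualities = quals,
             stringsAsFactors = FALSE)
}

#' @param records data.frame with columns `read_id`, `sequence`, `qualities`.
#' @rdname read_fastq
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("read_id", "sequence", "qualities") %in% names(records)))
  con <- fastq_connection(path, "wt")
  on.exit(close(con))
  if (nrow(records) > 0L) {
    out <- as.vector(rbind(paste0("@", records$read_id),
                           records$sequence,
                           "+",
                           records$qualities))
    writeLines(out, con)
  }
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

reverse_str <- function(x) {
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

#' Split an overlap-merged read into a non-overlapping read pair
#'
#' Inverts read merging so that merged single-end fragments can re-enter a
#' paired-end alignment workflow. The merged read of length L is cut at the
#' midpoint: R1 keeps the first `ceiling(L/2)` bases in original orientation;
#' R2 is the reverse complement of the remaining `floor(L/2)` bases with
#' reversed qualities, restoring standard FR pair orientation. R1 and R2
#' partition the fragment with no overlap.
#'
#' @param record A list or one-row data.frame with `read_id`, `sequence`,
#'   `qualities` (equal lengths, length >= 2).
#' @param id_suffixes Character pair appended to the read id (default
#'   `"/1"`, `"/2"`).
#' @return list with elements `r1` and `r2`, each a list with `read_id`,
#'   `sequence`, `qualities`.
#' @examples
#' split_merged_read(list(read_id = "m1", sequence = "ACGT", qualities = "IIII"))
#' @export
split_merged_read <- function(record, id_suffixes = c("/1", "/2")) {
  s <- as.character(record$sequence)
  q <- as.character(record$qualities)
  L <- nchar(s)
  if (L < 2L) stop("merged read must have length >= 2", call. = FALSE)
  if (nchar(q) != L) stop("sequence/quality length mismatch", call. = FALSE)
  cut <- ceiling(L / 2)
  list(
    r1 = list(read_id = paste0(record$read_id, id_suffixes[1]),
              sequence = substr(s, 1L, cut),
              qualities = substr(q, 1L, cut)),
    r2 = list(read_id = paste0(record$read_id, id_suffixes[2]),
              sequence = revcomp(substr(s, cut + 1L, L)),
              qualities = reverse_str(substr(q, cut + 1L, L)))
  )
}

#' Split a FASTQ of merged reads into R1/R2 files
#'
#' Applies [split_merged_read()] to every record, preserving order.
#'
#' @param in_path Input FASTQ of merged single-end reads.
#' @param out_r1_path,out_r2_path Output FASTQ paths.
#' @param id_suffixes Read-id suffix pair.
#' @return Number of records split (invisibly also written to both outputs).
#' @export
split_merged_fastq <- function(in_path, out_r1_path, out_r2_path,
                               id_suffixes = c("/1", "/2")) {
  rec <- read_fastq(in_path)
  n <- nrow(rec)
  if (n == 0L) {
    write_fastq(rec, out_r1_path)
    write_fastq(rec, out_r2_path)
    return(0L)
  }
  L <- nchar(rec$sequence)
  if (any(L < 2L)) {
    stop(sprintf("record %d: merged read shorter than 2 bases", which(L < 2L)[1]),
         call. = FALSE)
  }
  cut <- ceiling(L / 2)
  r1 <- data.frame(read_id = paste0(rec$read_id, id_suffixes[1]),
                   sequence = substr(rec$sequence, 1L, cut),
                   qualities = substr(rec$qualities, 1L, cut),
                   stringsAsFactors = FALSE)
  r2 <- data.frame(read_id = paste0(rec$read_id, id_suffixes[2]),
                   sequence = revcomp(substr(rec$sequence, cut + 1L, L)),
                   qualities = reverse_str(substr(rec$qualities, cut + 1L, L)),
                   stringsAsFactors = FALSE)
  write_fastq(r1, out_r1_path)
  write_fastq(r2, out_r2_path)
  n
}

#' Reconstruct a merged sequence from a split pair
#'
#' Round-trip identity: `merge_split_pair(r1, r2)` equals the original merged
#' sequence for any output of [split_merged_read()].
#'
#' @param r1_seq,r2_seq Character vectors of R1 and R2 sequences.
#' @return Character vector of reconstructed merged sequences.
#' @export
merge_split_pair <- function(r1_seq, r2_seq) {
  paste0(r1_seq, revcomp(r2_seq))
}
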