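#' Simulation configuration for the synthetic EEC cohort
#'
#' Builds the configuration object consumed by [simulate_counts()]. Defaults
#' emulate the study cohort the downstream analysis assumes: 28 FFPE tumor
#' samples in three latent expression clusters (A: 7 samples, all N+;
#' B: 10 samples, 6 N+ / 4 N-; C: 11 samples, 3 N+ / 8 N-), ~18,000 genes
#' with negative-binomial counts, FFPE-like dropout, and block-structured
#' differentially expressed gene modules driving the cluster separation.
#'
#' @param n_genes Number of genes.
#' @param cluster_sizes Named integer vector: samples per latent cluster.
#' @param cluster_npos Named integer vector: number of N+ samples per cluster
#'   (the remainder are N-). Must not exceed `cluster_sizes`.
#' @param de_block_sizes Integer vector: number of genes in each DE module.
#' @param log2_fc Numeric vector, one per module: log2 fold change applied to
#'   the module's genes in its target cluster.
#' @param module_cluster Character vector, one per module: the cluster in
#'   which the module is up/down-regulated. Each module targets exactly one
#'   cluster contrast (that cluster vs the rest).
#' @param baseline_mean_log,baseline_sd_log Mean and SD of the log-normal
#'   distribution of gene baseline abundances (natural-log scale).
#' @param dispersion_median Median gene-wise NB dispersion phi
#'   (variance = mu + phi * mu^2). FFPE material is noisy; the default 0.15
#'   sits at the upper end of typical human bulk RNA-seq.
#' @param dispersion_shape sdlog of the log-normal gene dispersion
#'   distribution.
#' @param libsize_range Length-2 numeric: sequencing depths are drawn
#'   log-uniformly over this range. The default straddles the 5M read QC
#'   inclusion threshold so that filtering is exercised on realistic input.
#' @param zero_inflation Probability that any count is zeroed post-hoc
#'   (independent Bernoulli dropout emulating FFPE degradation).
#' @param seed Integer seed governing all draws; per-stage sub-streams are
#'   derived deterministically from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 18000L,
                       cluster_sizes = c(A = 7L, B = 10L, C = 11L),
                       cluster_npos = c(A = 7L, B = 6L, C = 3L),
                       de_block_sizes = c(500L, 500L, 500L),
                       log2_fc = c(2, 2, -2),
                       module_cluster = c("A", "B", "C"),
                       baseline_mean_log = log(5),
                       baseline_sd_log = 1.8,
                       dispersion_median = 0.15,
                       dispersion_shape = 0.5,
                       libsize_range = c(5e6, 2e7),
                       zero_inflation = 0.03,
                       seed = 1L) {
  stopifnot_scalar_count(n_genes, "n_genes")
  if (length(cluster_sizes) < 1L || any(cluster_sizes < 1L)) {
    stop("'cluster_sizes' must be positive integers", call. = FALSE)
  }
  if (is.null(names(cluster_sizes))) names(cluster_sizes) <- LETTERS[seq_along(cluster_sizes)]
  if (!identical(sort(names(cluster_npos)), sort(names(cluster_sizes)))) {
    stop("'cluster_npos' must be named like 'cluster_sizes'", call. = FALSE)
  }
  cluster_npos <- cluster_npos[names(cluster_sizes)]
  if (any(cluster_npos < 0L) || any(cluster_npos > cluster_sizes)) {
    stop("cluster N+ counts must lie in [0, cluster size]", call. = FALSE)
  }
  nm <- length(de_block_sizes)
  if (nm > 0L) {
    if (any(de_block_sizes < 1L)) stop("'de_block_sizes' must be positive", call. = FALSE)
    if (length(log2_fc) != nm || length(module_cluster) != nm) {
      stop("'log2_fc' and 'module_cluster' must have one entry per DE module",
           call. = FALSE)
    }
    if (!all(module_cluster %in% names(cluster_sizes))) {
      stop("'module_cluster' entries must name existing clusters", call. = FALSE)
    }
    if (sum(de_block_sizes) > n_genes) {
      stop("DE modules cannot cover more than 'n_genes' genes", call. = FALSE)
    }
  }
  if (zero_inflation < 0 || zero_inflation > 1) {
    stop("'zero_inflation' must be a probability in [0, 1]", call. = FALSE)
  }
  if (length(libsize_range) != 2L || any(libsize_range <= 0) ||
      libsize_range[1] > libsize_range[2]) {
    stop("'libsize_range' must be an increasing positive pair", call. = FALSE)
  }
  if (dispersion_median <= 0 || dispersion_shape <= 0) {
    stop("dispersion parameters must be positive", call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes),
    cluster_sizes = as.integer(cluster_sizes) |> stats::setNames(names(cluster_sizes)),
    cluster_npos = as.integer(cluster_npos) |> stats::setNames(names(cluster_sizes)),
    de_block_sizes = as.integer(de_block_sizes),
    log2_fc = as.numeric(log2_fc),
    module_cluster = as.character(module_cluster),
    baseline_mean_log = baseline_mean_log,
    baseline_sd_log = baseline_sd_log,
    dispersion_median = dispersion_median,
    dispersion_shape = dispersion_shape,
    libsize_range = as.numeric(libsize_range),
    zero_inflation = zero_inflation,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a synthetic EEC cohort count matrix
#'
#' Draws gene-wise negative-binomial counts with library-size offsets.
#' Gene baseline abundances are log-normal; gene dispersions are log-normal;
#' each DE module multiplies its genes' means by `2^log2_fc` in its target
#' cluster; a `zero_inflation` fraction of entries is zeroed at random.
#' Fully reproducible for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (a [count_matrix()]) and `metadata`
#'   (data.frame: `sample_id`, `node_status` in `{Npos, Nneg}`,
#'   `true_cluster`).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 500, seed = 7))
#' table(sim$metadata$node_status)
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config", call. = FALSE)
  G <- config$n_genes
  sizes <- config$cluster_sizes
  n <- sum(sizes)
  cl_names <- names(sizes)
  cluster_of <- rep(cl_names, sizes)

  ## module membership: consecutive gene blocks, one target cluster each
  lfc_mat <- matrix(0, nrow = G, ncol = n)
  module_id <- integer(G)
  if (length(config$de_block_sizes) > 0L) {
    ends <- cumsum(config$de_block_sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (m in seq_along(ends)) {
      idx <- starts[m]:ends[m]
      module_id[idx] <- m
      lfc_mat[idx, cluster_of == config$module_cluster[m]] <- config$log2_fc[m]
    }
  }

  sample_ids <- sprintf("S%02d", seq_len(n))
  node <- unlist(lapply(cl_names, function(cl) {
    k <- config$cluster_npos[[cl]]
    rep(c("Npos", "Nneg"), c(k, sizes[[cl]] - k))
  }), use.names = FALSE)

  counts <- with_seed(derive_seed(config$seed, "counts"), {
    log_abund <- stats::rnorm(G, config$baseline_mean_log, config$baseline_sd_log)
    rel <- exp(log_abund); rel <- rel / sum(rel)
    phi <- stats::rlnorm(G, meanlog = log(config$dispersion_median),
                         sdlog = config$dispersion_shape)
    lr <- log(config$libsize_range)
    depth <- exp(stats::runif(n, lr[1], lr[2]))
    mu <- (rel %o% depth) * 2^lfc_mat
    x <- matrix(stats::rnbinom(G * n, mu = mu, size = rep(1 / phi, n)),
                nrow = G, ncol = n)
    if (config$zero_inflation > 0) {
      drop <- matrix(stats::runif(G * n) < config$zero_inflation, nrow = G)
      x[drop] <- 0L
    }
    dimnames(x) <- list(sprintf("gene_%05d", seq_len(G)), sample_ids)
    x
  })

  meta <- data.frame(sample_id = sample_ids,
                     node_status = node,
                     true_cluster = cluster_of,
                     stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = rownames(counts),
                      module = module_id,
                      log2_fc = ifelse(module_id > 0, config$log2_fc[pmax(module_id, 1L)], 0),
                      target_cluster = ifelse(module_id > 0,
                                              config$module_cluster[pmax(module_id, 1L)], NA),
                      stringsAsFactors = FALSE)
  list(counts = count_matrix(counts), metadata = meta, gene_truth = truth,
       config = config)
}

## Per-arm sampling probabilities and tumor-size summaries used by
## simulate_clinical_table(); cell frequencies follow the 12 N- / 16 N+
## cohort composition.
.clinical_freqs <- function() {
  list(
    categorical = list(
      angioinvasion = list(levels = c("absence", "non_substantial", "substantial"),
                           Nneg = c(9, 1, 2), Npos = c(3, 4, 9)),
      stromal_reaction = list(levels = c("presence", "absence"),
                              Nneg = c(5, 7), Npos = c(12, 4)),
      melf_pattern = list(levels = c("presence", "absence"),
                          Nneg = c(3, 9), Npos = c(10, 6)),
      inflammatory_infiltration = list(levels = c("presence", "absence"),
                                       Nneg = c(5, 7), Npos = c(6, 10)),
      perinervous_invasion = list(levels = c("presence", "absence"),
                                  Nneg = c(1, 11), Npos = c(4, 12)),
      histological_grade = list(levels = c("low", "high"),
                                Nneg = c(3, 9), Npos = c(5, 11)),
      myometrial_invasion = list(levels = c("le50", "gt50"),
                                 Nneg = c(4, 8), Npos = c(6, 10)),
      molecular_class = list(levels = c("POLE", "MSI", "TP53", "NSMP"),
                             Nneg = c(0, 4, 0, 8), Npos = c(0, 9, 3, 4)),
      ctnnb1_mutation = list(levels = c("pathogenic", "wild_type"),
                             Nneg = c(5, 7), Npos = c(2, 14))
    ),
    tumor_size = list(Nneg = c(mean = 46.8, sd = 22.5),
                      Npos = c(mean = 50.1, sd = 25.9))
  )
}

#' Simulate a clinico-pathological sample table
#'
#' Draws per-sample categorical covariates with the per-arm cell frequencies
#' of the 28-sample EEC cohort (12 N- / 16 N+) and continuous tumor size from
#' per-arm normal distributions (N-: mean 46.8, SD 22.5 mm; N+: mean 50.1,
#' SD 25.9 mm).
#'
#' @param seed Integer seed.
#' @param n_nneg,n_npos Samples per arm; setting one of them to 0 yields a
#'   single-arm table.
#' @param sample_ids Optional sample identifiers (length `n_nneg + n_npos`).
#' @return data.frame with `sample_id`, `node_status` and covariate columns.
#' @export
simulate_clinical_table <- function(seed, n_nneg = 12L, n_npos = 16L,
                                    sample_ids = NULL) {
  stopifnot_scalar_count(n_nneg, "n_nneg", min = 0L)
  stopifnot_scalar_count(n_npos, "n_npos", min = 0L)
  n <- n_nneg + n_npos
  if (n < 1L) stop("at least one sample is required", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(n))
  if (length(sample_ids) != n) stop("'sample_ids' has the wrong length", call. = FALSE)
  fr <- .clinical_freqs()
  arm <- rep(c("Nneg", "Npos"), c(n_nneg, n_npos))
  with_seed(derive_seed(seed, "clinical"), {
    out <- data.frame(sample_id = sample_ids, node_status = arm,
                      stringsAsFactors = FALSE)
    for (cov in names(fr$categorical)) {
      spec <- fr$categorical[[cov]]
      draw <- character(n)
      for (a in c("Nneg", "Npos")) {
        idx <- which(arm == a)
        if (length(idx) == 0L) next
        p <- spec[[a]] / sum(spec[[a]])
        draw[idx] <- sample(spec$levels, length(idx), replace = TRUE, prob = p)
      }
      out[[cov]] <- draw
    }
    ts <- numeric(n)
    for (a in c("Nneg", "Npos")) {
      idx <- which(arm == a)
      if (length(idx) == 0L) next
      par <- fr$tumor_size[[a]]
      ts[idx] <- round(pmax(stats::rnorm(length(idx), par["mean"], par["sd"]), 1), 1)
    }
    out$tumor_size_mm <- ts
    out
  })
}

#' Simulate overlap-merged single-end reads
#'
#' Emulates the situation where R1/R2 paired-end reads of short RNA fragments
#' overlap and have been merged into single-end reads: writes a FASTQ of
#' merged fragments of length `2 * read_len - overlap`, with the ground-truth
#' split point recorded in each read name (`split=<position>`).
#'
#' @param n_pairs Number of merged records to write.
#' @param read_len Original mate length (bases).
#' @param overlap Overlap between mates; must satisfy `0 < overlap < read_len`.
#' @param seed Integer seed.
#' @param path Output FASTQ path (".gz" accepted).
#' @return `path`, invisibly; the file holds `n_pairs` records.
#' @export
simulate_merged_reads <- function(n_pairs, read_len = 75L, overlap = 50L,
                                  seed = 1L, path) {
  stopifnot_scalar_count(n_pairs, "n_pairs", min = 0L)
  stopifnot_scalar_count(read_len, "read_len", min = 2L)
  if (overlap <= 0 || overlap >= read_len) {
    stop("'overlap' must satisfy 0 < overlap < read_len", call. = FALSE)
  }
  L <- 2L * as.integer(read_len) - as.integer(overlap)
  with_seed(derive_seed(seed, "reads"), {
    seqs <- vapply(seq_len(n_pairs), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    quals <- vapply(seq_len(n_pairs), function(i) {
      intToUtf8(33L + sample(20:40, L, replace = TRUE))
    }, character(1))
    ids <- sprintf("merged_%06d split=%d len=%d", seq_len(n_pairs),
                   ceiling(L / 2), L)
    write_fastq(data.frame(read_id = ids, sequence = seqs, qualities = quals,
                           stringsAsFactors = FALSE), path)
  })
  invisible(path)
}
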