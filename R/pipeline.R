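#' Pipeline run configuration
#'
#' Collects all thresholds, stage parameters and input locations for
#' [run_pipeline()]. With no `counts_path`, the synthetic cohort generator
#' supplies the input data according to `sim`.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed; required because several stages are stochastic.
#' @param sim A [sim_config()] for synthetic input (ignored when
#'   `counts_path` is given).
#' @param counts_path,metadata_path Optional TSV inputs replacing simulation.
#' @param gmt_path Optional GMT collection for the enrichment stage.
#' @param qc_min_aligned,qc_max_zero_genes Sample QC thresholds.
#' @param fdr,min_fc DE calling thresholds.
#' @param cluster_k,cluster_iterations,cluster_fraction,cluster_min_genes
#'   Consensus-clustering parameters.
#' @param delta_grid,n_folds,n_randomizations Classifier parameters.
#' @param validation_fraction Fraction of signature-contrast samples held
#'   out (stratified) for the centroid validator.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed,
                       sim = sim_config(seed = seed),
                       counts_path = NULL, metadata_path = NULL,
                       gmt_path = NULL,
                       qc_min_aligned = 5e6, qc_max_zero_genes = 3500,
                       fdr = 0.05, min_fc = 2,
                       cluster_k = 3L, cluster_iterations = 10000L,
                       cluster_fraction = 0.6, cluster_min_genes = 3000L,
                       delta_grid = seq(0, 5, by = 0.1), n_folds = 10L,
                       n_randomizations = 1000L,
                       validation_fraction = 1 / 3) {
  if (missing(seed)) stop("'seed' is required: several stages are stochastic",
                          call. = FALSE)
  stopifnot(fdr > 0, min_fc > 0, cluster_min_genes > 0,
            qc_min_aligned >= 0, qc_max_zero_genes > 0)
  structure(as.list(environment()), class = "run_config")
}

stage_run <- function(name, expr) {
  message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Remove node-discordant samples from a cluster
#'
#' The refinement step taken before the signature contrast: within the given
#' cluster, samples whose node-status label disagrees with the cluster's
#' majority label are dropped (e.g. turning the N--enriched cluster C into
#' the all-N- group C').
#'
#' @param sample_ids Samples in the cluster.
#' @param node_status Node labels for those samples.
#' @return list with `kept`, `removed` and `majority`.
#' @export
refine_cluster <- function(sample_ids, node_status) {
  tab <- table(node_status)
  majority <- names(tab)[which.max(tab)]
  keep <- node_status == majority
  list(kept = sample_ids[keep], removed = sample_ids[!keep],
       majority = majority)
}

#' Run the full signature-discovery workflow
#'
#' Executes the study workflow end to end: simulate (or load) counts ->
#' sample QC -> N+/N- differential expression -> SD-cutoff selection and
#' consensus clustering into `k` expression groups -> per-cluster pairwise
#' DE (A-B, A-C, B-C, A-BC) -> refinement of the N--enriched cluster into a
#' node-homogeneous group (C -> C') -> A vs C' DE -> NSC signature with
#' cross-validation -> MSE centroid validation on a held-out split ->
#' over-representation of the signature (when a GMT collection is given) ->
#' clinico-pathological group comparison. Clusters are renamed so that "A"
#' is the cluster with the highest N+ fraction and the last letter the
#' lowest. Every stage writes its table under `out_dir`, and the returned
#' manifest records the seed, parameters and an md5 per output so a run can
#' be reproduced stage by stage.
#'
#' @param config A [run_config()].
#' @return list of class `run_manifest` with stage results and output
#'   hashes.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("'config' must be a run_config", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character()

  ## -- input ---------------------------------------------------------------
  input <- stage_run("input", {
    if (is.null(config$counts_path)) {
      sim <- simulate_counts(config$sim)
      clin <- simulate_clinical_table(
        seed = derive_seed(config$seed, "clinical_covariates"),
        n_nneg = sum(sim$metadata$node_status == "Nneg"),
        n_npos = sum(sim$metadata$node_status == "Npos"),
        sample_ids = sim$metadata$sample_id[order(sim$metadata$node_status)])
      meta <- merge(sim$metadata, clin[, setdiff(names(clin), "node_status")],
                    by = "sample_id", sort = FALSE)
      list(counts = sim$counts, metadata = meta)
    } else {
      list(counts = read_counts_tsv(config$counts_path),
           metadata = read_metadata_tsv(config$metadata_path))
    }
  })
  write_counts_tsv(input$counts, out("counts.tsv"))
  write_metadata_tsv(input$metadata, out("metadata.tsv"))
  files <- c(files, "counts.tsv", "metadata.tsv")

  ## -- sample QC -----------------------------------------------------------
  qc <- stage_run("qc", {
    sample_qc(input$counts, config$qc_min_aligned, config$qc_max_zero_genes)
  })
  write_metadata_tsv(qc$report, out("qc_report.tsv"))
  files <- c(files, "qc_report.tsv")
  counts <- qc$counts
  meta <- input$metadata[match(counts$sample_ids, input$metadata$sample_id), ]

  ## -- N+/N- differential expression --------------------------------------
  dge_node <- stage_run("dge_node_status", {
    v <- voom_weights(counts, meta$node_status)
    call_de(fit_moderated_t(v), fdr = config$fdr, min_fc = config$min_fc)
  })
  write_metadata_tsv(dge_node$table, out("dge_Npos_vs_Nneg.tsv"))
  files <- c(files, "dge_Npos_vs_Nneg.tsv")

  ## -- clustering ----------------------------------------------------------
  clust <- stage_run("clustering", {
    e <- logcpm(counts)
    sel <- select_sd_cutoff(e, min_genes = min(config$cluster_min_genes,
                                               nrow(e) %/% 2L))
    genes <- if (sel$status == "ok") sel$chosen_genes else rownames(e)
    cons <- consensus_cluster(e[genes, , drop = FALSE], k = config$cluster_k,
                              n_iterations = config$cluster_iterations,
                              subsample_fraction = config$cluster_fraction,
                              seed = derive_seed(config$seed, "cluster"))
    ## rename clusters by decreasing N+ fraction: A = most N+-enriched
    frac <- vapply(seq_len(cons$k), function(c) {
      mean(meta$node_status[cons$assignments == c] == "Npos")
    }, numeric(1))
    letter <- LETTERS[rank(-frac, ties.method = "first")]
    assignments <- stats::setNames(letter[cons$assignments], names(cons$assignments))
    list(selection = sel, consensus = cons, assignments = assignments)
  })
  meta$cluster <- clust$assignments[meta$sample_id]
  write_metadata_tsv(data.frame(sample_id = names(clust$assignments),
                                cluster = clust$assignments),
                     out("cluster_assignments.tsv"))
  cons_dt <- data.frame(sample_id = rownames(clust$consensus$consensus),
                        clust$consensus$consensus, check.names = FALSE)
  write_metadata_tsv(cons_dt, out("consensus_matrix.tsv"))
  files <- c(files, "cluster_assignments.tsv", "consensus_matrix.tsv")

  ## -- inter-cluster DE ----------------------------------------------------
  cl_levels <- sort(unique(meta$cluster))
  contrasts <- list()
  if (length(cl_levels) >= 2L) {
    for (i in seq_along(cl_levels)) for (j in seq_along(cl_levels)) {
      if (i < j) contrasts[[paste0(cl_levels[i], "_vs_", cl_levels[j])]] <-
          list(a = cl_levels[i], b = cl_levels[j])
    }
    first <- cl_levels[1]
    contrasts[[paste0(first, "_vs_rest")]] <- list(a = first, b = setdiff(cl_levels, first))
  }
  dge_clusters <- stage_run("dge_clusters", {
    lapply(contrasts, function(ct) {
      keep <- meta$cluster %in% c(ct$a, ct$b)
      grp <- factor(ifelse(meta$cluster[keep] %in% ct$a, "ref", "alt"),
                    levels = c("alt", "ref"))
      sub <- count_matrix(counts$counts[, keep, drop = FALSE])
      call_de(fit_moderated_t(voom_weights(sub, grp)),
              fdr = config$fdr, min_fc = config$min_fc)
    })
  })
  for (nm in names(dge_clusters)) {
    write_metadata_tsv(dge_clusters[[nm]]$table, out(sprintf("dge_%s.tsv", nm)))
    files <- c(files, sprintf("dge_%s.tsv", nm))
  }

  ## -- C -> C' refinement and signature contrast ---------------------------
  sig <- stage_run("signature", {
    cl_a <- cl_levels[1]                       # most N+-enriched
    cl_c <- utils::tail(cl_levels, 1)          # most N--enriched
    in_c <- meta$sample_id[meta$cluster == cl_c]
    ref <- refine_cluster(in_c, meta$node_status[meta$cluster == cl_c])
    keep <- meta$sample_id[meta$cluster == cl_a | meta$sample_id %in% ref$kept]
    sub_meta <- meta[match(keep, meta$sample_id), ]
    sub <- count_matrix(counts$counts[, keep, drop = FALSE])
    grp <- factor(ifelse(sub_meta$cluster == cl_a, "Aprime", "Cprime"),
                  levels = c("Cprime", "Aprime"))
    v <- voom_weights(sub, grp)
    de <- call_de(fit_moderated_t(v), fdr = config$fdr, min_fc = config$min_fc)
    ## signature on the node-status labels of the homogeneous groups
    labels <- factor(sub_meta$node_status, levels = c("Nneg", "Npos"))
    cv <- cross_validate_nsc(v$logcpm, labels, delta_grid = config$delta_grid,
                             n_folds = config$n_folds,
                             seed = derive_seed(config$seed, "cv"))
    list(contrast = paste0(cl_a, "_vs_", cl_c, "prime"),
         removed = ref$removed, de = de, cv = cv, expr = v$logcpm,
         labels = labels, samples = keep)
  })
  write_metadata_tsv(sig$de$table, out("dge_A_vs_Cprime.tsv"))
  write_metadata_tsv(sig$cv$cv_table, out("nsc_cv_table.tsv"))
  writeLines(sig$cv$signature, out("signature_genes.txt"))
  files <- c(files, "dge_A_vs_Cprime.tsv", "nsc_cv_table.tsv", "signature_genes.txt")

  ## -- centroid validation on a held-out split -----------------------------
  validation <- stage_run("validation", {
    labs <- sig$labels
    hold <- with_seed(derive_seed(config$seed, "holdout"), {
      unlist(lapply(levels(labs), function(l) {
        idx <- which(labs == l)
        sample(idx, max(1L, round(config$validation_fraction * length(idx))))
      }))
    })
    signature <- sig$cv$signature
    if (length(signature) == 0L) signature <- rownames(sig$expr)
    centroid_validator(sig$expr[, -hold, drop = FALSE], labs[-hold],
                       sig$expr[, hold, drop = FALSE], labs[hold],
                       signature, n_randomizations = config$n_randomizations,
                       seed = derive_seed(config$seed, "validator"))
  })
  write_metadata_tsv(validation$samples, out("validation_report.tsv"))
  files <- c(files, "validation_report.tsv")

  ## -- enrichment ----------------------------------------------------------
  enrich <- NULL
  if (!is.null(config$gmt_path)) {
    enrich <- stage_run("enrichment", {
      gsc <- read_gmt(config$gmt_path)
      query <- if (length(sig$cv$signature) > 0) sig$cv$signature else
        sig$de$de_genes
      ora(query, universe = counts$gene_ids, collection = gsc)
    })
    write_metadata_tsv(enrich, out("enrichment.tsv"))
    files <- c(files, "enrichment.tsv")
  }

  ## -- clinico-pathological comparison -------------------------------------
  clin <- stage_run("clinical_stats", {
    compare_groups(meta, group_col = "node_status")
  })
  write_metadata_tsv(clin, out("clinical_comparison.tsv"))
  files <- c(files, "clinical_comparison.tsv")

  manifest <- list(
    package = as.character(utils::packageVersion("nodalsig")),
    seed = config$seed,
    parameters = list(fdr = config$fdr, min_fc = config$min_fc,
                      qc_min_aligned = config$qc_min_aligned,
                      qc_max_zero_genes = config$qc_max_zero_genes,
                      cluster_k = config$cluster_k,
                      cluster_iterations = config$cluster_iterations,
                      cluster_fraction = config$cluster_fraction),
    outputs = as.list(tools::md5sum(file.path(config$out_dir, files)) |>
                        stats::setNames(files))
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  structure(list(manifest = manifest, qc = qc, dge_node = dge_node,
                 clustering = clust, dge_clusters = dge_clusters,
                 signature = sig, validation = validation,
                 enrichment = enrich, clinical = clin,
                 metadata = meta, out_dir = config$out_dir),
            class = "run_manifest")
}
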