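#' Fit a nearest-shrunken-centroids classifier
#'
#' Standardized class-centroid offsets
#' `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` are soft-thresholded by
#' `delta` (`d'_ik = sign(d_ik) * max(|d_ik| - delta, 0)`), giving shrunken
#' centroids `xbar_i + m_k * (s_i + s0) * d'_ik`. Here `s_i` is the pooled
#' within-class SD of gene i, `s0` the median of the `s_i` (the fudge
#' factor), and `m_k = sqrt(1/n_k - 1/n)`. Genes whose offsets shrink to zero
#' in every class drop out of the signature, so gene selection is embedded in
#' the fit. Classification minimizes the discriminant
#' `sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log(pi_k)`.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param labels Class labels, one per sample; >= 2 classes with >= 2 samples
#'   each.
#' @param delta Non-negative shrinkage threshold.
#' @param priors Class priors; default the observed class frequencies
#'   (`"uniform"` for equal priors).
#' @return list of class `nsc_model` with elements `overall_centroid`,
#'   `class_centroids`, `shrunken_centroids`, `pooled_sd`, `s0`, `mk`,
#'   `delta`, `dprime`, `priors`, `surviving_genes`, `classes`.
#' @export
fit_shrunken_centroids <- function(expr, labels, delta = 0, priors = NULL) {
  if (delta < 0) stop("'delta' must be non-negative", call. = FALSE)
  labels <- droplevels(as.factor(labels))
  K <- nlevels(labels)
  if (K < 2L) stop("need at least two classes", call. = FALSE)
  nk <- table(labels)
  if (any(nk < 2L)) stop("every class needs at least 2 samples", call. = FALSE)
  n <- ncol(expr)
  if (length(labels) != n) stop("one label per sample required", call. = FALSE)

  xbar <- rowMeans(expr)
  cent <- sapply(levels(labels), function(cl) {
    rowMeans(expr[, labels == cl, drop = FALSE])
  })
  ## pooled within-class variance with n - K df
  ss <- 0
  for (cl in levels(labels)) {
    sub <- expr[, labels == cl, drop = FALSE]
    ss <- ss + rowSums((sub - cent[, cl])^2)
  }
  s_i <- sqrt(ss / (n - K))
  s0 <- stats::median(s_i)
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  names(mk) <- levels(labels)

  denom <- outer(s_i + s0, mk)
  d_ik <- (cent - xbar) / denom
  dprime <- sign(d_ik) * pmax(abs(d_ik) - delta, 0)
  shrunken <- xbar + denom * dprime

  if (is.null(priors)) {
    pi_k <- as.numeric(nk) / n
  } else if (identical(priors, "uniform")) {
    pi_k <- rep(1 / K, K)
  } else {
    if (length(priors) != K || any(priors <= 0)) {
      stop("'priors' must be positive with one entry per class", call. = FALSE)
    }
    pi_k <- priors / sum(priors)
  }
  names(pi_k) <- levels(labels)

  surviving <- rownames(expr)[rowSums(abs(dprime) > 0) > 0]
  structure(list(overall_centroid = xbar, class_centroids = cent,
                 shrunken_centroids = shrunken, pooled_sd = s_i, s0 = s0,
                 mk = mk, delta = delta, dprime = dprime, priors = pi_k,
                 surviving_genes = surviving, classes = levels(labels)),
            class = "nsc_model")
}

#' Predict class membership from an NSC model
#'
#' @param object An `nsc_model`.
#' @param newdata Numeric matrix, genes x samples (same gene order as the
#'   training matrix).
#' @param ... Unused.
#' @return list with `class` (factor of predictions) and `scores`
#'   (samples x classes discriminant matrix; smaller is closer).
#' @export
predict.nsc_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 1)
  if (nrow(newdata) != length(object$overall_centroid)) {
    stop("'newdata' must have the training genes in rows", call. = FALSE)
  }
  s <- (object$pooled_sd + object$s0)^2
  scores <- sapply(object$classes, function(cl) {
    colSums((newdata - object$shrunken_centroids[, cl])^2 / s) -
      2 * log(object$priors[cl])
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
                                             dimnames = list(NULL, object$classes))
  pred <- factor(object$classes[max.col(-scores, ties.method = "first")],
                 levels = object$classes)
  list(class = pred, scores = scores)
}

## Stratified fold assignment; falls back to leave-one-out when the smallest
## class has fewer members than the requested fold count.
make_stratified_folds <- function(labels, n_folds, seed) {
  labels <- droplevels(as.factor(labels))
  n <- length(labels)
  if (min(table(labels)) < n_folds) n_folds <- n  # leave-one-out
  with_seed(derive_seed(seed, "folds"), {
    fold <- integer(n)
    if (n_folds == n) {
      fold <- seq_len(n)
    } else {
      for (cl in levels(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    }
    fold
  })
}

#' Cross-validated NSC signature discovery
#'
#' Runs stratified cross-validation over a grid of shrinkage thresholds,
#' picks the threshold with minimal CV misclassification error (ties broken
#' toward the largest threshold, i.e. the smallest signature), refits on all
#' data at that threshold and reports the surviving genes as the signature,
#' together with cross-validated accuracy, sensitivity and specificity.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param labels Two-or-more-level class labels.
#' @param delta_grid Numeric vector of candidate thresholds (default
#'   `seq(0, 5, by = 0.1)`).
#' @param n_folds Fold count (default 10); leave-one-out is used when the
#'   smallest class has fewer members than `n_folds` — the operative branch
#'   at cohort scale (7 vs 8 samples).
#' @param seed Integer seed for fold construction.
#' @param pos_class Positive class for sensitivity/specificity (default
#'   `"Npos"` when present, else the last class level).
#' @return list of class `nsc_cv`: `cv_table` (delta, signature size, CV
#'   errors), `best_delta`, `signature` (gene ids), `model` (refit on all
#'   data), `cv_predictions`, `accuracy`, `sensitivity`, `specificity`,
#'   `confusion`.
#' @export
cross_validate_nsc <- function(expr, labels, delta_grid = seq(0, 5, by = 0.1),
                               n_folds = 10L, seed = 1L, pos_class = NULL) {
  if (length(delta_grid) == 0L) stop("'delta_grid' is empty", call. = FALSE)
  delta_grid <- sort(unique(delta_grid))
  labels <- droplevels(as.factor(labels))
  n <- length(labels)
  fold <- make_stratified_folds(labels, n_folds, seed)

  pred_mat <- matrix(NA_character_, nrow = n, ncol = length(delta_grid))
  for (f in sort(unique(fold))) {
    test <- fold == f
    ## refuse folds that empty out a training class
    if (any(table(labels[!test]) < 2L)) {
      stop("fold construction left a training class with < 2 samples",
           call. = FALSE)
    }
    base <- fit_shrunken_centroids(expr[, !test, drop = FALSE], labels[!test],
                                   delta = 0)
    for (j in seq_along(delta_grid)) {
      m <- rethreshold_nsc(base, delta_grid[j])
      pred_mat[test, j] <- as.character(
        predict(m, expr[, test, drop = FALSE])$class)
    }
  }
  errors <- colMeans(pred_mat != as.character(labels))
  full0 <- fit_shrunken_centroids(expr, labels, 0)
  sizes <- vapply(delta_grid, function(d) {
    length(rethreshold_nsc(full0, d)$surviving_genes)
  }, integer(1))
  ## ties toward larger delta -> smaller signature
  best_j <- max(which(errors == min(errors)))
  best_delta <- delta_grid[best_j]
  model <- fit_shrunken_centroids(expr, labels, delta = best_delta)

  cvp <- factor(pred_mat[, best_j], levels = levels(labels))
  if (is.null(pos_class)) {
    pos_class <- if ("Npos" %in% levels(labels)) "Npos" else utils::tail(levels(labels), 1)
  }
  perf <- binary_performance(cvp, labels, pos_class)

  structure(list(cv_table = data.frame(delta = delta_grid, n_genes = sizes,
                                       cv_error = errors),
                 best_delta = best_delta, signature = model$surviving_genes,
                 model = model, cv_predictions = cvp, folds = fold,
                 accuracy = perf$accuracy, sensitivity = perf$sensitivity,
                 specificity = perf$specificity, confusion = perf$confusion,
                 pos_class = pos_class),
            class = "nsc_cv")
}

## Re-apply soft-thresholding to a delta = 0 fit without recomputing the
## sufficient statistics (used inside the CV loop).
rethreshold_nsc <- function(model, delta) {
  denom <- outer(model$pooled_sd + model$s0, model$mk)
  dprime <- sign(model$dprime) * pmax(abs(model$dprime) - delta, 0)
  model$shrunken_centroids <- model$overall_centroid + denom * dprime
  model$delta <- delta
  gene_ids <- names(model$overall_centroid)
  model$surviving_genes <- gene_ids[rowSums(abs(dprime) > 0) > 0]
  model$dprime_thresholded <- dprime
  model
}

binary_performance <- function(pred, truth, pos_class) {
  truth <- as.factor(truth)
  lev <- levels(truth)
  confusion <- table(predicted = factor(pred, levels = lev),
                     expected = truth)
  acc <- mean(as.character(pred) == as.character(truth))
  if (length(lev) == 2L && pos_class %in% lev) {
    tp <- sum(pred == pos_class & truth == pos_class)
    fn <- sum(pred != pos_class & truth == pos_class)
    tn <- sum(pred != pos_class & truth != pos_class)
    fp <- sum(pred == pos_class & truth != pos_class)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  } else {
    sens <- spec <- NA_real_
  }
  list(confusion = confusion, accuracy = acc, sensitivity = sens,
       specificity = spec)
}

## All permutations of seq_len(n) as a matrix (n! rows); used for exact
## randomization when the signature is small.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' MSE centroid validator
#'
#' Independent check of a gene signature: group centroids are the mean
#' expression of each signature gene over the training samples of each
#' group; a validation sample's score for a group is the mean squared error
#' between its signature-gene expression and that group's centroid, and the
#' sample is assigned to the group with minimal MSE (ties broken to the
#' first group in sorted label order and flagged). Significance per sample
#' comes from randomization: the sample's expression values are permuted
#' across the signature genes and the best (minimal) MSE recomputed; the
#' p-value is the fraction of null scores at or below the observed best
#' score. When the signature is small enough that all permutations fit
#' within `n_randomizations`, the null is enumerated exhaustively (exact p,
#' identity permutation included); otherwise `n_randomizations` Monte-Carlo
#' draws are used with the add-one estimate `(r + 1) / (B + 1)`.
#'
#' @param train_expr,valid_expr Numeric matrices, genes x samples, sharing
#'   the signature genes in their row names.
#' @param train_labels,valid_labels Group labels.
#' @param signature_genes Character vector of signature gene ids.
#' @param n_randomizations Randomization budget B (default 1000).
#' @param seed Integer seed.
#' @param pos_class Positive class for the confusion summary (default
#'   `"Npos"` when present).
#' @return list of class `validation_report`: `samples` (data.frame with
#'   per-group MSE columns, `predicted`, `tie`, `p_rand`), `confusion`,
#'   `accuracy`, `sensitivity`, `specificity`, `exact` (whether the null was
#'   enumerated exhaustively).
#' @export
centroid_validator <- function(train_expr, train_labels, valid_expr,
                               valid_labels, signature_genes,
                               n_randomizations = 1000L, seed = 1L,
                               pos_class = NULL) {
  if (length(signature_genes) == 0L) stop("empty signature", call. = FALSE)
  miss <- setdiff(signature_genes, intersect(rownames(train_expr), rownames(valid_expr)))
  if (length(miss) > 0L) {
    stop(sprintf("signature genes missing from expression data: %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  if (ncol(valid_expr) < 1L) stop("need at least one validation sample", call. = FALSE)
  train_labels <- droplevels(as.factor(train_labels))
  groups <- sort(levels(train_labels))
  if (!all(as.character(valid_labels) %in% groups)) {
    stop("validation labels contain groups absent from training", call. = FALSE)
  }
  tr <- train_expr[signature_genes, , drop = FALSE]
  va <- valid_expr[signature_genes, , drop = FALSE]
  centroids <- vapply(groups, function(g) {
    rowMeans(tr[, train_labels == g, drop = FALSE])
  }, numeric(length(signature_genes)))
  if (is.null(dim(centroids))) {  # single-gene signature
    centroids <- matrix(centroids, nrow = 1,
                        dimnames = list(signature_genes, groups))
  }

  p_genes <- length(signature_genes)
  exact <- factorial(p_genes) <= n_randomizations
  perms <- if (exact) all_permutations(p_genes) else NULL

  mse <- sapply(groups, function(g) colMeans((va - centroids[, g])^2))
  if (is.null(dim(mse))) mse <- matrix(mse, nrow = 1, dimnames = list(NULL, groups))
  pred_idx <- apply(mse, 1, which.min)
  tie <- apply(mse, 1, function(r) sum(r == min(r)) > 1)
  predicted <- groups[pred_idx]
  best <- mse[cbind(seq_len(nrow(mse)), pred_idx)]

  p_rand <- with_seed(derive_seed(seed, "validator"), {
    vapply(seq_len(ncol(va)), function(j) {
      x <- va[, j]
      if (exact) {
        null_best <- apply(perms, 1, function(pm) {
          min(colMeans((x[pm] - centroids)^2))
        })
        mean(null_best <= best[j] + 1e-12)
      } else {
        null_best <- vapply(seq_len(n_randomizations), function(b) {
          min(colMeans((sample(x) - centroids)^2))
        }, numeric(1))
        (sum(null_best <= best[j] + 1e-12) + 1) / (n_randomizations + 1)
      }
    }, numeric(1))
  })

  if (is.null(pos_class)) {
    pos_class <- if ("Npos" %in% groups) "Npos" else utils::tail(groups, 1)
  }
  perf <- binary_performance(factor(predicted, levels = groups),
                             factor(as.character(valid_labels), levels = groups),
                             pos_class)
  samples <- data.frame(sample_id = colnames(va) %||% paste0("V", seq_len(ncol(va))),
                        stringsAsFactors = FALSE)
  for (g in groups) samples[[paste0("mse_", g)]] <- mse[, g]
  samples$predicted <- predicted
  samples$expected <- as.character(valid_labels)
  samples$tie <- tie
  samples$p_rand <- p_rand

  structure(list(samples = samples, confusion = perf$confusion,
                 accuracy = perf$accuracy, sensitivity = perf$sensitivity,
                 specificity = perf$specificity, exact = exact,
                 n_randomizations = as.integer(n_randomizations),
                 pos_class = pos_class),
            class = "validation_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
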