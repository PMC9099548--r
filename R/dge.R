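#' log2 counts per million
#'
#' The voom expression scale: `log2((count + 0.5) / (library_size + 1) * 1e6)`.
#' The 0.5 / 1 offsets avoid taking logs of zero and keep the transform
#' defined for empty genes.
#'
#' @param counts A [count_matrix()] or numeric matrix (column sums then act
#'   as library sizes).
#' @param lib_sizes Optional per-sample library sizes overriding the stored
#'   column sums.
#' @return Numeric matrix of logCPM values, same shape and dimnames as the
#'   counts.
#' @export
logcpm <- function(counts, lib_sizes = NULL) {
  x <- as_count_matrix(counts)
  ls <- if (is.null(lib_sizes)) x$library_sizes else lib_sizes
  if (any(ls <= 0)) stop("library sizes must be positive", call. = FALSE)
  t(log2(t(x$counts + 0.5) / (ls + 1) * 1e6))
}

## Unweighted group-means fit on a genes x samples matrix; returns fitted
## values, residual SD per gene and residual df. The design is the one the
## pairwise contrasts use throughout: an intercept per group.
group_means_fit <- function(y, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  K <- nlevels(groups)
  n <- ncol(y)
  if (any(table(groups) < 2L)) {
    stop("every group must contain at least 2 samples", call. = FALSE)
  }
  idx <- split(seq_len(n), groups)
  fitted <- y
  for (g in idx) fitted[, g] <- rowMeans(y[, g, drop = FALSE])
  resid <- y - fitted
  df <- n - K
  sigma <- sqrt(rowSums(resid^2) / df)
  list(fitted = fitted, sigma = sigma, df_residual = df, groups = groups,
       amean = rowMeans(y))
}

#' voom: mean-variance precision weights for count data
#'
#' Transforms counts to logCPM, fits a per-gene group-means model, estimates
#' the mean-variance trend by lowess of the square-root residual standard
#' deviation against average log2 count, and assigns each observation the
#' weight `trend(fitted log2 count)^-4`. Trend evaluation is clamped outside
#' the fitted range, and the predicted square-root SD is floored at a small
#' positive value so weights stay finite even for genes with zero residual
#' variance.
#'
#' @param counts A [count_matrix()] or numeric matrix of raw counts.
#' @param groups Sample group labels (>= 2 samples per group).
#' @param span lowess span for the trend (default 0.5).
#' @return list of class `voom_result`: `logcpm` (matrix `E`), `weights`
#'   (same shape, strictly positive), `trend` (list with `x`, `y` of the
#'   lowess curve), `groups`, `lib_sizes`.
#' @export
voom_weights <- function(counts, groups, span = 0.5) {
  x <- as_count_matrix(counts)
  if (length(groups) != ncol(x$counts)) {
    stop("'groups' must have one label per sample", call. = FALSE)
  }
  keep <- rowSums(x$counts) > 0
  cnt <- x$counts[keep, , drop = FALSE]
  if (nrow(cnt) < 2L) stop("need at least two non-empty genes", call. = FALSE)
  lib <- x$library_sizes
  y <- t(log2(t(cnt + 0.5) / (lib + 1) * 1e6))
  fit <- group_means_fit(y, groups)

  sx <- fit$amean + mean(log2(lib + 1)) - log2(1e6)  # average log2 count
  sy <- sqrt(fit$sigma)                               # quarter-root variance
  lo <- stats::lowess(sx, sy, f = span)
  trend_fun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)

  fitted_cpm <- 2^fit$fitted
  fitted_count <- 1e-6 * t(t(fitted_cpm) * (lib + 1))
  fitted_logcount <- log2(fitted_count)
  pred <- pmax(trend_fun(as.vector(fitted_logcount)), 1e-4)
  w <- matrix(pred^-4, nrow = nrow(y), ncol = ncol(y), dimnames = dimnames(y))

  structure(list(logcpm = y, weights = w,
                 trend = list(x = lo$x, y = lo$y, span = span),
                 groups = fit$groups, lib_sizes = lib),
            class = "voom_result")
}

## Invert the trigamma function by Newton iteration (monotone decreasing on
## (0, Inf)); used to match moments of log chi-square variances.
trigamma_inverse <- function(y) {
  if (!is.finite(y)) return(NA_real_)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes squeezing of gene-wise variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` by
#' moment matching on the log residual variances (digamma/trigamma method),
#' then returns the posterior (moderated) variances
#' `(d0 * s0^2 + df * s2) / (d0 + df)`. When the excess spread of the log
#' variances is non-positive (near-constant variances) the trigamma inversion
#' has no solution and the prior df is taken as infinite: all genes share
#' `s0^2`.
#'
#' @param s2 Gene-wise residual variances.
#' @param df Residual degrees of freedom (scalar).
#' @return list with `var_post`, `var_prior` (`s0^2`) and `df_prior` (`d0`,
#'   possibly `Inf`).
#' @export
squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) stop("need at least two positive variances", call. = FALSE)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (sum(ok) - 1L) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s0_2 <- exp(emean)
  }
  var_post <- if (is.infinite(df_prior)) rep(s0_2, length(s2)) else {
    (df_prior * s0_2 + df * s2) / (df_prior + df)
  }
  var_post[!is.finite(s2)] <- s0_2
  list(var_post = var_post, var_prior = s0_2, df_prior = df_prior)
}

#' Moderated t-test between two sample groups
#'
#' Per gene: weighted least-squares estimate of the between-group difference
#' on the voom logCPM scale (the log2 fold change), residual variance, then
#' empirical-Bayes moderation of the variances via [squeeze_var()] and a
#' moderated t statistic on `d0 + df` degrees of freedom.
#'
#' The reported `log2fc` is the mean of the second factor level minus the
#' mean of the first (so with levels `c("Nneg", "Npos")`, positive values are
#' up in N+).
#'
#' @param voom A `voom_result` from [voom_weights()], or a list with
#'   `logcpm` and `weights` matrices.
#' @param groups Two-level sample labels; defaults to the groups stored in
#'   the voom object.
#' @param prior `"eb"` (default) for empirical-Bayes moderation, `"none"` to
#'   disable the prior (`d0 = 0`), in which case the statistic reduces to the
#'   ordinary per-gene weighted t-test.
#' @return data.frame of class `dge_result`, one row per gene: `gene_id`,
#'   `log2fc`, `t`, `df_total`, `p_value`, `p_adj` (Benjamini-Hochberg),
#'   `s2_gene`, `s2_post`; attributes `df_prior` and `s2_prior`.
#' @export
fit_moderated_t <- function(voom, groups = NULL, prior = c("eb", "none")) {
  prior <- match.arg(prior)
  y <- voom$logcpm
  w <- voom$weights
  if (is.null(groups)) groups <- voom$groups
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("exactly two groups are required", call. = FALSE)
  if (ncol(y) < 3L) stop("need at least 3 samples in total", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("every group must contain at least 2 samples", call. = FALSE)
  }
  i1 <- groups == levels(groups)[1]
  i2 <- groups == levels(groups)[2]

  sw1 <- rowSums(w[, i1, drop = FALSE]); sw2 <- rowSums(w[, i2, drop = FALSE])
  m1 <- rowSums(w[, i1, drop = FALSE] * y[, i1, drop = FALSE]) / sw1
  m2 <- rowSums(w[, i2, drop = FALSE] * y[, i2, drop = FALSE]) / sw2
  fitted <- y
  fitted[, i1] <- m1; fitted[, i2] <- m2
  resid <- y - fitted
  df <- ncol(y) - 2L
  s2 <- rowSums(w * resid^2) / df
  se_unscaled <- sqrt(1 / sw1 + 1 / sw2)
  log2fc <- m2 - m1

  if (prior == "eb") {
    sq <- squeeze_var(s2, df)
    s2_post <- sq$var_post
    df_prior <- sq$df_prior
    s2_prior <- sq$var_prior
  } else {
    s2_post <- s2
    df_prior <- 0
    s2_prior <- NA_real_
  }
  df_total <- df_prior + df
  tstat <- log2fc / (sqrt(s2_post) * se_unscaled)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)

  out <- data.frame(gene_id = rownames(y), log2fc = log2fc, t = tstat,
                    df_total = df_total, p_value = p,
                    p_adj = bh_adjust(p), s2_gene = s2, s2_post = s2_post,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "df_prior") <- df_prior
  attr(out, "s2_prior") <- s2_prior
  attr(out, "contrast") <- paste(levels(groups)[2], "vs", levels(groups)[1])
  class(out) <- c("dge_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; input values must lie in \[0, 1\].
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is called DE when its BH-adjusted p-value is below `fdr` AND its
#' absolute fold change is at least `min_fc` (i.e. `|log2fc| >= log2(min_fc)`).
#'
#' @param dge A `dge_result` from [fit_moderated_t()].
#' @param fdr FDR threshold (default 0.05).
#' @param min_fc Minimum fold change (default 2).
#' @return list with `table` (the input annotated with an `is_de` column),
#'   `de_genes`, `up` (log2fc > 0) and `down` gene-id vectors.
#' @export
call_de <- function(dge, fdr = 0.05, min_fc = 2) {
  stopifnot(is.data.frame(dge), all(c("gene_id", "log2fc", "p_adj") %in% names(dge)))
  is_de <- dge$p_adj < fdr & abs(dge$log2fc) >= log2(min_fc)
  tab <- dge
  tab$is_de <- is_de
  list(table = tab,
       de_genes = dge$gene_id[is_de],
       up = dge$gene_id[is_de & dge$log2fc > 0],
       down = dge$gene_id[is_de & dge$log2fc < 0])
}
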