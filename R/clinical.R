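#' Exact Fisher test for r x c contingency tables
#'
#' Full Freeman-Halton enumeration: all tables with the observed margins are
#' generated, their hypergeometric probabilities computed via log-factorials,
#' and the two-sided p-value is the total probability of tables no more
#' probable than the observed one (probability-mass criterion, with a
#' relative tolerance of 1e-7 to absorb floating-point ties — the de-facto
#' standard definition). Rows and columns that are entirely zero are dropped
#' first; this provably leaves the p-value unchanged.
#'
#' @param tab Non-negative integer matrix with at least 2 non-zero rows and
#'   2 non-zero columns; grand total at most 200 (the enumeration is exact,
#'   not approximated).
#' @return Two-sided p-value in \[0, 1\].
#' @examples
#' fisher_exact_rxc(matrix(c(3, 9, 10, 6), nrow = 2))  # ~0.067
#' @export
fisher_exact_rxc <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)) || any(!is.finite(tab))) {
    stop("table entries must be non-negative integers", call. = FALSE)
  }
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("need at least 2 non-zero rows and 2 non-zero columns", call. = FALSE)
  }
  n <- sum(tab)
  if (n > 200) {
    stop("grand total exceeds the exact-enumeration limit (200)", call. = FALSE)
  }
  rs <- rowSums(tab); cs <- colSums(tab)
  const <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n)
  lp_obs <- const - sum(lfactorial(tab))

  ## enumerate all tables with the given margins, accumulating probability
  ## of tables with log-probability <= lp_obs (+ tolerance). Rows are filled
  ## one cell at a time; the last row is forced by the column remainders.
  tol <- log1p(1e-7)
  r <- length(rs); cdim <- length(cs)
  total <- 0
  recurse_row <- function(i, col_rem, lf_acc) {
    if (i == r) {
      lp <- const - (lf_acc + sum(lfactorial(col_rem)))
      if (lp <= lp_obs + tol) total <<- total + exp(lp)
      return(invisible())
    }
    fill_cell <- function(j, remaining, row_lf, col_rem_cur) {
      if (j == cdim) {
        if (remaining <= col_rem_cur[cdim]) {
          col_rem_cur[cdim] <- col_rem_cur[cdim] - remaining
          recurse_row(i + 1L, col_rem_cur,
                      lf_acc + row_lf + lfactorial(remaining))
        }
        return(invisible())
      }
      for (v in 0:min(remaining, col_rem_cur[j])) {
        col_rem2 <- col_rem_cur
        col_rem2[j] <- col_rem2[j] - v
        fill_cell(j + 1L, remaining - v, row_lf + lfactorial(v), col_rem2)
      }
    }
    fill_cell(1L, rs[i], 0, col_rem)
  }
  recurse_row(1L, cs, 0)
  min(total, 1)
}

#' Welch two-sample t-test from summary statistics
#'
#' `t = (mean2 - mean1) / sqrt(sd1^2/n1 + sd2^2/n2)` with Satterthwaite
#' degrees of freedom and a two-sided p-value. When both SDs are zero and
#' the means are equal, t is 0 by convention (p = 1).
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @return list with `t`, `df`, `p`.
#' @examples
#' welch_t_from_summary(46.8, 22.5, 12, 50.1, 25.9, 16)$p  # ~0.72
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  mean1 <- as.numeric(mean1); sd1 <- as.numeric(sd1); n1 <- as.numeric(n1)
  mean2 <- as.numeric(mean2); sd2 <- as.numeric(sd2); n2 <- as.numeric(n2)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative", call. = FALSE)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    t <- if (mean1 == mean2) 0 else sign(mean2 - mean1) * Inf
    return(list(t = t, df = n1 + n2 - 2, p = if (t == 0) 1 else 0))
  }
  t <- (mean2 - mean1) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

## Journal-style p display: two decimals below ~0.1 (three below 0.02 so
## values like 0.013 keep their precision), one decimal otherwise.
format_p <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 0.001) return("<0.001")
    if (x < 0.02) return(sprintf("%.3f", x))
    if (x < 0.145) return(sprintf("%.2f", x))
    sprintf("%.1f", x)
  }, character(1))
}

#' Compare clinico-pathological covariates between two groups
#'
#' Builds the group-comparison table: every categorical covariate is tested
#' with the exact r x c Fisher test (all-zero levels dropped) and every
#' continuous covariate with the Welch two-sample t-test. Covariates with a
#' single observed level are reported without a p-value.
#'
#' @param metadata data.frame with one row per sample.
#' @param group_col Name of the two-level grouping column (default
#'   `"node_status"`).
#' @param covariates Columns to compare; defaults to every column except the
#'   group column and `sample_id`-like identifiers.
#' @return data.frame: `covariate`, `type` (`"categorical"`/`"continuous"`),
#'   `test`, `p`, `p_printed`, and a human-readable `summary` (counts and
#'   percentages per arm, or mean (SD) per arm).
#' @export
compare_groups <- function(metadata, group_col = "node_status",
                           covariates = NULL) {
  if (!group_col %in% names(metadata)) {
    stop(sprintf("column '%s' not found", group_col), call. = FALSE)
  }
  g <- as.factor(metadata[[group_col]])
  g <- droplevels(g)
  if (nlevels(g) != 2L) stop("exactly two groups are required", call. = FALSE)
  if (is.null(covariates)) {
    covariates <- setdiff(names(metadata),
                          c(group_col, "sample_id", "true_cluster", "cluster"))
  }
  rows <- lapply(covariates, function(cv) {
    x <- metadata[[cv]]
    if (is.numeric(x)) {
      s <- vapply(levels(g), function(a) {
        c(mean(x[g == a]), stats::sd(x[g == a]), sum(g == a))
      }, numeric(3))
      res <- welch_t_from_summary(s[1, 1], s[2, 1], s[3, 1],
                                  s[1, 2], s[2, 2], s[3, 2])
      data.frame(covariate = cv, type = "continuous", test = "welch_t",
                 p = res$p,
                 summary = paste(sprintf("%s: %.1f (%.1f)", levels(g),
                                         s[1, ], s[2, ]), collapse = "; "),
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(x), g)
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      pct <- sweep(tab, 2, colSums(tab), "/") * 100
      summ <- paste(vapply(rownames(tab), function(lv) {
        paste0(lv, " ", paste(sprintf("%s=%d(%.0f%%)", colnames(tab),
                                      tab[lv, ], pct[lv, ]), collapse = " "))
      }, character(1)), collapse = "; ")
      p <- if (nrow(tab) < 2L) NA_real_ else fisher_exact_rxc(unclass(tab))
      data.frame(covariate = cv, type = "categorical", test = "fisher_exact",
                 p = p, summary = summ, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_printed <- format_p(out$p)
  out[, c("covariate", "type", "test", "p", "p_printed", "summary")]
}

#' Cohort contingency tables for the 28-sample EEC node-status comparison
#'
#' The clinico-pathological counts of the 12 N- / 16 N+ endometrioid
#' endometrial carcinoma cohort the workflow targets, as ready-to-test
#' contingency tables (rows = covariate levels, columns = `Nneg`, `Npos`)
#' plus the per-arm tumor-size summaries. These counts double as the
#' sampling frequencies of [simulate_clinical_table()].
#'
#' @return list with one matrix per categorical covariate and a
#'   `tumor_size` element (list of per-arm `mean`, `sd`, `n`).
#' @export
eec_node_tables <- function() {
  fr <- .clinical_freqs()
  tabs <- lapply(fr$categorical, function(spec) {
    m <- cbind(Nneg = spec$Nneg, Npos = spec$Npos)
    rownames(m) <- spec$levels
    m
  })
  tabs$tumor_size <- list(
    Nneg = c(mean = 46.8, sd = 22.5, n = 12),
    Npos = c(mean = 50.1, sd = 25.9, n = 16)
  )
  tabs
}
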