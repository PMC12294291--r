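#' One-way ANOVA decomposition
#'
#' Classic fixed-effects one-way decomposition of `values` by `groups`:
#' between/within sums of squares, F statistic and p-value. When every group
#' has zero internal variance the F statistic is undefined (0/0 or infinite
#' separation); the result is flagged `degenerate` instead of erroring, so
#' that simulation loops and rounded published data (SD printed as 0)
#' survive.
#'
#' @param values Numeric response vector.
#' @param groups Factor-like group labels, same length.
#' @return List with `F`, `p`, `df1`, `df2`, `ms_within`, `means`, `n`,
#'   `grand_mean`, `degenerate`, `residuals`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(values) != length(groups)) stop("length mismatch", call. = FALSE)
  means <- tapply(values, groups, mean)
  n <- tapply(values, groups, length)
  if (any(n < 2L)) {
    stop("group '", names(n)[which(n < 2L)[1L]],
         "' has fewer than 2 replicates", call. = FALSE)
  }
  grand <- mean(values)
  ss_between <- sum(n * (means - grand)^2)
  resid <- values - means[groups]
  ss_within <- sum(resid^2)
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  degenerate <- ss_within == 0
  Fstat <- if (degenerate) {
    if (ss_between == 0) 0 else Inf
  } else {
    (ss_between / df1) / (ss_within / df2)
  }
  p <- if (degenerate) {
    if (ss_between == 0) 1 else 0
  } else {
    stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  list(F = Fstat, p = p, df1 = df1, df2 = df2,
       ms_within = ss_within / df2, means = means, n = n,
       grand_mean = grand, degenerate = degenerate,
       residuals = as.numeric(resid))
}

#' Variance-homogeneity and normality checks for a one-way design
#'
#' Levene's test in its original form (one-way ANOVA on the absolute
#' deviations from the group means) for homogeneity of variances, and the
#' Shapiro-Wilk test (Royston's AS R94 approximation, as implemented in
#' `stats::shapiro.test`) on the pooled within-group residuals for
#' normality. Both are advisory gates for the subsequent ANOVA at level
#' `alpha`. Groups that are all internally constant make Levene's statistic
#' 0/0; this is reported as statistic 0 with a degenerate flag.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length; every group needs >= 2
#'   replicates, and Shapiro-Wilk needs total n >= 3.
#' @param alpha Significance level (default 0.05).
#' @return List with `levene` (statistic, p, degenerate), `shapiro`
#'   (statistic, p), `alpha`, and logical verdicts `variances_homogeneous`,
#'   `residuals_normal`.
#' @export
check_assumptions <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  ao <- anova_oneway(values, groups)  # validates design, gives residuals
  absdev <- abs(values - ao$means[groups])
  lev <- anova_oneway(absdev, groups)
  levene <- if (lev$degenerate) {
    list(statistic = 0, p = NA_real_, degenerate = TRUE)
  } else {
    list(statistic = lev$F, p = lev$p, degenerate = FALSE)
  }
  if (length(values) < 3L) stop("Shapiro-Wilk needs n >= 3", call. = FALSE)
  sh <- if (stats::var(ao$residuals) == 0) {
    list(statistic = NA_real_, p.value = NA_real_)
  } else {
    stats::shapiro.test(ao$residuals)
  }
  list(levene = levene,
       shapiro = list(statistic = unname(sh$statistic), p = sh$p.value),
       alpha = alpha,
       variances_homogeneous = !isTRUE(levene$p < alpha),
       residuals_normal = !isTRUE(sh$p.value < alpha))
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise group comparisons using the studentized range distribution
#' (Tukey-Kramer standard errors for unbalanced groups). Quantiles and tail
#' probabilities come from numerical evaluation of the studentized range
#' distribution (`stats::ptukey`/`qtukey`).
#'
#' @param ao Result of [anova_oneway()].
#' @param alpha Family-wise significance level (default 0.05).
#' @return Data frame with one row per pair: `group1`, `group2`, `diff`
#'   (mean of group2 minus group1), `q` statistic, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(ao, alpha = 0.05) {
  g <- names(ao$means)
  k <- length(g)
  pairs <- utils::combn(k, 2)
  out <- data.frame(group1 = g[pairs[1L, ]], group2 = g[pairs[2L, ]])
  d <- q <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    d[j] <- ao$means[i2] - ao$means[i1]
    se <- sqrt(ao$ms_within / 2 * (1 / ao$n[i1] + 1 / ao$n[i2]))
    if (ao$degenerate || se == 0) {
      q[j] <- if (d[j] == 0) 0 else Inf
      p[j] <- if (d[j] == 0) 1 else 0
    } else {
      q[j] <- abs(d[j]) / se
      p[j] <- stats::ptukey(q[j], nmeans = k, df = ao$df2,
                            lower.tail = FALSE)
    }
  }
  out$diff <- d; out$q <- q; out$p_adj <- p
  out$significant <- out$p_adj < alpha
  out
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb algorithm: start from a single letter covering all
#' groups; for each significantly different pair split every letter that
#' still contains both; absorb letters that became subsets of others.
#' Letters are assigned in ascending order of group mean, so `"a"` marks the
#' lowest-mean homogeneous set — the convention of the published ratio
#' tables this reproduces. Groups share a letter if and only if they are not
#' significantly different.
#'
#' @param comparisons Data frame from [tukey_hsd()] (needs `group1`,
#'   `group2`, `significant`).
#' @param means Named numeric vector of group means (orders the letters;
#'   ties broken by label order).
#' @return Named character vector of letter strings, one per group.
#' @export
compact_letter_display <- function(comparisons, means) {
  g <- names(means)
  cols <- list(g)  # each element: character vector of member groups
  sig <- comparisons[comparisons$significant, , drop = FALSE]
  for (j in seq_len(nrow(sig))) {
    a <- as.character(sig$group1[j]); b <- as.character(sig$group2[j])
    newcols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        newcols <- c(newcols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        newcols <- c(newcols, list(col))
      }
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(newcols))
    for (i in seq_along(newcols)) {
      for (l in seq_along(newcols)) {
        if (i != l && keep[i] &&
            all(newcols[[i]] %in% newcols[[l]]) &&
            (length(newcols[[i]]) < length(newcols[[l]]) ||
             (length(newcols[[i]]) == length(newcols[[l]]) && l < i))) {
          keep[i] <- FALSE
        }
      }
    }
    cols <- newcols[keep]
  }
  # order letter columns by the smallest mean they contain (ties: label order)
  colmin <- vapply(cols, function(col) min(means[col]), numeric(1))
  cols <- cols[order(colmin)]
  letters_out <- stats::setNames(rep("", length(g)), g)
  for (i in seq_along(cols)) {
    for (m in cols[[i]]) {
      letters_out[m] <- paste0(letters_out[m], letters[i])
    }
  }
  letters_out
}

#' One-way ANOVA with Tukey HSD letter grouping
#'
#' Assumption checks (Levene, Shapiro-Wilk — advisory, never blocking),
#' one-way ANOVA, Tukey HSD pairwise comparisons and a compact letter
#' display. When all groups are internally constant the design is an exact
#' separation: the result is flagged and letters are assigned directly from
#' the pairwise equality of group means.
#'
#' @param values Numeric response vector (e.g. 440/510 nm band ratios).
#' @param groups Group labels (e.g. molar ratio), same length.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `group_stats_result`: list with `assumptions`,
#'   `anova` (F, p, dfs), `tukey` (pairwise table), `letters`, `means`,
#'   `sd`, `n`, `flags`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  ao <- anova_oneway(values, groups)
  assumptions <- check_assumptions(values, groups, alpha)
  tk <- tukey_hsd(ao, alpha)
  flags <- character()
  if (ao$degenerate) flags <- c(flags, "zero within-group variance: exact separation")
  letters_out <- compact_letter_display(tk, ao$means)
  structure(list(
    assumptions = assumptions,
    anova = list(F = ao$F, p = ao$p, df1 = ao$df1, df2 = ao$df2,
                 degenerate = ao$degenerate),
    tukey = tk, letters = letters_out, means = ao$means,
    sd = tapply(values, groups, stats::sd), n = ao$n,
    alpha = alpha, flags = flags),
    class = "group_stats_result")
}

#' @export
print.group_stats_result <- function(x, ...) {
  cat(sprintf("<group_stats_result> F(%d, %d) = %.4g, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  for (g in names(x$means)) {
    cat(sprintf("  %-8s %.4g +/- %.3g  %s\n", g, x$means[g], x$sd[g],
                x$letters[g]))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
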