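# Group-difference and correlation statistics: one-way ANOVA (from raw values
# or from printed mean/SEM summaries), Tukey HSD pairwise comparisons, and
# Pearson correlation matrices with significance flags.

anova_result <- function(F, df_between, df_within, p, infinite = FALSE) {
  structure(list(F = F, df_between = df_between, df_within = df_within,
                 p = p, infinite = infinite),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %s, p = %.4g\n",
              x$df_between, x$df_within,
              if (x$infinite) "Inf" else formatC(x$F, digits = 4), x$p))
  invisible(x)
}

check_groups <- function(values_by_group) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2)
  small <- names(values_by_group)[lengths(values_by_group) < 2]
  if (length(small))
    stop("every group needs >= 2 values; too few in: ",
         paste(small, collapse = ", "))
  invisible(values_by_group)
}

#' One-way fixed-effects ANOVA
#'
#' @param values_by_group named list mapping group label to a numeric vector
#'   (>= 2 values per group, >= 2 groups).
#' @return An `anova_result` with `F`, `df_between` = groups - 1,
#'   `df_within` = animals - groups, and `p` from the F distribution.
#' @export
oneway_anova <- function(values_by_group) {
  check_groups(values_by_group)
  values <- unlist(values_by_group, use.names = FALSE)
  group <- factor(rep(names(values_by_group), lengths(values_by_group)),
                  levels = names(values_by_group))
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  Fval <- tab[1, "F value"]
  df_b <- tab[1, "Df"]; df_w <- tab[2, "Df"]
  # guard degenerate inputs where both sums of squares are rounding noise
  tol <- .Machine$double.eps^0.75 * (sum(values^2) + 1)
  ss_b <- tab[1, "Sum Sq"]; ss_w <- tab[2, "Sum Sq"]
  if (ss_b + ss_w <= tol) return(anova_result(0, df_b, df_w, 1))
  if (ss_w <= tol && ss_b > tol)
    return(anova_result(Inf, df_b, df_w, 0, infinite = TRUE))
  anova_result(Fval, df_b, df_w, stats::pf(Fval, df_b, df_w, lower.tail = FALSE))
}

#' One-way ANOVA reconstructed from printed summaries
#'
#' Recovers the F statistic a raw-data ANOVA would give, from per-group mean,
#' SEM and n alone: the between-group sum of squares comes from the n-weighted
#' group means around the grand mean; the within-group mean square pools the
#' per-group variances `sem^2 * n` weighted by their degrees of freedom.
#' With equal n this is algebraically identical to [oneway_anova()] on the
#' underlying raw values.
#'
#' @param means,sems,n numeric vectors, one entry per group (n >= 2,
#'   sems >= 0).
#' @return An `anova_result`. When all SEMs are zero but means differ, `F` is
#'   reported as `Inf` with the `infinite` flag set.
#' @export
anova_from_summary <- function(means, sems, n) {
  stopifnot(length(means) >= 2, length(means) == length(sems),
            length(means) == length(n), all(n >= 2), all(sems >= 0))
  df_b <- length(means) - 1L
  df_w <- as.integer(sum(n) - length(means))
  grand <- sum(n * means) / sum(n)
  ss_b <- sum(n * (means - grand)^2)
  ms_b <- ss_b / df_b
  # per-group variance = (sem * sqrt(n))^2 = sem^2 * n
  ms_w <- sum((n - 1) * sems^2 * n) / sum(n - 1)
  if (ms_w == 0) {
    if (ss_b == 0) return(anova_result(0, df_b, df_w, 1))
    return(anova_result(Inf, df_b, df_w, 0, infinite = TRUE))
  }
  Fval <- ms_b / ms_w
  anova_result(Fval, df_b, df_w, stats::pf(Fval, df_b, df_w, lower.tail = FALSE))
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' Studentized-range adjusted p values for every unordered pair of groups,
#' computed with [stats::TukeyHSD()].
#'
#' @inheritParams oneway_anova
#' @return data.frame with columns `group_a`, `group_b`, `mean_diff`,
#'   `p_adj`, covering all `choose(k, 2)` pairs.
#' @export
tukey_hsd <- function(values_by_group) {
  check_groups(values_by_group)
  values <- unlist(values_by_group, use.names = FALSE)
  group <- factor(rep(names(values_by_group), lengths(values_by_group)),
                  levels = names(values_by_group))
  tk <- stats::TukeyHSD(stats::aov(values ~ group))$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    group_a = vapply(pairs, `[`, "", 2),   # TukeyHSD labels "b-a"
    group_b = vapply(pairs, `[`, "", 1),
    mean_diff = -tk[, "diff"],
    p_adj = tk[, "p adj"],
    stringsAsFactors = FALSE)
  out$p_adj[is.nan(out$p_adj)] <- 1   # zero residual variance, zero diff
  rownames(out) <- NULL
  out
}

#' Pearson correlation matrix with significance flags
#'
#' Pairwise Pearson correlations over the requested cohort columns with
#' pairwise (not global) listwise deletion. Zero-variance columns yield `NA`
#' correlations, never 0. Star flags mark p below `alpha`.
#'
#' @param cohort cohort data.frame.
#' @param columns columns to correlate (region abbreviations and/or behavior
#'   columns); default: all region columns.
#' @param alpha significance level for the star flags (default 0.001, the
#'   convention used in correlation heatmaps of this kind).
#' @return A list of class `correlation_report` with symmetric matrices `r`,
#'   `p`, logical `star`, plus `n` (pairwise complete observations).
#' @export
pearson_matrix <- function(cohort, columns = NULL, alpha = 0.001) {
  if (is.null(columns)) columns <- cohort_regions(cohort)
  missing <- setdiff(columns, names(cohort))
  if (length(missing))
    stop("column(s) not in cohort: ", paste(missing, collapse = ", "))
  k <- length(columns)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    nmat[i, i] <- sum(stats::complete.cases(cohort[[columns[i]]]))
    for (j in seq_len(i - 1)) {
      ok <- stats::complete.cases(cohort[[columns[i]]], cohort[[columns[j]]])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3) next
      x <- cohort[[columns[i]]][ok]; y <- cohort[[columns[j]]][ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # undefined, stays NA
      ct <- stats::cor.test(x, y, method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(variables = columns, r = r, p = p, star = !is.na(p) & p < alpha,
                 n = nmat, alpha = alpha),
            class = "correlation_report")
}

#' Serialize a correlation report to long-format CSV
#'
#' One row per unordered pair: `var_a`, `var_b`, `r`, `p`, `star`.
#'
#' @param report a `correlation_report` from [pearson_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_report <- function(report, path) {
  stopifnot(inherits(report, "correlation_report"))
  idx <- which(upper.tri(report$r), arr.ind = TRUE)
  df <- data.frame(var_a = report$variables[idx[, 1]],
                   var_b = report$variables[idx[, 2]],
                   r = report$r[idx], p = report$p[idx],
                   star = report$star[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-region group comparison table
#'
#' Runs [oneway_anova()] and [tukey_hsd()] on every region column of a
#' cohort, optionally adding Benjamini-Hochberg adjusted ANOVA p values
#' across regions (off by default; the conventional analysis reports
#' unadjusted per-region tests).
#'
#' @param cohort cohort data.frame with a `group` column.
#' @param adjust_bh add a `p_bh` column of BH-adjusted ANOVA p values.
#' @return list with `anova` (region, F, df_between, df_within, p\[, p_bh\])
#'   and `tukey` (region + pairwise comparison columns) data.frames.
#' @export
region_group_stats <- function(cohort, adjust_bh = FALSE) {
  regs <- cohort_regions(cohort)
  split_vals <- function(r) split(cohort[[r]], cohort$group)
  an <- lapply(regs, function(r) oneway_anova(split_vals(r)))
  anova_df <- data.frame(
    region = regs,
    F = vapply(an, function(a) a$F, 0),
    df_between = as.integer(vapply(an, function(a) a$df_between, 0)),
    df_within = as.integer(vapply(an, function(a) a$df_within, 0)),
    p = vapply(an, function(a) a$p, 0),
    stringsAsFactors = FALSE)
  if (adjust_bh) anova_df$p_bh <- stats::p.adjust(anova_df$p, method = "BH")
  tk <- do.call(rbind, lapply(regs, function(r)
    cbind(region = r, tukey_hsd(split_vals(r)))))
  list(anova = anova_df, tukey = tk)
}
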