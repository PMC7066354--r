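#' Standardize the measure columns of a score table
#'
#' Transforms every measure column to z-scores, either pooled over all rows
#' (default: groups stay comparable on one scale) or within each group.
#' Z-scoring is idempotent and leaves partial-correlation structure intact.
#'
#' @param table Score table (see [generate_group()] / [read_score_csv()]).
#' @param scheme `"pooled"` or `"per_group"`.
#' @return The table with measure columns standardized.
#' @export
zscore_table <- function(table, scheme = c("pooled", "per_group")) {
  scheme <- match.arg(scheme)
  cols <- measure_columns(table)
  zs <- function(x, where) {
    s <- sd(x)
    if (!is.finite(s) || s == 0)
      stop("DegenerateColumn: zero SD in ", where)
    (x - mean(x)) / s
  }
  for (cl in cols) {
    if (scheme == "pooled") {
      table[[cl]] <- zs(table[[cl]], cl)
    } else {
      for (g in unique(table$group)) {
        idx <- table$group == g
        table[[cl]][idx] <- zs(table[[cl]][idx], paste0(cl, " (group ", g, ")"))
      }
    }
  }
  table
}

#' Two-group one-way ANOVA
#'
#' Fixed-effects one-way ANOVA for exactly two groups; `F` equals the
#' squared pooled-variance t statistic, with df (1, n1 + n2 - 2).
#'
#' @param values_a,values_b Numeric score vectors for the two groups.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("InsufficientData: each group needs n >= 2")
  if (!all(is.finite(values_a)) || !all(is.finite(values_b)))
    stop("InsufficientData: non-finite values")
  anova_from_summary(mean(values_a), sd(values_a), length(values_a),
                     mean(values_b), sd(values_b), length(values_b))
}

#' Two-group ANOVA from summary statistics
#'
#' Closed form of the two-group one-way ANOVA:
#' `F = (m1 - m2)^2 / (s_p^2 (1/n1 + 1/n2))` with pooled variance
#' `s_p^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`.  Agrees with
#' [anova_oneway()] on any raw data sharing these summaries, and lets
#' published group means/SDs be turned back into F statistics.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @return List with `F`, `df1` (1), `df2` (n1 + n2 - 2), `p`.
#' @export
anova_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("InsufficientData: need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) stop("InsufficientData: negative SD")
  df2 <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df2
  if (sp2 == 0) {
    if (m1 != m2) {
      warning("DegenerateVariance: zero pooled variance with unequal means; ",
              "F = Inf")
      return(list(F = Inf, df1 = 1L, df2 = df2, p = 0))
    }
    return(list(F = 0, df1 = 1L, df2 = df2, p = 1))
  }
  F <- (m1 - m2)^2 / (sp2 * (1 / n1 + 1 / n2))
  list(F = F, df1 = 1L, df2 = df2, p = pf(F, 1, df2, lower.tail = FALSE))
}

#' Bonferroni adjustment with an explicit family size
#'
#' Adjusted p = min(1, p * m); a result is flagged significant when its
#' adjusted p falls below `alpha`.  `m` may exceed the number of p-values
#' supplied (a declared family size).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param m Family size (>= 1); defaults to `length(p_values)`.
#' @param alpha Significance level (default 0.05).
#' @return List with `p_adjusted` and logical `significant`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values), alpha = 0.05) {
  if (m < 1) stop("InvalidFamilySize: m must be >= 1")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p_adj <- pmin(1, p_values * m)
  list(p_adjusted = p_adj, significant = p_adj < alpha)
}

#' Between-group ANOVA over all measures
#'
#' Runs the two-group one-way ANOVA for every measure column and applies the
#' Bonferroni correction across measures (family size = number of measures
#' unless overridden).  F is scale-invariant, so raw and z-scored tables
#' give identical statistics.
#'
#' @param table Two-group score table.
#' @param m Bonferroni family size (default: number of measures).
#' @param alpha Significance level.
#' @return Data frame: `measure, mean_a, sd_a, mean_b, sd_b, F, df1, df2, p,
#'   p_adjusted, significant`, where group a/b are the sorted group labels.
#' @export
group_anova_table <- function(table, m = NULL, alpha = 0.05) {
  groups <- sort(unique(table$group))
  if (length(groups) != 2)
    stop("group_anova_table: exactly two groups required, got ",
         length(groups))
  cols <- measure_columns(table)
  if (is.null(m)) m <- length(cols)
  rows <- lapply(cols, function(cl) {
    a <- table[[cl]][table$group == groups[1]]
    b <- table[[cl]][table$group == groups[2]]
    fit <- anova_oneway(a, b)
    data.frame(measure = cl, mean_a = mean(a), sd_a = sd(a),
               mean_b = mean(b), sd_b = sd(b),
               F = fit$F, df1 = fit$df1, df2 = fit$df2, p = fit$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- bonferroni_adjust(out$p, m = m, alpha = alpha)
  out$p_adjusted <- adj$p_adjusted
  out$significant <- adj$significant
  attr(out, "groups") <- groups
  out
}
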