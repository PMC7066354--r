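#' Case-resampling bootstrap of node centralities
#'
#' Resamples participants with replacement B times; each replicate re-runs
#' the full estimation (z-score, covariance, partial correlations,
#' significance pruning) and recomputes the three centrality indices.  One
#' master seed spawns an independent substream per replicate, so results do
#' not depend on execution order.  Replicates with a singular covariance are
#' redrawn (counted) so B stays exact; more than `max_redraw_frac * B`
#' redraws aborts.
#'
#' @param table Single-group score table (or numeric score matrix).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer master seed.
#' @param alpha,adjust Edge-pruning settings, see [estimate_network()].
#' @param disconnected Closeness convention, see [node_closeness()].
#' @param max_redraw_frac Abort threshold for degenerate replicates.
#' @return Object of class `bootstrap_distribution`: list with `values`
#'   (B x p x 3 array, indices strength/betweenness/closeness), `B`,
#'   `seed`, `group`, `nodes`, `redraws`.
#' @export
bootstrap_centrality <- function(table, B = 1000, seed = 1, alpha = 0.05,
                                 adjust = "none", disconnected = "zero",
                                 max_redraw_frac = 0.1) {
  X <- if (is.data.frame(table)) .score_matrix(table) else as.matrix(table)
  group <- if (is.data.frame(table) && "group" %in% names(table))
    as.character(table$group[1]) else NA_character_
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 2) stop("InsufficientData: need at least p + 2 participants")
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2147483646L, B)
  vals <- array(NA_real_, dim = c(B, p, 3),
                dimnames = list(NULL, colnames(X),
                                c("strength", "betweenness", "closeness")))
  redraws <- 0L
  max_redraws <- ceiling(max_redraw_frac * B)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- .fit_centrality(X[idx, , drop = FALSE], alpha = alpha,
                             adjust = adjust, disconnected = disconnected)
      if (!is.null(fit)) break
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("TooManyDegenerateReplicates: more than ",
             round(100 * max_redraw_frac), "% of bootstrap draws were singular")
    }
    vals[b, , ] <- fit[, c("strength", "betweenness", "closeness")]
  }
  structure(list(values = vals, B = B, seed = as.integer(seed),
                 group = group, nodes = colnames(X), redraws = redraws),
            class = "bootstrap_distribution")
}

#' Summarize a bootstrap distribution
#'
#' Per node and centrality index, the sample mean and sample SD
#' (denominator B - 1) over replicates.
#'
#' @param dist A [bootstrap_centrality()] result.
#' @return Object of class `centrality_summary`: list with p x 3 matrices
#'   `mean` and `sd`, plus `nodes`, `indices`, `B`, `group`.
#' @export
summarize_bootstrap <- function(dist) {
  stopifnot(inherits(dist, "bootstrap_distribution"))
  if (dist$B < 2) stop("InsufficientReplicates: need B >= 2")
  mu <- apply(dist$values, c(2, 3), mean)
  sdev <- apply(dist$values, c(2, 3), sd)
  centrality_summary(mu, sdev, group = dist$group, B = dist$B)
}

#' Construct a centrality summary from mean/SD matrices
#'
#' Useful both for bootstrap output and for re-analysing published
#' mean/SD summary tables.
#'
#' @param mean,sd p x 3 numeric matrices (rows = nodes, columns = strength,
#'   betweenness, closeness in any consistent order).
#' @param group Optional group label.
#' @param B Replicate count behind the summaries, if known.
#' @return Object of class `centrality_summary`.
#' @export
centrality_summary <- function(mean, sd, group = NA_character_, B = NA_integer_) {
  mean <- as.matrix(mean)
  sd <- as.matrix(sd)
  stopifnot(identical(dim(mean), dim(sd)))
  if (any(sd < 0)) stop("centrality_summary: SD must be >= 0")
  structure(list(mean = mean, sd = sd, nodes = rownames(mean),
                 indices = colnames(mean), group = group, B = B),
            class = "centrality_summary")
}

#' Compare two groups' centrality summaries with z statistics
#'
#' Per node and index, `delta = mean_ref - mean_other`.  The `"plain"`
#' variant uses `z = delta / sqrt(sd_ref^2 + sd_other^2)` (the conventional
#' two-sample z on bootstrap SDs).  The `"scaled"` variant divides the
#' combined SD by 10 (equivalent to treating it as a standard error over
#' 100 replicates); it is the convention under which published
#' network-comparison z tables computed from bootstrap mean/SD summaries
#' are reproduced, and the two variants always agree on ranking (their z
#' values differ by the constant factor 10).  Two-sided p-values come from
#' the standard normal, with Bonferroni correction over the declared family
#' size `m` at `alpha`.
#'
#' @param summary_ref,summary_other [centrality_summary()] objects sharing
#'   node and index sets; `summary_ref` is the reference (its mean enters
#'   positively).
#' @param variant `"plain"` (default) or `"scaled"`.
#' @param m Bonferroni family size (default: nodes x indices).
#' @param alpha Significance level (default 0.05).
#' @return Data frame of class `comparison_table`: `node, index, mean_ref,
#'   sd_ref, mean_other, sd_other, z, p, p_adjusted, significant`.
#' @export
compare_groups <- function(summary_ref, summary_other,
                           variant = c("plain", "scaled"), m = NULL,
                           alpha = 0.05) {
  variant <- match.arg(variant)
  stopifnot(inherits(summary_ref, "centrality_summary"),
            inherits(summary_other, "centrality_summary"),
            identical(dim(summary_ref$mean), dim(summary_other$mean)))
  delta <- summary_ref$mean - summary_other$mean
  pooled <- sqrt(summary_ref$sd^2 + summary_other$sd^2)
  denom <- if (variant == "scaled") pooled / 10 else pooled
  z <- delta / denom
  zero_var <- pooled == 0
  if (any(zero_var & delta != 0))
    warning("ZeroVariance: zero combined SD with non-zero mean difference; ",
            "z set to +/-Inf")
  z[zero_var & delta == 0] <- 0
  z[zero_var & delta != 0] <- sign(delta[zero_var & delta != 0]) * Inf
  pval <- 2 * pnorm(-abs(z))
  if (is.null(m)) m <- length(z)
  adj <- bonferroni_adjust(as.vector(pval), m = m, alpha = alpha)
  nodes <- summary_ref$nodes
  if (is.null(nodes)) nodes <- paste0("V", seq_len(nrow(delta)))
  indices <- summary_ref$indices
  if (is.null(indices)) indices <- paste0("index", seq_len(ncol(delta)))
  out <- data.frame(
    node = rep(nodes, times = ncol(delta)),
    index = rep(indices, each = nrow(delta)),
    mean_ref = as.vector(summary_ref$mean),
    sd_ref = as.vector(summary_ref$sd),
    mean_other = as.vector(summary_other$mean),
    sd_other = as.vector(summary_other$sd),
    z = as.vector(z),
    p = as.vector(pval),
    p_adjusted = adj$p_adjusted,
    significant = adj$significant,
    stringsAsFactors = FALSE
  )
  attr(out, "variant") <- variant
  attr(out, "m") <- m
  attr(out, "reference") <- summary_ref$group
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Full two-group bootstrap comparison pipeline
#'
#' Splits a two-group score table, estimates each group's pruned network,
#' bootstraps each group's centralities, summarizes, and compares the
#' groups with z statistics under Bonferroni correction.  Per-group seeds
#' are spawned from the master seed, so the whole run is reproducible.
#'
#' @param table Two-group score table.
#' @param B Bootstrap replicates per group (default 1000).
#' @param seed Master integer seed.
#' @param reference Reference group label (its mean enters positively);
#'   default: the second group label in sorted order.
#' @param variant z variant, see [compare_groups()].
#' @param m Bonferroni family size (default: nodes x indices).
#' @param alpha Significance level.
#' @param adjust Edge-pruning adjustment, see [estimate_network()].
#' @param disconnected Closeness convention.
#' @return List with `networks` (per-group pruned networks), `bootstraps`,
#'   `summaries`, `comparison` (a [compare_groups()] table) and `reference`.
#' @export
run_group_comparison <- function(table, B = 1000, seed = 1, reference = NULL,
                                 variant = c("plain", "scaled"), m = NULL,
                                 alpha = 0.05, adjust = "none",
                                 disconnected = "zero") {
  variant <- match.arg(variant)
  groups <- sort(unique(as.character(table$group)))
  if (length(groups) != 2)
    stop("run_group_comparison: exactly two groups required")
  if (is.null(reference)) reference <- groups[2]
  if (!reference %in% groups) stop("unknown reference group: ", reference)
  other <- setdiff(groups, reference)
  set.seed(as.integer(seed))
  gseeds <- setNames(sample.int(2147483646L, 2), groups)
  split_tab <- lapply(setNames(groups, groups),
                      function(g) table[table$group == g, , drop = FALSE])
  networks <- lapply(split_tab, estimate_network, alpha = alpha, adjust = adjust)
  boots <- lapply(groups, function(g) {
    bootstrap_centrality(split_tab[[g]], B = B, seed = gseeds[[g]],
                         alpha = alpha, adjust = adjust,
                         disconnected = disconnected)
  })
  names(boots) <- groups
  summaries <- lapply(boots, summarize_bootstrap)
  comparison <- compare_groups(summaries[[reference]], summaries[[other]],
                               variant = variant, m = m, alpha = alpha)
  list(networks = networks, bootstraps = boots, summaries = summaries,
       comparison = comparison, reference = reference)
}
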