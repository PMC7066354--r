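#' Weighted partial-correlation network
#'
#' A node-labelled symmetric edge-weight matrix; weights are partial
#' correlations, absent edges are exactly 0 and the diagonal is 0.
#'
#' @param W Symmetric numeric matrix, zero diagonal, |w| < 1.
#' @param nodes Node labels (default: `rownames(W)`).
#' @return Object of class `weighted_network` (a list with `nodes`, `W`).
#' @export
weighted_network <- function(W, nodes = rownames(W)) {
  W <- as.matrix(W)
  p <- nrow(W)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  stopifnot(ncol(W) == p, length(nodes) == p)
  if (max(abs(W - t(W))) > 1e-12) stop("weighted_network: W must be symmetric")
  if (any(diag(W) != 0)) stop("weighted_network: diagonal must be 0")
  if (any(abs(W) >= 1)) stop("weighted_network: |weights| must be < 1")
  W <- (W + t(W)) / 2
  dimnames(W) <- list(nodes, nodes)
  structure(list(nodes = nodes, W = W), class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  ne <- sum(x$W[upper.tri(x$W)] != 0)
  cat("weighted_network:", length(x$nodes), "nodes,", ne, "edges\n")
  invisible(x)
}

#' Edge list of a network
#' @param network A [weighted_network()].
#' @param keep_zero Include absent edges (all node pairs) when `TRUE`.
#' @return Data frame `node_i, node_j, weight`.
#' @export
network_edges <- function(network, keep_zero = FALSE) {
  ut <- which(upper.tri(network$W), arr.ind = TRUE)
  out <- data.frame(node_i = network$nodes[ut[, 1]],
                    node_j = network$nodes[ut[, 2]],
                    weight = network$W[ut],
                    stringsAsFactors = FALSE)
  if (!keep_zero) out <- out[out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Number of connected components of a network
#' @param network A [weighted_network()] (absent edges are exact zeros).
#' @return Integer component count.
#' @export
network_components <- function(network) {
  g <- igraph::graph_from_adjacency_matrix(abs(network$W) > 0, mode = "undirected")
  igraph::components(g)$no
}

#' Unbiased sample covariance of a score table
#'
#' @param table Score table or numeric matrix (columns = measures).
#' @return Covariance matrix (denominator n - 1) with measure labels.
#' @export
sample_covariance <- function(table) {
  X <- if (is.data.frame(table)) .score_matrix(table) else as.matrix(table)
  if (anyNA(X)) stop("InsufficientData: missing values in score table")
  if (nrow(X) < ncol(X) + 2)
    stop("InsufficientData: need at least p + 2 rows, got ", nrow(X))
  cov(X)
}

#' Partial correlations from a covariance matrix
#'
#' Gaussian graphical model estimate: with concentration matrix
#' `K = S^{-1}`, the edge weights are `W_ij = -K_ij / sqrt(K_ii K_jj)`
#' (diagonal 0).  No silent regularization: an ill-conditioned input raises
#' an error naming the most collinear pair, unless an explicit ridge is
#' requested for exploratory use.
#'
#' @param S Covariance (or correlation) matrix.
#' @param max_condition Condition-number threshold above which `S` is
#'   treated as singular (default 1e10).
#' @param ridge Optional ridge added to the diagonal (fraction of the mean
#'   diagonal; default 0 = off).  Applied loudly via a message.
#' @return Unpruned [weighted_network()].
#' @export
partial_correlations <- function(S, max_condition = 1e10, ridge = 0) {
  S <- as.matrix(S)
  if (ridge > 0) {
    message("partial_correlations: applying ridge ", ridge,
            " * mean(diag(S)) to the diagonal (exploratory use only)")
    S <- S + diag(ridge * mean(diag(S)), nrow(S))
  }
  K <- .concentration(S, max_condition)
  if (is.null(K)) {
    R <- suppressWarnings(stats::cov2cor(S))
    off <- abs(R); diag(off) <- 0
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    labs <- rownames(S)
    if (is.null(labs)) labs <- paste0("V", seq_len(nrow(S)))
    stop("SingularCovariance: condition number exceeds ", max_condition,
         "; strongest collinearity between ", labs[worst[1]], " and ",
         labs[worst[2]], " (r = ", signif(R[worst[1], worst[2]], 4), ")")
  }
  d <- sqrt(diag(K))
  W <- -K / tcrossprod(d)
  diag(W) <- 0
  W[abs(W) > 1 - 1e-12] <- sign(W[abs(W) > 1 - 1e-12]) * (1 - 1e-12)
  weighted_network(W, rownames(S))
}

# inverse of S, or NULL when singular / ill-conditioned
.concentration <- function(S, max_condition = 1e10) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  if (rcond(S) < 1 / max_condition) return(NULL)
  chol2inv(ch)
}

#' Analytic significance test for partial-correlation edges
#'
#' Each edge weight is tested with the t statistic for a partial
#' correlation, `t = w sqrt(df / (1 - w^2))` with `df = n - p` (n - 2 minus
#' the p - 2 conditioned variables), two-sided p from Student's t.
#'
#' @param network Unpruned [weighted_network()].
#' @param n_subjects Sample size behind the covariance estimate.
#' @return Object of class `edge_tests`: list with matrices `t`, `p` and
#'   scalar `df`.
#' @export
edge_significance <- function(network, n_subjects) {
  p <- length(network$nodes)
  df <- n_subjects - p
  if (df <= 0) stop("InsufficientData: df = n - p must be positive")
  W <- network$W
  tmat <- W * sqrt(df / pmax(1 - W^2, .Machine$double.eps))
  pmat <- 2 * pt(-abs(tmat), df)
  diag(pmat) <- NA_real_
  diag(tmat) <- NA_real_
  structure(list(t = tmat, p = pmat, df = df), class = "edge_tests")
}

#' Prune non-significant edges
#'
#' Sets edge weights to exactly 0 wherever the (optionally adjusted)
#' p-value is at or above `alpha`; surviving weights are unchanged.
#'
#' @param network Unpruned [weighted_network()].
#' @param tests Matching [edge_significance()] result.
#' @param alpha Significance level (default 0.05).
#' @param adjust Multiplicity adjustment over the p(p-1)/2 edge tests:
#'   `"none"` (default), `"bonferroni"` or `"holm"`.
#' @return Pruned [weighted_network()]; the applied p-values are attached as
#'   attribute `p_values`.
#' @export
prune_network <- function(network, tests, alpha = 0.05,
                          adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(identical(dim(network$W), dim(tests$p)))
  P <- tests$p
  if (adjust != "none") {
    ut <- upper.tri(P)
    P[ut] <- p.adjust(P[ut], method = adjust)
    P[lower.tri(P)] <- t(P)[lower.tri(P)]
  }
  W <- network$W
  drop <- !is.na(P) & P >= alpha
  W[drop] <- 0
  out <- weighted_network(W, network$nodes)
  attr(out, "p_values") <- P
  out
}

#' Estimate a pruned partial-correlation network from scores
#'
#' The full per-group chain: z-score the measures, take the sample
#' covariance, invert to partial correlations, and keep only significant
#' edges.  Partial correlations are scale-free, so standardization is
#' presentation-neutral.
#'
#' @param table Single-group score table (or numeric score matrix).
#' @param alpha Edge significance level (default 0.05).
#' @param adjust Edge-test multiplicity adjustment (default `"none"`).
#' @param max_condition,ridge Passed to [partial_correlations()].
#' @return Pruned [weighted_network()] with attributes `n` (sample size),
#'   `tests` (the [edge_significance()] object) and `p_values`.
#' @export
estimate_network <- function(table, alpha = 0.05,
                             adjust = c("none", "bonferroni", "holm"),
                             max_condition = 1e10, ridge = 0) {
  adjust <- match.arg(adjust)
  X <- if (is.data.frame(table)) .score_matrix(table) else as.matrix(table)
  X <- scale(X)
  S <- sample_covariance(X)
  net <- partial_correlations(S, max_condition = max_condition, ridge = ridge)
  tests <- edge_significance(net, nrow(X))
  out <- prune_network(net, tests, alpha = alpha, adjust = adjust)
  attr(out, "n") <- nrow(X)
  attr(out, "tests") <- tests
  out
}
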