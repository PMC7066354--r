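# Weighted geodesics and the three centrality indices.
#
# Distances use the reciprocal-absolute-weight metric (the convention of the
# psychometric network literature): a strong edge is a short link.  Geodesic
# ties are counted within a 1e-9 relative tolerance.

.tie_tol <- 1e-9

#' Edge lengths of a weighted network
#'
#' `length_ij = 1 / |w_ij|` for present edges, `Inf` for absent edges,
#' 0 on the diagonal.
#'
#' @param network A [weighted_network()].
#' @return Numeric length matrix.
#' @export
edge_lengths <- function(network) {
  L <- 1 / abs(network$W)
  diag(L) <- 0
  L
}

# Floyd-Warshall with geodesic counting on an absolute-weight matrix.
# Returns D (shortest lengths, Inf = unreachable) and sigma (geodesic
# counts; 0 when unreachable).  Ties within relative tolerance are pooled.
.fw_paths <- function(A) {
  p <- nrow(A)
  D <- 1 / A
  diag(D) <- 0
  sig <- (A > 0) * 1
  diag(sig) <- 0
  for (k in seq_len(p)) {
    via <- outer(D[, k], D[k, ], `+`)
    nsig <- tcrossprod(sig[, k], sig[k, ])
    finite <- is.finite(via)
    tol <- .tie_tol * via
    shorter <- finite & (via < D - tol)
    equal <- finite & !shorter & (via <= D + tol)
    D[shorter] <- via[shorter]
    sig[shorter] <- nsig[shorter]
    sig[equal] <- sig[equal] + nsig[equal]
  }
  list(D = D, sigma = sig)
}

#' Shortest paths with geodesic counts
#'
#' All-pairs shortest path lengths under a non-negative length matrix, with
#' the number of tied geodesics per pair and, for every node, the number of
#' geodesics passing through it.  Two path lengths are tied when they agree
#' to 1e-9 relative tolerance.
#'
#' @param lengths Length matrix as from [edge_lengths()] (non-negative,
#'   `Inf` = no direct link, zero diagonal).
#' @return List with `D` (p x p lengths), `sigma` (p x p geodesic counts;
#'   `sigma_jk >= 1` iff k reachable from j) and `through` (p x p x p array:
#'   `through[i, j, k]` = geodesics from j to k with i as an intermediate).
#' @export
shortest_paths <- function(lengths) {
  L <- as.matrix(lengths)
  if (any(L < 0, na.rm = TRUE)) stop("shortest_paths: negative lengths")
  A <- 1 / L          # back to "conductance" form used by .fw_paths
  diag(A) <- 0
  fw <- .fw_paths(A)
  p <- nrow(L)
  through <- array(0, dim = c(p, p, p),
                   dimnames = list(rownames(L), rownames(L), rownames(L)))
  for (i in seq_len(p)) {
    thr <- outer(fw$D[, i], fw$D[i, ], `+`)
    cnt <- tcrossprod(fw$sigma[, i], fw$sigma[i, ])
    on <- is.finite(fw$D) & is.finite(thr) &
      abs(thr - fw$D) <= .tie_tol * pmax(fw$D, 1e-300)
    m <- matrix(0, p, p)
    m[on] <- cnt[on]
    diag(m) <- 0
    m[i, ] <- 0; m[, i] <- 0
    through[i, , ] <- m
  }
  list(D = fw$D, sigma = fw$sigma, through = through)
}

# strength / betweenness / closeness from a pruned weight matrix.
# Lean path shared by the public API and the bootstrap loop.
.centrality_matrix <- function(W, absolute = TRUE,
                               disconnected = c("zero", "component")) {
  disconnected <- match.arg(disconnected)
  p <- nrow(W)
  A <- abs(W)
  strength <- if (absolute) rowSums(A) else rowSums(W)
  fw <- .fw_paths(A)
  D <- fw$D
  sig <- fw$sigma
  # betweenness: b_i = sum_{j<k} sigma(j,i) sigma(i,k) / sigma(j,k) over
  # pairs whose geodesic passes through i (endpoints excluded via the zero
  # diagonal of sigma)
  b <- numeric(p)
  ut <- upper.tri(D)
  for (i in seq_len(p)) {
    thr <- outer(D[, i], D[i, ], `+`)
    on <- is.finite(D) & is.finite(thr) &
      abs(thr - D) <= .tie_tol * pmax(D, 1e-300) & sig > 0
    if (any(on & ut)) {
      cnt <- tcrossprod(sig[, i], sig[i, ])
      m <- on & ut
      b[i] <- sum(cnt[m] / sig[m])
    }
  }
  # closeness: (n-1) / sum of distances to ALL others; any unreachable peer
  # makes the sum infinite and closeness 0 (strict reading), unless the
  # within-component variant is requested
  if (disconnected == "zero") {
    tot <- rowSums(D)
    closeness <- ifelse(is.finite(tot) & tot > 0, (p - 1) / tot, 0)
    closeness[p == 1] <- 0
  } else {
    closeness <- vapply(seq_len(p), function(i) {
      reach <- is.finite(D[i, ]) & seq_len(p) != i
      if (!any(reach)) return(0)
      sum(reach) / sum(D[i, reach])
    }, numeric(1))
  }
  out <- cbind(strength = strength, betweenness = b, closeness = closeness)
  rownames(out) <- rownames(W)
  out
}

#' Node strength
#'
#' `k_i = sum_j |w_ij|`: a node's total (absolute) edge weight.  The
#' absolute-value convention keeps strength non-negative in the presence of
#' negative partial correlations; the raw signed sum is available with
#' `absolute = FALSE`.
#'
#' @param network A [weighted_network()].
#' @param absolute Sum absolute weights (default) or raw signed weights.
#' @return Named numeric vector, one value per node.
#' @export
node_strength <- function(network, absolute = TRUE) {
  A <- if (absolute) abs(network$W) else network$W
  setNames(rowSums(A), network$nodes)
}

#' Node betweenness
#'
#' `b_i = sum_{j<k} p_jk(i) / p_jk`: over every pair of other nodes, the
#' fraction of their geodesics (under the 1/|w| length metric) that pass
#' through node i.  Unreachable pairs contribute 0; the maximum possible
#' value is (p-1)(p-2)/2, attained by a star centre.
#'
#' @param network A [weighted_network()].
#' @return Named numeric vector.
#' @export
node_betweenness <- function(network) {
  setNames(.centrality_matrix(network$W)[, "betweenness"], network$nodes)
}

#' Node closeness
#'
#' `(n - 1) / sum_j d_ij`: inverse average geodesic distance from the node
#' to every other node.  When any peer is unreachable the distance sum is
#' infinite and closeness is 0 under the strict convention (default); the
#' `"component"` convention instead uses `(n_c - 1) / sum` within the
#' node's connected component.
#'
#' @param network A [weighted_network()].
#' @param disconnected `"zero"` (default) or `"component"`.
#' @return Named numeric vector.
#' @export
node_closeness <- function(network, disconnected = c("zero", "component")) {
  disconnected <- match.arg(disconnected)
  setNames(.centrality_matrix(network$W, disconnected = disconnected)[, "closeness"],
           network$nodes)
}

#' Centrality profile of a network
#'
#' Bundles strength, betweenness and closeness per node (node order
#' preserved).
#'
#' @param network A [weighted_network()].
#' @param absolute Strength convention, see [node_strength()].
#' @param disconnected Closeness convention, see [node_closeness()].
#' @return Data frame `node, strength, betweenness, closeness`.
#' @export
centrality_profile <- function(network, absolute = TRUE,
                               disconnected = c("zero", "component")) {
  disconnected <- match.arg(disconnected)
  M <- .centrality_matrix(network$W, absolute = absolute,
                          disconnected = disconnected)
  data.frame(node = network$nodes, strength = M[, "strength"],
             betweenness = M[, "betweenness"], closeness = M[, "closeness"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Long-format centrality table
#' @param profile Result of [centrality_profile()].
#' @return Data frame `node, index, value` (for plotting).
#' @export
centrality_long <- function(profile) {
  data.frame(
    node = rep(profile$node, 3),
    index = rep(c("strength", "betweenness", "closeness"),
                each = nrow(profile)),
    value = c(profile$strength, profile$betweenness, profile$closeness),
    stringsAsFactors = FALSE
  )
}

# fast path used by the bootstrap: scores -> pruned GGM -> p x 3 centrality
# matrix; NULL when the covariance is singular/ill-conditioned
.fit_centrality <- function(X, alpha = 0.05, adjust = "none",
                            max_condition = 1e10,
                            disconnected = "zero") {
  n <- nrow(X)
  p <- ncol(X)
  S <- cov(X)
  K <- .concentration(S, max_condition)
  if (is.null(K)) return(NULL)
  d <- sqrt(diag(K))
  W <- -K / tcrossprod(d)
  diag(W) <- 0
  df <- n - p
  tmat <- W * sqrt(df / pmax(1 - W^2, .Machine$double.eps))
  P <- 2 * pt(-abs(tmat), df)
  if (adjust != "none") {
    ut <- upper.tri(P)
    P[ut] <- p.adjust(P[ut], method = adjust)
    P[lower.tri(P)] <- t(P)[lower.tri(P)]
  }
  W[P >= alpha] <- 0
  diag(W) <- 0
  .centrality_matrix(W, disconnected = disconnected)
}
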