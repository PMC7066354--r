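#' Generating partial-correlation structure
#'
#' Encodes the population network a synthetic cohort is drawn from: an
#' ordered node set plus a sparse list of partial correlations.  The implied
#' standardized precision matrix (unit diagonal, off-diagonal `-rho` on
#' listed edges) must be positive definite.
#'
#' @param nodes Ordered character vector of node labels.
#' @param edges Data frame with columns `from`, `to`, `rho` (each `rho` in
#'   (-1, 1)); may have zero rows for an empty (independence) structure.
#' @param label Group label attached to cohorts drawn from this structure.
#' @return An object of class `structure_spec`.
#' @export
structure_spec <- function(nodes, edges = NULL, label = "group") {
  stopifnot(is.character(nodes), length(nodes) >= 2L, !anyDuplicated(nodes))
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        rho = numeric(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "rho") %in% names(edges)))
    stop("structure_spec: 'edges' needs columns from, to, rho")
  bad <- setdiff(c(edges$from, edges$to), nodes)
  if (length(bad)) stop("structure_spec: unknown node(s): ",
                        paste(bad, collapse = ", "))
  if (any(edges$from == edges$to)) stop("structure_spec: self-edges not allowed")
  if (any(abs(edges$rho) >= 1)) stop("structure_spec: |rho| must be < 1")
  key <- apply(edges[, c("from", "to")], 1L,
               function(r) paste(sort(r), collapse = "\r"))
  if (anyDuplicated(key)) stop("structure_spec: duplicate edge pair(s)")
  spec <- structure(list(nodes = nodes, edges = edges, label = label),
                    class = "structure_spec")
  precision_from_structure(spec)  # errors if jointly infeasible
  spec
}

#' Standardized precision matrix of a generating structure
#'
#' Under the Gaussian graphical model relation `rho_ij = -K_ij / sqrt(K_ii
#' K_jj)`, a unit-diagonal precision matrix with `K_ij = -rho_ij` on listed
#' edges (0 elsewhere) generates exactly the requested partial correlations.
#'
#' @param spec A [structure_spec()].
#' @return Symmetric positive-definite matrix with node labels as dimnames.
#' @export
precision_from_structure <- function(spec) {
  stopifnot(inherits(spec, "structure_spec"))
  p <- length(spec$nodes)
  K <- diag(p)
  dimnames(K) <- list(spec$nodes, spec$nodes)
  if (nrow(spec$edges)) {
    i <- match(spec$edges$from, spec$nodes)
    j <- match(spec$edges$to, spec$nodes)
    K[cbind(i, j)] <- -spec$edges$rho
    K[cbind(j, i)] <- -spec$edges$rho
  }
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("NotPositiveDefinite: requested edge weights are jointly infeasible ",
         "(min eigenvalue ", signif(min(ev), 3), ")")
  K
}

#' Population correlation matrix implied by a structure
#'
#' Inverts the standardized precision matrix and rescales to unit variances.
#' Estimating partial correlations from this matrix recovers the structure's
#' edge weights exactly.
#'
#' @param spec A [structure_spec()].
#' @return Correlation matrix (p x p).
#' @export
correlation_from_structure <- function(spec) {
  K <- precision_from_structure(spec)
  stats::cov2cor(solve(K))
}

#' Number of connected components of a structure
#' @param spec A [structure_spec()].
#' @return Integer component count (isolated nodes count as components).
#' @export
structure_components <- function(spec) {
  g <- igraph::graph_from_data_frame(spec$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = spec$nodes)
  igraph::components(g)$no
}

#' Preset generating structures
#'
#' `td_like_structure()` is a connected 6-edge tree over the seven measures
#' with high-strength hub nodes A_TOM, SSQ_EQ and ET (weights 0.30-0.40,
#' A_TOM the strongest node); `asd_like_structure()` has three weak edges
#' (|rho| <= 0.30) leaving four disconnected components.  These mirror the
#' qualitative contrast between a connected typically-developing network and
#' a fragmented ASD network.
#'
#' @return A [structure_spec()].
#' @export
td_like_structure <- function() {
  structure_spec(
    nodes = sc_measure_names(),
    edges = data.frame(
      from = c("A_TOM", "A_TOM", "A_TOM", "SSQ_EQ", "SSQ_EQ", "ET"),
      to   = c("SSQ_EQ", "ET", "EEQ_EQ", "AES_BES", "CEQ_EQ", "CES_BES"),
      rho  = c(0.40, 0.35, 0.30, 0.30, 0.30, 0.30),
      stringsAsFactors = FALSE
    ),
    label = "TD"
  )
}

#' @rdname td_like_structure
#' @export
asd_like_structure <- function() {
  structure_spec(
    nodes = sc_measure_names(),
    edges = data.frame(
      from = c("CES_BES", "CEQ_EQ", "ET"),
      to   = c("AES_BES", "EEQ_EQ", "A_TOM"),
      rho  = c(0.30, 0.25, 0.25),
      stringsAsFactors = FALSE
    ),
    label = "ASD"
  )
}

#' Cohort configuration
#'
#' Bundles a group's sample size, generating structure and the seven measure
#' marginals.
#'
#' @param n Number of participants (>= 10).
#' @param structure A [structure_spec()].
#' @param measures List of 7 [measure_spec()]s named/ordered like
#'   `structure$nodes`.
#' @param label Group label; defaults to the structure's label.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n, structure, measures, label = structure$label) {
  stopifnot(inherits(structure, "structure_spec"))
  if (n < 10) stop("cohort_config: n must be >= 10")
  if (length(measures) != length(structure$nodes))
    stop("cohort_config: need exactly ", length(structure$nodes), " measures")
  mnames <- unname(vapply(measures, function(m) m$name, character(1)))
  if (!identical(mnames, structure$nodes))
    stop("cohort_config: measure names/order must match structure nodes")
  structure(list(n = as.integer(n), structure = structure,
                 measures = measures, label = label),
            class = "cohort_config")
}

#' Default two-scenario study configuration
#'
#' The study conditions emulated throughout: a TD-like cohort (n = 61,
#' connected hub structure, TD marginals) and an ASD-like cohort (n = 65,
#' fragmented sparse structure, ASD marginals).
#'
#' @return Named list with elements `td_like` and `asd_like`, each a
#'   [cohort_config()].
#' @export
default_scenarios <- function() {
  list(
    td_like = cohort_config(61L, td_like_structure(), measure_presets("TD")),
    asd_like = cohort_config(65L, asd_like_structure(), measure_presets("ASD"))
  )
}
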