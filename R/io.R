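#' Read and validate a participant score CSV
#'
#' Expects a header row with `participant_id` (optional), a group column and
#' numeric measure columns.  Validation failures name the offending row or
#' column.
#'
#' @param path CSV file (comma-separated, dot decimal, UTF-8).
#' @param group_col Name of the group column (default `"group"`).
#' @param measures Measure column names; default: every column other than
#'   `participant_id` and the group column.
#' @return Validated score table.
#' @export
read_score_csv <- function(path, group_col = "group", measures = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  if (!group_col %in% names(raw))
    stop("MissingColumn: group column '", group_col, "' not found in ", path)
  if (is.null(measures))
    measures <- setdiff(names(raw), c("participant_id", group_col))
  missing <- setdiff(measures, names(raw))
  if (length(missing))
    stop("MissingColumn: ", paste(missing, collapse = ", "))
  out <- data.frame(stringsAsFactors = FALSE,
                    participant_id = if ("participant_id" %in% names(raw))
                      raw$participant_id else sprintf("row_%04d", seq_len(nrow(raw))),
                    group = raw[[group_col]])
  if (anyDuplicated(out$participant_id))
    stop("DuplicateParticipantId: ",
         paste(unique(out$participant_id[duplicated(out$participant_id)]),
               collapse = ", "))
  for (cl in measures) {
    vals <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(vals))
    if (length(bad))
      stop("NonNumericCell: column '", cl, "', row ", bad[1],
           " (value '", raw[[cl]][bad[1]], "')")
    out[[cl]] <- vals
  }
  out
}

#' Write a score table as CSV
#' @param table Score table.
#' @param path Output file.
#' @export
write_score_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a network as an edge-list CSV
#'
#' One row per node pair: `node_i, node_j, weight, p_value, retained`.
#'
#' @param network A pruned [weighted_network()] (from [estimate_network()],
#'   so p-values are attached) or any weighted network.
#' @param path Output file.
#' @export
write_network_csv <- function(network, path) {
  edges <- network_edges(network, keep_zero = TRUE)
  P <- attr(network, "p_values")
  if (!is.null(P)) {
    ut <- which(upper.tri(network$W), arr.ind = TRUE)
    edges$p_value <- P[ut]
  } else {
    edges$p_value <- NA_real_
  }
  edges$retained <- edges$weight != 0
  write.csv(format_numeric(edges), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Standard GraphML via igraph, with the partial correlation stored in the
#' `weight` edge attribute; all nodes are written even when the network has
#' no edges.
#'
#' @param network A [weighted_network()].
#' @param path Output file.
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_adjacency_matrix(network$W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a centrality profile CSV
#' @param profile [centrality_profile()] output.
#' @param path Output file.
#' @param long Also derivable long format (`node,index,value`) if `TRUE`.
#' @export
write_centrality_csv <- function(profile, path, long = FALSE) {
  out <- if (long) centrality_long(profile) else profile
  write.csv(format_numeric(out), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a group-comparison table CSV
#' @param comparison [compare_groups()] output.
#' @param path Output file.
#' @export
write_comparison_csv <- function(comparison, path) {
  write.csv(format_numeric(as.data.frame(comparison)), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

# print numeric columns at 6 significant digits for stable text output
format_numeric <- function(df) {
  for (cl in names(df)) {
    if (is.numeric(df[[cl]])) df[[cl]] <- signif(df[[cl]], 6)
  }
  df
}

#' Write a run manifest
#'
#' Records everything needed to regenerate a run byte-for-byte: the
#' configuration, master seed, package version and any bootstrap redraw
#' counts.
#'
#' @param path Output JSON file.
#' @param seed Master seed of the run.
#' @param config Named list of run settings.
#' @param redraws Named vector/list of per-group degenerate-replicate
#'   redraw counts (optional).
#' @export
write_manifest <- function(path, seed, config = list(), redraws = NULL) {
  manifest <- list(
    package = "scnet",
    version = as.character(packageVersion("scnet")),
    seed = as.integer(seed),
    config = config,
    redraws = redraws,
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a run manifest
#' @param path Manifest JSON file.
#' @return Named list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Serialize a scenario configuration to JSON
#' @param config A [cohort_config()].
#' @param path Output JSON file.
#' @export
write_scenario_json <- function(config, path) {
  jsonlite::write_json(list(
    label = config$label,
    n = config$n,
    nodes = config$structure$nodes,
    edges = config$structure$edges,
    measures = lapply(config$measures, function(m)
      list(name = m$name, mean = m$mean, sd = m$sd, range = m$range))
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a scenario configuration from JSON
#' @param path JSON file written by [write_scenario_json()].
#' @return A [cohort_config()].
#' @export
read_scenario_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- structure_spec(unlist(raw$nodes), raw$edges, label = raw$label)
  measures <- lapply(raw$measures, function(m)
    measure_spec(m$name, m$mean, m$sd,
                 range = if (length(m$range)) unlist(m$range) else NULL))
  cohort_config(raw$n, spec, measures, label = raw$label)
}
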