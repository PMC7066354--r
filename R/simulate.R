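#' Draw one synthetic cohort
#'
#' Latent scores are multivariate Gaussian with the correlation matrix
#' implied by the generating structure's precision matrix, then affinely
#' rescaled to each measure's target mean and SD.  Scores are continuous by
#' default (the pipeline standardizes everything, so integer rounding is
#' optional); draws outside a measure's admissible range are reported via a
#' warning rather than truncated, so the correlation structure is not
#' distorted (truncation available behind `truncate`).
#'
#' @param n Participants to draw.
#' @param structure A [structure_spec()].
#' @param measures List of [measure_spec()]s matching `structure$nodes`.
#' @param seed Integer seed; same seed, same table.
#' @param label Group label for the `group` column.
#' @param integer_scores Round scores to integers (off by default).
#' @param truncate Clamp scores into the admissible range (off by default;
#'   distorts the generating correlations when on).
#' @param warn_range Warn when draws fall outside an admissible range.
#' @return A score table: data frame with `participant_id`, `group` and one
#'   numeric column per measure.
#' @export
generate_group <- function(n, structure, measures, seed,
                           label = structure$label,
                           integer_scores = FALSE, truncate = FALSE,
                           warn_range = TRUE) {
  cfg <- cohort_config(n, structure, measures, label)
  Sigma <- correlation_from_structure(cfg$structure)
  p <- ncol(Sigma)
  set.seed(as.integer(seed))
  Z <- matrix(rnorm(cfg$n * p), cfg$n, p) %*% chol(Sigma)
  X <- Z
  for (j in seq_len(p)) {
    m <- cfg$measures[[j]]
    X[, j] <- m$mean + m$sd * Z[, j]
    if (integer_scores) X[, j] <- round(X[, j])
    if (!is.null(m$range)) {
      out_of_range <- sum(X[, j] < m$range[1] | X[, j] > m$range[2])
      if (truncate) {
        X[, j] <- pmin(pmax(X[, j], m$range[1]), m$range[2])
      } else if (warn_range && out_of_range > 0) {
        warning(out_of_range, " draw(s) of ", m$name,
                " outside admissible range [", m$range[1], ", ", m$range[2],
                "] (reported, not truncated)", call. = FALSE)
      }
    }
  }
  colnames(X) <- cfg$structure$nodes
  out <- data.frame(
    participant_id = sprintf("%s_%04d", cfg$label, seq_len(cfg$n)),
    group = rep(cfg$label, cfg$n),
    X,
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Simulate the default two-group study
#'
#' Draws both default scenarios ([default_scenarios()]) with seeds derived
#' from one master seed and stacks them into a single two-group score table.
#'
#' @param seed Master integer seed.
#' @param scenarios List of [cohort_config()]s (default: the two presets).
#' @param ... Passed on to [generate_group()].
#' @return Combined score table (one row per participant across all groups).
#' @export
simulate_study <- function(seed, scenarios = default_scenarios(), ...) {
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(2147483646L, length(scenarios))
  tabs <- lapply(seq_along(scenarios), function(i) {
    cfg <- scenarios[[i]]
    generate_group(cfg$n, cfg$structure, cfg$measures, seed = sub_seeds[i], ...)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Measure columns of a score table
#' @param table Score table.
#' @return Character vector of numeric measure column names (everything but
#'   `participant_id` and `group`).
#' @export
measure_columns <- function(table) {
  setdiff(names(table), c("participant_id", "group"))
}

# numeric matrix of the measure columns
.score_matrix <- function(table, measures = measure_columns(table)) {
  X <- as.matrix(table[, measures, drop = FALSE])
  storage.mode(X) <- "double"
  X
}
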