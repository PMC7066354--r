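#' Canonical social-cognition measure names
#'
#' The seven measures, in the fixed column order used throughout the package:
#' the cognitive and affective empathy subscales of the Basic Empathy Scale
#' (CES_BES, AES_BES), the Eyes Task (ET), the cognitive, social-skills and
#' emotional subscales of the Empathy Quotient (CEQ_EQ, SSQ_EQ, EEQ_EQ), and
#' the Advanced Theory of Mind task (A_TOM).
#'
#' @return Character vector of length 7.
#' @export
sc_measure_names <- function() {
  c("CES_BES", "AES_BES", "ET", "CEQ_EQ", "SSQ_EQ", "EEQ_EQ", "A_TOM")
}

#' Specification of one measure's marginal distribution
#'
#' Describes the target mean and SD (in raw score units) of one measure in a
#' synthetic cohort, with an optional admissible score range used for
#' reporting out-of-range draws.
#'
#' @param name Measure label (one of [sc_measure_names()] in typical use).
#' @param mean Target sample mean, score units.
#' @param sd Target sample SD, score units; must be positive.
#' @param range Optional numeric `c(min, max)` admissible score range.
#' @return An object of class `measure_spec`.
#' @export
measure_spec <- function(name, mean, sd, range = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd))
  if (sd <= 0) stop("measure_spec: 'sd' must be > 0 for ", name)
  if (!is.null(range)) {
    stopifnot(is.numeric(range), length(range) == 2L)
    if (!(range[1] < range[2]))
      stop("measure_spec: admissible range must satisfy min < max for ", name)
    if (mean < range[1] || mean > range[2])
      stop("InvalidRange: target mean ", mean, " outside admissible range [",
           range[1], ", ", range[2], "] for ", name)
  }
  structure(list(name = name, mean = mean, sd = sd, range = range),
            class = "measure_spec")
}

# admissible score ranges: ET and A-ToM bounds from the task definitions
# (36 photographs; 13 vignettes scored 0-1 each); BES subscales from item
# counts (CES 9 items, AES 11 items, 1-5 Likert). EQ subscale item counts
# are instrument-version dependent, so no range is imposed.
.sc_ranges <- list(
  CES_BES = c(9, 45), AES_BES = c(11, 55), ET = c(0, 36),
  CEQ_EQ = NULL, SSQ_EQ = NULL, EEQ_EQ = NULL, A_TOM = c(0, 13)
)

#' Reference per-group summary statistics of the seven measures
#'
#' Mean and SD of each social-cognition measure in the reference ASD
#' (n = 65) and TD (n = 61) cohorts.  These are the marginals the synthetic
#' presets reproduce and the input to closed-form between-group ANOVA
#' ([anova_from_summary()]).
#'
#' @return A data frame with columns `measure`, `mean_asd`, `sd_asd`,
#'   `mean_td`, `sd_td`, plus attributes `n_asd` (65) and `n_td` (61).
#' @export
sc_measure_summaries <- function() {
  out <- data.frame(
    measure = sc_measure_names(),
    mean_asd = c(28.40, 33.30, 19.90, 9.86, 4.00, 9.40, 7.60),
    sd_asd   = c(5.40, 6.76, 5.26, 3.79, 0.81, 3.59, 3.37),
    mean_td  = c(40.67, 42.00, 23.64, 13.04, 10.83, 16.66, 12.67),
    sd_td    = c(3.44, 3.68, 2.89, 3.33, 1.32, 3.26, 0.51),
    stringsAsFactors = FALSE
  )
  attr(out, "n_asd") <- 65L
  attr(out, "n_td") <- 61L
  out
}

#' Reference bootstrap centrality summaries per group
#'
#' Bootstrap mean and SD of strength, betweenness and closeness for every
#' node in the reference ASD and TD networks (B = 1000 case-resampling
#' replicates).  Together with [compare_groups()] (variant `"scaled"`) these
#' summaries yield the reference between-group z statistics.
#'
#' @return Long data frame: `node`, `index`, `mean_asd`, `sd_asd`,
#'   `mean_td`, `sd_td`.
#' @export
sc_centrality_summaries <- function() {
  nodes <- sc_measure_names()
  data.frame(
    node = rep(nodes, times = 3),
    index = rep(c("betweenness", "closeness", "strength"), each = 7),
    mean_asd = c(1.23, 2.23, 0.95, 1.19, 0.82, 1.80, 1.71,
                 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01,
                 1.08, 1.40, 0.92, 0.96, 0.87, 1.31, 1.10),
    sd_asd   = c(3.11, 3.77, 3.16, 3.39, 2.31, 3.42, 3.71,
                 0.03, 0.03, 0.03, 0.03, 0.03, 0.03, 0.03,
                 1.15, 1.09, 1.20, 1.11, 1.22, 1.12, 1.25),
    mean_td  = c(0.46, 0.81, 0.99, 0.75, 3.17, 2.44, 5.94,
                 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.02,
                 0.61, 1.46, 1.93, 0.91, 1.85, 1.55, 2.51),
    sd_td    = c(2.26, 2.75, 2.97, 2.60, 4.77, 4.35, 5.82,
                 0.02, 0.02, 0.03, 0.02, 0.03, 0.03, 0.03,
                 0.84, 0.91, 0.86, 0.89, 0.94, 0.99, 0.79),
    stringsAsFactors = FALSE
  )
}

#' Measure presets for one reference group
#'
#' Builds the list of seven [measure_spec()]s whose means/SDs match the
#' reference summaries of the requested group.
#'
#' @param group `"TD"` or `"ASD"`.
#' @return List of 7 `measure_spec` objects in canonical order.
#' @export
measure_presets <- function(group = c("TD", "ASD")) {
  group <- match.arg(group)
  tab <- sc_measure_summaries()
  mcol <- if (group == "TD") tab$mean_td else tab$mean_asd
  scol <- if (group == "TD") tab$sd_td else tab$sd_asd
  out <- lapply(seq_len(nrow(tab)), function(i) {
    measure_spec(tab$measure[i], mcol[i], scol[i],
                 range = .sc_ranges[[tab$measure[i]]])
  })
  names(out) <- tab$measure
  out
}
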