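# small synthetic cohort used across test files
small_cohort <- function(n = 80, seed = 21, label = "g1") {
  spec <- td_like_structure()
  spec$label <- label
  suppressWarnings(generate_group(n, spec, measure_presets("TD"), seed = seed,
                                  label = label, warn_range = FALSE))
}
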