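#!/usr/bin/env Rscript
# Step 4: case-resampling bootstrap (B = 1000 per group) of the centrality
# indices and the between-group z comparison, Bonferroni-corrected over the
# 21 node x index cells.  Also reproduces the reference z table from the
# packaged bootstrap summaries via the scaled variant.

suppressPackageStartupMessages(library(scnet))

seed <- 20200124L
B <- 1000L

tab <- read_score_csv("results/scores.csv")
res <- run_group_comparison(tab, B = B, seed = seed, reference = "TD",
                            variant = "plain", m = 21)
write_comparison_csv(res$comparison, "results/comparison_simulated.csv")
write_manifest("results/manifest_bootstrap.json", seed = seed,
               config = list(B = B, variant = "plain", m = 21,
                             reference = res$reference),
               redraws = lapply(res$bootstraps, `[[`, "redraws"))

cat("Bootstrap comparison (reference TD, plain z, B =", B, "):\n")
sig <- res$comparison[res$comparison$significant, c("node", "index", "z")]
print(cbind(sig[, 1:2], z = round(sig$z, 2)), row.names = FALSE)

# reference z table from the packaged bootstrap mean/SD summaries
ref <- sc_centrality_summaries()
idx <- unique(ref$index)
as_summary <- function(mcol, scol, grp) {
  centrality_summary(
    matrix(ref[[mcol]], 7, 3, dimnames = list(sc_measure_names(), idx)),
    matrix(ref[[scol]], 7, 3, dimnames = list(sc_measure_names(), idx)),
    group = grp, B = 1000L)
}
cmp <- compare_groups(as_summary("mean_td", "sd_td", "TD"),
                      as_summary("mean_asd", "sd_asd", "ASD"),
                      variant = "scaled", m = 21)
write_comparison_csv(cmp, "results/comparison_reference.csv")
cat("\nReference-summary z statistics (scaled variant):\n")
print(cbind(cmp[, c("node", "index")], z = round(cmp$z, 2)), row.names = FALSE)
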