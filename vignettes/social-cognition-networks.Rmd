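---
title: "Partial-correlation networks over social-cognition measures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-correlation networks over social-cognition measures}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The model

`scnet` analyses a participant × measure score table for two groups.  Seven
social-cognition measures form the node set: the cognitive and affective
empathy subscales of the Basic Empathy Scale (`CES_BES`, `AES_BES`), the
Eyes Task (`ET`), the cognitive, social-skills and emotional subscales of
the Empathy Quotient (`CEQ_EQ`, `SSQ_EQ`, `EEQ_EQ`), and the Advanced
Theory of Mind task (`A_TOM`).

Each group's network is a Gaussian graphical model: after z-scoring, the
sample covariance `S` is inverted and the edge between measures *i* and
*j* is the partial correlation `-K_ij / sqrt(K_ii K_jj)` with `K = S^-1` —
the association between two measures conditional on all the others.  Edges
are kept only when significant; on the pruned weighted graph we compute
strength, betweenness and closeness per node, bootstrap all three by case
resampling within each group, and compare groups cell-by-cell with z
statistics under Bonferroni correction.  A between-group one-way ANOVA on
the raw measures (Bonferroni over the seven tests) completes the pipeline.

The GGM assumes approximately multivariate-Gaussian, linearly related
measures with enough participants to invert a 7 × 7 covariance stably
(`n > p + 1` is required; `n` of several dozen is realistic for this
design).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | edge-retention significance level |
| `adjust` | `"none"` | multiplicity adjustment over the 21 edge tests (`bonferroni`/`holm` selectable) |
| `B` | 1000 | bootstrap replicates per group |
| `m` | 21 (7 nodes × 3 indices) | Bonferroni family size for the group comparison; 7 for the ANOVA |
| `variant` | `"plain"` | z denominator (see below) |
| `disconnected` | `"zero"` | closeness convention for disconnected graphs |
| `max_condition` | 1e10 | covariance condition-number limit before a `SingularCovariance` error |

Defaults that deserve a word:

* **Edge significance.**  Pruning "keep only significant partial
  correlations" needs a test; we use the analytic t test for a partial
  correlation, `t = w sqrt(df/(1 - w^2))` with `df = n − p` (n − 2 minus
  the p − 2 conditioned variables), two-sided, unadjusted at α = 0.05 —
  the common "threshold by significance" practice in psychometric network
  software.  Simulation confirms the nominal level: under a fully
  independent generating model at n = 61 the empirical false-edge rate is
  5.1%.
* **No shrinkage estimator.**  The pipeline is covariance-input partial
  correlations with significance pruning; EBIC-lasso style regularization
  is a different estimator family and is deliberately out of scope.  An
  ill-conditioned covariance raises an error naming the most collinear
  pair; an optional ridge exists for exploration and announces itself.
* **Bonferroni family sizes** are not uniquely determined by the design;
  we default to the number of tests actually run (7 measures; 21
  comparison cells) and expose `m` everywhere.

## Centrality conventions

The distance behind betweenness and closeness is `d_ij = 1/|w_ij|`: a
strong conditional association is a short link.  This reciprocal metric is
the standard choice in weighted psychometric networks; `edge_lengths()` is
a separate step so another metric can be substituted.

* **Strength** sums *absolute* weights by default.  The raw signed sum is
  available (`absolute = FALSE`), but absolute weights keep strength
  non-negative when negative partial correlations are present, matching
  how reported strength values behave.
* **Geodesic ties** are counted within a 1e-9 relative tolerance; tied
  geodesics share betweenness credit fractionally (`p_jk(i)/p_jk`).
  Unreachable pairs contribute zero.
* **Closeness of disconnected nodes.**  The formula `(n−1)/Σ d_ij` over
  *all* other nodes gives 0 as soon as any peer is unreachable.  We
  implement this strict reading as the default and provide a
  within-component alternative (`disconnected = "component"`, i.e.
  `(n_c − 1)/Σ` over the node's component).  Reported closeness values for
  fragmented networks in the literature are convention-dependent (small
  positive values rather than exact zeros are common); neither convention
  is asserted as "the" published one, which is why the package's
  reproduction targets focus on strength and betweenness.
* Betweenness is bounded by `(p−1)(p−2)/2` (star centre attains it); the
  test suite checks both indices against brute-force enumeration of all
  simple paths on random graphs.

## The bootstrap and the z comparison

`bootstrap_centrality()` resamples participants with replacement (n
unchanged), re-runs the *entire* estimation per replicate, and records all
three indices.  One master seed spawns an independent RNG substream per
replicate, so results are reproducible and independent of execution order.
Replicates with a singular covariance are redrawn within their substream
and counted (more than 10% aborts); redraw counts land in the run
manifest.

`compare_groups()` computes `Δ = mean_ref − mean_other` per node × index.
Two denominators are offered:

* `"plain"`: `z = Δ / sqrt(sd_ref² + sd_other²)` — the conventional
  two-sample z on bootstrap SDs, the default for new analyses;
* `"scaled"`: the same divided by 10, equivalent to treating each SD as a
  standard error over 100 replicates.  This is the convention under which
  z statistics recomputed from published-style bootstrap mean/SD summary
  tables agree with their reported z values, so it is the variant used for
  reproduction; it is documented as a reverse-engineered convention, not a
  derivation.

The two variants differ by the constant factor 10, so ranking and signs
are identical.  Swapping reference and comparison groups negates every z
and leaves p-values unchanged.

## The synthetic generator

The raw study data behind this design are not public, so the package ships
a generator that *defines* the study conditions rather than estimating
them.  `structure_spec()` encodes a sparse set of partial correlations;
the standardized precision matrix with `K_ij = −rho_ij` reproduces them
exactly (positive definiteness is checked, infeasible edge sets are
rejected), and latent scores are multivariate Gaussian with the implied
correlation matrix, affinely rescaled to each measure's target mean/SD.

Two presets mirror the qualitative group contrast:

* **TD-like** (n = 61): a connected 6-edge tree, hubs `A_TOM` (partial
  correlations 0.40/0.35/0.30), `SSQ_EQ` and `ET`; `A_TOM` is the
  highest-strength node.
* **ASD-like** (n = 65): three weak edges (0.25–0.30), leaving four
  disconnected components and an isolated `SSQ_EQ`.

Weights of 0.25–0.40 were chosen once as realistic for psychometric
partial correlations: large enough to be detectable around n = 60 with
moderate power (≈ 0.69 per edge at n = 61, ≈ 1.0 at n = 500), small enough
that the precision matrix stays comfortably positive definite.  Marginal
means/SDs come from the reference group summary table
(`sc_measure_summaries()`).

What the generator does *not* emulate: integer/bounded scoring (scores are
continuous by default; rounding and truncation exist behind flags, and
out-of-range draws are reported rather than clamped so the correlation
structure is untouched), item-level response processes, floor/ceiling
effects (the TD `A_TOM` marginal, mean 12.67 and SD 0.51 against a 13-point
ceiling, is strongly censored in real data but Gaussian here), and
non-Gaussian tails.  Passing recovery tests therefore shows the estimator
is correct *under the model's own assumptions*, not that real scores meet
them.

## Numerical choices and degenerate inputs

* Shortest paths use Floyd–Warshall with geodesic counting; tie tolerance
  1e-9 relative.  The identity `σ_jk(i) = σ_ji σ_ik` when
  `d_ji + d_ik = d_jk` gives the through-counts.
* Covariance inversion goes through the Cholesky factor; condition number
  above 1e10 is an error, never silently regularized.
* Zero-variance columns raise `DegenerateColumn` at z-scoring; zero pooled
  variance with unequal means yields `F = Inf` with a warning; a zero
  combined bootstrap SD with a non-zero mean difference yields `z = ±Inf`
  with a warning (and `z = 0` when the difference is also zero).
* All seeds are 32-bit integers; derived substream seeds are drawn below
  2³¹.

## Validation problem sizes

The test suite validates centralities against exhaustive path enumeration
on 200 random graphs of 3–6 nodes; edge recovery at n = 500 over 20 seeds
(≥ 90% sensitivity for generating edges, ≤ 10% false edges at α = 0.05);
and the null calibration of the plain bootstrap z on 500 two-group
pipeline runs (n = 200 per group, B = 200, identical generating
structures), asserting a per-cell rejection fraction ≤ 0.10 — bootstrap-SD
z tests are conservative-to-nominal, so an upper bound rather than an
exact 5% is the defensible claim.  These sizes were chosen as the smallest
that make the stochastic assertions stable across seeds.

## Known limitations

* Two groups only; no >2-group designs, post-hoc contrasts or effect
  sizes in the ANOVA layer.
* Undirected GGMs only — no directed, mixed or regularized graphical
  models, and no missing-data estimation (validation rejects missing
  cells).
* No edge-weight difference tests or network-invariance permutation tests;
  the group comparison is centrality-based, as designed.
* The generator's presets are plausible stand-ins for an unknown
  population structure, not estimates of it.
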