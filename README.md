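# gfnet

Group comparison of structural and fast-oscillatory functional brain
connectomes, for researchers studying how whole-brain network organisation
relates to fluid intelligence (Gf) or any other two-group contrast.

The package covers the full chain:

1. **Connectome construction.** Structural networks from probabilistic
   tractography: the two tract directions are averaged and each connection is
   normalised by the mean size of the two parcels,
   `w_ab = ((c_ab + c_ba)/2) / ((s_a + s_b)/2)`. Functional networks from
   source-level MEG-like signals: zero-phase FIR band-pass (delta 0.1–2,
   theta 2–8, alpha 8–12, beta 12–32, gamma 32–75 Hz at 150 Hz), Hilbert
   amplitude envelope, Pearson correlation of envelopes.
2. **Graph measures.** Weighted degree (strength); Newman leading-eigenvector
   community detection with Kernighan–Lin refinement and its modularity `Q`;
   a node **segregation coefficient** (within-module strength / total
   strength, in [0, 1]); characteristic path length, global and local
   efficiency (reciprocal-weight Dijkstra lengths); density after removing
   the weakest 1% of edges.
3. **Inference.** Whole-brain Monte-Carlo permutation test on per-ROI
   median differences: the statistic is the pair of counts of ROIs whose
   median metric is higher/lower in the high group; 10,000 label
   permutations; tail p-values `p = (1 + #{perm >= obs}) / (n_perm + 1)`;
   Bonferroni levels 0.05/2 (structural), 0.05/10 (five bands x two tails).
   Modularity is tested against 1000 edge-shuffled null networks at the
   99.9% rule. Global measures and per-subject SC–FC similarity are compared
   by ANCOVA (group + sex factors, age + education covariates, type-II F,
   alpha 0.05/24). Group construction splits at the cohort mean Gf and
   reports the separation in standard-score SDs; a Welch t from summary
   statistics reproduces published group contrasts.
4. **Synthetic cohorts.** A first-class generator plants known module
   structure, group weight shifts and band-specific envelope correlations
   (lognormal envelopes on constant-amplitude FM carriers, with the exact
   lognormal moment mapping so population envelope correlations equal the
   target), plus WAIS-like Gf scores and demographics — so calibration and
   recovery are testable without any subject data.

## Worked example

A small synthetic cohort with a planted dissociation — the high group has
stronger alpha-band but weaker gamma-band envelope connectivity:

```r
library(gfnet)
spec <- cohort_spec(
  n_rois = 16, n_high = 7, n_avg = 7,
  partition_true = rep(1:4, each = 4),
  bands = canonical_bands(c("alpha", "gamma")),
  duration_s = 30, noise_sd = 0.2,
  fc_group_shift = c(alpha = 0.2, gamma = -0.08))

report <- run_pipeline(run_config("synthetic", spec = spec,
                                  n_perm_node = 1000,
                                  n_perm_modularity = 200, seed = 21))
report
#> <gf_run_report>
#>   cohort: 14 subjects (7 high / 7 average), separation 1.50 SDs
#>   Gf Welch t = 10.21 (df = 11.8)
#>   structural degree MCS: +5/-11 ROIs (p = 0.857 / 0.218); segregation MCS: +10/-6 (p = 0.305 / 0.808); Q = 0.290*
#>   alpha      degree MCS: +16/-0 ROIs (p = 0.198 / 1); segregation MCS: +2/-14 (p = 0.942 / 0.109); Q = 0.071*
#>   gamma      degree MCS: +0/-16 ROIs (p = 1 / 0.00799); segregation MCS: +6/-10 (p = 0.798 / 0.294); Q = 0.157*
```

Reading the output: every one of the 16 ROIs has a higher median alpha
degree in the high group (`+16/-0`) and a lower median gamma degree
(`+0/-16`) — the planted dissociation, mirrored in opposite count
asymmetries. The `*` after each `Q` marks modularity that beat the 99.9th
percentile of its edge-shuffle null. With only 7 + 7 subjects the count
p-values are limited by the permutation granularity; the full-size design
uses 10,000 permutations and the default cohort sizes (38 vs 31).

Reproducing a published group contrast from summary statistics alone:

```r
w <- welch_t_from_summary(117.72, 4.66, 38, 102.98, 6.09, 31)
#> t = 11.09, df = 55.3, p = 1.1e-15
```

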