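---
title: "Comparing structural and fast-oscillatory functional brain networks between fluid-intelligence groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing structural and fast-oscillatory functional brain networks between fluid-intelligence groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfnet)
```

## The scientific problem

Individual differences in fluid intelligence (Gf) — abstract reasoning,
working memory, processing speed — have repeatedly been associated with the
organisation of whole-brain networks.  `gfnet` implements a complete analysis
chain for comparing two cohorts (e.g. high-Gf versus average-Gf adults) on

* **structural connectivity (SC)**: weighted networks built from
  probabilistic-tractography streamline counts between the 90 non-cerebellar
  parcels of an anatomical atlas, and
* **functional connectivity (FC)**: weighted networks built from the Pearson
  correlations of band-limited amplitude envelopes of source-level MEG
  signals, in the five canonical bands (delta 0.1–2 Hz, theta 2–8 Hz, alpha
  8–12 Hz, beta 12–32 Hz, gamma 32–75 Hz) at a 150 Hz effective sampling
  rate.

Because subject-level neuroimaging data of this kind are rarely shareable,
the package also ships a synthetic-cohort generator with *known planted
structure*, so that every stage — connectome construction, graph metrics,
permutation inference — can be exercised, calibrated and regression-tested
end to end without any download.

## Connectome construction

**Structural.** Tractography estimates each ordered pair of regions
independently, so raw counts are asymmetric.  The network weight is

$$w_{ab} = \frac{(c_{ab} + c_{ba})/2}{(s_a + s_b)/2},$$

the direction-averaged count normalised by the mean voxel size of the two
parcels, so that large parcels are not credited with more connectivity merely
because they contain more seed voxels.  The result is symmetric, nonnegative,
with a zero diagonal.

**Functional.** Each region's signal is band-pass filtered with a zero-phase
(forward–backward) windowed-sinc FIR filter and the amplitude envelope is
taken as the magnitude of the analytic (Hilbert-transformed) signal; FC is
the Pearson correlation of envelopes over the whole recording.  Choices worth
knowing:

* *Filter family and order.*  A linear-phase FIR of order equal to three
  cycles of the band's low edge (configurable via `cycles`).  Zero-phase
  filtering means envelopes are not time-shifted against each other; an FIR
  remains stable even at the 0.1 Hz delta edge where IIR designs are fragile.
* *Edge handling.*  One filter length is discarded at each end before
  correlation (transient ringing is otherwise correlated across regions).
  A minimum duration of $30/f_{lo}$ seconds is enforced — 300 s for delta —
  because shorter recordings are mostly filter transient.
* *Nyquist capping.*  At 150 Hz the nominal gamma upper edge (75 Hz) sits
  exactly at Nyquist; all filters and generators cap the upper edge at
  0.95 × Nyquist (71.25 Hz).
* *No leakage correction.*  No orthogonalisation is applied before envelope
  correlation; the pipeline reproduces the plain envelope-correlation
  definition, and any beamforming leakage present in real source
  reconstructions is out of scope.
* *Negative correlations.*  Envelope correlations can be mildly negative, but
  modularity, segregation and reciprocal-weight path metrics are defined for
  nonnegative networks; the pipeline clips negative FC weights to zero before
  those metrics (the usual convention in envelope-correlation MEG work).

## Graph measures

* **Weighted degree (strength)**: row sums of the weight matrix.
* **Modularity and community structure**: Newman's leading-eigenvector
  method on the modularity matrix $B = W - kk^\top/2m$, with recursive
  bisection using the generalised modularity matrix for subgraphs, and a
  Kernighan–Lin single-node sweep after each split (on by default,
  `fine_tune = FALSE` for the strict spectral variant).  A split is accepted
  only if it increases $Q$; eigenvalues below $10^{-10}$ count as
  non-positive; eigenvector entries exactly zero go to the positive side.
  The single-module partition ($Q = 0$) is the fallback, so returned $Q$ is
  never negative.  Note that the refinement improves each *bisection*; on
  rare graphs the refined first split can steer the recursion to a final $Q$
  slightly below the strict-spectral one — both variants are exposed.
* **Segregation coefficient**: for each node, within-module strength divided
  by total strength, in $[0,1]$; 1 means fully intra-module, values near 0
  mark connector hubs.  Isolated nodes are undefined (`NA`) and are dropped
  listwise (with a record) by the permutation test.
* **Path metrics**: edge lengths are reciprocal weights, shortest paths by
  Dijkstra.  Characteristic path length averages over *finite* ordered pairs
  and reports the unreachable-pair count alongside, which keeps the measure
  well-defined on pruned or sparse synthetic networks.  Global efficiency is
  by default the mean inverse distance over ordered pairs (with $1/\infty =
  0$); the literal "inverse of the characteristic path length" is also
  exposed (`method = "inverse_cpl"`) because the two definitions circulate
  interchangeably in the applied literature even though they differ on
  irregular graphs — we default to the toolbox convention and document
  rather than resolve the discrepancy.
* **Density**: the weakest `ceiling(0.01 × E)` existing edges are removed
  (ties broken by stable node order; the ceiling guarantees at least one edge
  is removed whenever any exists), the rest binarised, and the fraction of
  possible edges reported.

## Statistical layer

**Group construction.** Subjects are split at the cohort mean Gf; the
separation of the resulting group means is reported in units of the
standardised test SD (15), with a warning — advisory, not fatal — below one
SD.  The split rule is deliberately simple and the reported separation makes
its adequacy auditable.  `welch_t_from_summary()` reproduces the published
group t-test from summary statistics alone.

**Whole-brain node-metric MCS.** The package deliberately does not test ROIs
one at a time.  The observed statistic is the pair of counts
$(n_{pos}, n_{neg})$ of ROIs whose median metric is higher (lower) in the
high group.  Group labels are permuted (10,000 times by default, group sizes
preserved) and each tail's p-value is

$$p = \frac{1 + \#\{\text{permuted count} \ge \text{observed count}\}}
  {n_{perm} + 1},$$

with Bonferroni-corrected levels 0.05/2 (structural: one network, two tails)
and 0.05/10 (functional: five bands × two tails).  Exact-zero median
differences count in neither tail.  The $\ge$ convention is the conservative
one that keeps the test valid under ties; a consequence worth understanding
is that the test is powered for *asymmetries* in the count pair, not for
uniform all-ROI effects: an effect so strong that every ROI moves saturates
the count at $n$, and permutations in which the majority of each true group
stays together reproduce the saturated count, so the p-value levels off
(at roughly the probability of a majority-preserving permutation) rather
than attaining the add-one floor.  Heterogeneous effects — the realistic
case — do not saturate.  Swapping the group labels swaps
$(n_{pos}, p_{pos})$ and $(n_{neg}, p_{neg})$ bit-exactly under the same
seed, which the tests verify.

A Bartlett test on the subjects' mean metric per group is run first as an
advisory variance-homogeneity check, mirroring standard practice.

**Modularity null.** Group-level community structure is computed on the mean
connectivity matrix; significance is assessed against 1000 networks obtained
by shuffling the upper-triangle weights uniformly at random (weight multiset
and symmetry preserved, diagonal zero) and recomputing $Q$; the observed
value must exceed the 99.9th percentile of the permuted values.  A
degree-preserving rewiring null is available (`null = "rewire"`) but the
weight shuffle is the default because it is the plain "connections placed
randomly" null.  For the segregation analysis the partition of the
grand-mean network is applied to every subject's network — a group-level
partition with subject-level metrics — so the permutation test's
exchangeability assumption is untouched by the partition choice.

**Global measures.** Characteristic path length, global and local
efficiency, and pruned density are compared between groups by ANCOVA
(`value ~ group + sex + age + education`, type-II F-tests, no interactions)
at 0.05/24: four measures across the five functional bands plus the
structural network make 24 comparisons.
Rank-deficient designs are rejected with the collinear columns named;
zero-residual fits are rejected as degenerate.

**SC–FC integration.** Per subject and band, the Pearson correlation between
the vectorised upper triangles of SC and FC is the modality-similarity
score; the scores enter the same ANCOVA.

## The synthetic-cohort generator

The generator's defaults are the emulated study's conditions: 90 ROIs in
five modules, groups of 38 and 31, Gf 117.72 ± 4.66 versus 102.98 ± 6.09
(WAIS-IV-like), ages and education years matching the published
demographics, five bands at 150 Hz, 600 s of signal.

* **Tractography**: streamline counts are zero-truncated normal draws,
  independent for the two directions of each pair, with mean equal to the
  planted weight times the mean parcel size (sizes uniform on 200–2000
  voxels, exercising the normalisation path).  Counts are kept continuous
  rather than integer-rounded so that the zero-noise case recovers the
  planted weights exactly; at realistic count magnitudes (hundreds) rounding
  would be statistically invisible anyway.  Group effects are additive weight
  shifts: `group_degree_shift` on all connections, `group_inter_shift` on
  inter-module connections only.
* **Band-limited signals**: each region is a strictly positive slow envelope
  times a constant-amplitude FM carrier — the cosine of an integrated random
  instantaneous frequency confined well inside the band.  Envelopes are
  exponentiated low-pass Gaussian processes (cutoff `min(1, lo/2)` Hz,
  log-scale SD 0.4 ≈ envelope CV 0.42, typical of MEG band envelopes); the
  Gaussian-process correlation is set through the exact lognormal moment
  mapping $\rho = \log(1 + r(e^{\sigma^2}-1))/\sigma^2$ so that the
  *population* Pearson correlation of the envelopes equals the requested
  target matrix.  The FM carrier matters: a band-pass-filtered unit-modulus
  carrier retains amplitude fluctuations that dilute recovered envelope
  correlations by 30–40%, whereas the FM construction keeps the carrier
  envelope constant to within a few percent, and (by Bedrosian's theorem)
  the Hilbert envelope of the product is the planted envelope.
* **What the generator does not emulate**: beamforming leakage and its
  spurious zero-lag correlations, 1/f spectra and band co-modulation,
  non-Gaussian tractography error, site or session effects.  Passing tests
  therefore demonstrate the *procedures* are correct and calibrated, not
  that real MEG/DTI data will show any particular effect.

Every generator is a pure function of its parameters and a seed; the
pipeline expands one master seed into per-stage, per-subject streams with a
counter-based scheme, so adding a stage never perturbs earlier stages'
randomness, and a cohort written to disk and read back reproduces the
in-memory analysis bit-exactly (matrices are serialised with 17 significant
digits).

## A small worked run

The problem sizes here are scaled down (16 ROIs, 7 + 7 subjects, two bands,
30 s) so the vignette and test suite stay fast; the same code runs the
full-size configuration unchanged.

```{r example, eval = FALSE}
spec <- cohort_spec(
  n_rois = 16, n_high = 7, n_avg = 7,
  partition_true = rep(1:4, each = 4),
  bands = canonical_bands(c("alpha", "gamma")),
  duration_s = 30, noise_sd = 0.2,
  fc_group_shift = c(alpha = 0.2, gamma = -0.08))

report <- run_pipeline(run_config("synthetic", spec = spec,
                                  n_perm_node = 1000,
                                  n_perm_modularity = 200, seed = 21))
summary(report)
```

The planted dissociation — high group stronger in alpha, weaker in gamma —
appears as opposite count asymmetries in the two bands' degree tests.

## Known limitations

* The count-pair MCS statistic has no power against perfectly uniform
  all-ROI effects (see above); this is a property of the statistic, not of
  the implementation.
* The leading-eigenvector method is a polynomial-time heuristic; on 8-node
  instances it is verified to reach the exhaustive optimum within 0.02, but
  no global guarantee exists for larger graphs.
* ANCOVA assumes the usual linear-model conditions; global graph measures
  on small pruned networks can be heavily tied, which the degenerate-design
  checks flag but cannot repair.
* Delta-band analyses need 300 s of signal by construction; shorter
  recordings are rejected rather than silently filtered.
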