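---
title: "Methods: epigenome-based profiling of kinase-inhibitor perturbations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenome-based profiling of kinase-inhibitor perturbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiperturb)
```

## The problem

Kinase inhibitors used in the clinic are polypharmacological: beyond their
intended target they engage off-target kinases with appreciable potency.
When a stimulus (e.g. LPS acting through TLR4 in macrophages) drives an
acetylation response (H3K27ac) at thousands of cis-regulatory elements
(CREs) with element-specific kinetics, pre-treatment with an inhibitor
perturbs that response at the subset of CREs wired — through kinases and the
transcription-factor programs they control — to the inhibited targets. A
time course of H3K27ac counts per CRE under each inhibitor, plus one vehicle
(DMSO) series, is therefore a functional fingerprint of the inhibitor.

`epiperturb` turns a collection of such per-condition CRE × time count
tables into:

1. normalized tables (invariant-feature scaling),
2. a joint low-dimensional representation across all conditions (MFA),
3. a signed, per-CRE, per-inhibitor perturbation-likelihood score and
   discrete up/down event calls,
4. inhibitor-level comparative statistics (proximity networks, target-family
   tests, kinetic-angle profiles, standardized Jaccard overlaps),
5. permutation association between affected CREs and TF peak sets, and
6. a weighted multi-class model predicting each CRE's perturbation direction
   from kinetic and TF-binding features, with directional feature
   importance.

A synthetic-data generator with machine-readable ground truth defines the
conditions under which every claim of the package is tested.

## Normalization by invariant features

Given a sample × feature count matrix, a pseudo-reference is built as the
per-feature median of `log2(count + pseudocount)` across samples
(pseudocount 1 by default; the reference construction is exposed because
reasonable variants exist). Each sample's vector of log2 differences from
the reference is modelled with a skew-normal distribution (location, scale,
shape) fitted by maximum likelihood with method-of-moments initialization;
if the skew fit fails to beat a plain normal fit it falls back to the normal
(shape 0). Features within `sigma` (default 1) fitted standard deviations of
the fitted *mean* are declared invariant, and the sample is rescaled so its
median ratio to the reference over its invariant set is 1.

Two grouping modes exist in `normalize_tables()`:

* **Within time point (default).** Samples sharing a time point are directly
  comparable: only the minority of perturbed CREs differ between an
  inhibitor and the vehicle at the same time. The pseudo-reference is built
  per time point.
* **Pooled (`group_by_time = FALSE`).** One cross-time reference. This is
  appropriate when the feature universe is dominated by features that do not
  respond to the stimulus (e.g. a full peak atlas of which only a fraction
  is stimulus-regulated). On a universe containing *only* regulated CREs,
  a cross-time reference absorbs kinetics into the scale factors and can
  erase perturbation signal, which is why it is not the default here.

The invariant-window strategy assumes a majority of unchanged features per
comparison; the tests verify recovery of known depth factors to within 5%
with up to ~25–30% truly changed features at screen-scale sample counts
(13 samples per group), and idempotence (refitting a normalized matrix moves
factors by < 1%).

## Multiple Factor Analysis

Tables are first standardized **by CRE**: each CRE row is centred and scaled
over the concatenation of all tables' columns (the `scale()` convention,
sample sd with n − 1; `joint = FALSE` standardizes within table instead —
the joint default reflects that all tables measure the same elements on the
same scale after normalization). Constant rows are dropped and reported.

Each standardized table is then weighted by the inverse of its first squared
singular value — equivalently, divided by its first singular value — so that
its first PCA eigenvalue is exactly 1 and every condition enters the joint
analysis on an equal footing regardless of its overall variance. The
weighted tables are concatenated and a global SVD taken (no further
centering: rows are already standardized; a config switch exists).
With `Z = U D V'` the *compromise factor scores* are `U D`; the *partial
factor scores* of table *k* are `K · Z_k V_k` (K tables), so the average of
the partial scores over tables equals the compromise exactly — the
barycenter identity, verified to 1e-8 in the tests. Dimension signs are
fixed by making the largest-magnitude loading of each dimension positive, so
outputs are deterministic under fixed input ordering.

**Dimension selection.** Values are permuted independently within every
column of every table, the full analysis is refit (row re-standardization,
table weights, SVD) and the per-dimension eigenvalue recorded. The
permutation p-value is `(1 + #{perm ≥ obs}) / (1 + n_perm)`; dimensions with
p below `alpha` (default 0.01, 500 permutations) are retained. Two numerical
details matter: the refit must re-standardize rows (the observed matrix
satisfies exact row constraints that a permuted matrix does not; omitting
the re-standardization makes selection anticonservative on pure noise), and
dimensions beyond the numerical rank are excluded (their ~0 eigenvalues
compare meaninglessly against the null). On pure-noise fixtures the mean
number of selected dimensions at `alpha = 0.01` is below 1.

## Perturbation-likelihood score

For each CRE and inhibitor, the Euclidean distance between the inhibitor's
and the vehicle's partial factor scores over the selected dimensions
measures how differently that element behaved under the inhibitor,
integrated over the whole time course. The natural logs of all
CRE × inhibitor distances for a stimulus are pooled and a normal
distribution fitted by maximum likelihood (`fitdistrplus`); each distance is
converted to its upper-tail probability (CCDF), floored at `10^-clamp`
(default 300 decades) to keep scores finite, with zero distances replaced by
10^-3 times the smallest positive distance before the log.

The direction comes from **delta z**: the sum over all time points
(including t = 0) of the inhibitor's standardized values minus the
vehicle's, per CRE. The final score is

&nbsp;&nbsp;&nbsp;&nbsp;`score = -log10(ccdf) · sign(delta_z)`, `0` when `delta_z = 0`.

Events are called at `|score| > 1` by default (tail probability below 0.1 in
the called direction). The null fit is pooled across **all** inhibitors
rather than per inhibitor: a per-inhibitor null would equalize call counts
across inhibitors by construction, whereas the pooled null lets inhibitors
with larger genuine effect budgets produce more calls — the behaviour a
screen needs. The score uses all selected dimensions by default (a switch
restricts it, since reasonable analyses might use only the first two).

On the null generator (`effect_scale = 0`) the call rate at threshold 1
stays within the nominal 0.1 tail. On the default wired fixture, ranking
cells by `|score|` separates perturbed from unperturbed (CRE, inhibitor)
pairs with AUROC ≥ 0.9, and mean `|score|` per program × inhibitor group is
strongly monotone in the group's injected effect. The *cell-level* rank
correlation between `|score|` and the latent injected effect is, however,
intrinsically limited at realistic count noise: within a program all member
CREs carry the same latent effect, so their score spread is pure noise, and
a CRE's own perturbations inflate its row sd under joint standardization
(13 tables at this scale versus ~60 in a full screen), compressing z-scores
program-wise. Even in the noise-free limit the global cell-level Spearman
tops out near 0.78 on this fixture; group-level monotonicity is the
noise-robust formulation and is what the unit tests assert.

## Comparative statistics

* **Proximity.** PCA of the inhibitor × CRE signed-score matrix; components
  selected by the same within-column permutation scheme; Euclidean distances
  in the selected-component space; each inhibitor connected to its 3 nearest
  neighbours (ties broken lexicographically for determinism); Ward
  (`ward.D2`) dendrogram on the same distances (a switch to graph distances
  exists for the network reading of the clustering).
* **Family test.** Mean pairwise distance among inhibitors sharing a target
  family versus a label-shuffle null,
  `p = (1 + #{null ≤ obs}) / (1 + n_shuffle)`, with a Kruskal–Wallis rank
  test of within- versus between-family distances reported alongside.
* **Kinetic angles.** Each CRE's (dim 1, dim 2) compromise coordinates map
  to an angle in [0, 360) (atan2); affected CREs are binned in 5° bins (72
  bins) per direction and min-max scaled to [0, 1]. Because the first two
  dimensions encode response kinetics, CREs of one kinetic cluster occupy a
  coherent angular sector.
* **Overlap.** The Jaccard index of two affected-CRE sets is standardized
  against a null of same-size uniform draws (without replacement, 1000
  iterations) from the CRE universe: `SES = (J − mean) / sd`. This corrects
  for set sizes; the tests verify the null mean against the exact
  hypergeometric enumeration.
* **Cross-readout comparison.** Spearman correlation between two pairwise
  distance tables over the same inhibitor pairs, plus the distribution of
  the second readout within quintiles of the first (ties broken by pair id;
  quintile sizes differ by at most one).

## TF-peak association

A CRE counts as overlapped by a peak set when any peak shares ≥ 1 bp
(0-based half-open on disk, converted to the 1-based closed `GRanges`
convention in memory). For each TF × inhibitor × direction, the number of
peak-bearing CREs among the affected set is compared with `n_perm` (default
5000) uniform same-size resamples from the CRE universe:
`z = (obs − null_mean) / null_sd`, two-sided empirical p with +1 smoothing,
Benjamini–Hochberg correction across all tests of the invocation. Resampling
is by CRE identity from the fixed catalogue rather than by random genomic
regions: the universe of interest *is* the catalogue, and identity
resampling makes the null exactly hypergeometric (which the tests check).
Both over- and under-representation are reported (two-sided).

## Direction classifier

Features are extracted by MFA over source tables grouped by assay (kinetic
time courses, TF peak presence/signal), keeping dimensions holding at least
1% of the variance. Components are described by their correlation with each
source column and, for categorical sources, by the group-mean standardized
statistic `v = (x̄_g − x̄) / sqrt(((N − n_g)/(N − 1)) · s²/n_g)` — the
standard v-test reading, adopted because the exact formula is a genuinely
open choice.

Class imbalance (most CREs unaffected) is handled with the custom weights

&nbsp;&nbsp;&nbsp;&nbsp;`w0 = n/(2 n0)`, `w_eff = n/(2 (n − n0))`,
`w_u = n_u/(n_d + n_u) · w_eff`, `w_d = n_d/(n_d + n_u) · w_eff`,

scaled to sum to 1. Within changing observations the larger class gets the
larger weight. Per-observation weights are rescaled to mean 1 before
fitting, so that absolute-scale tree knobs (`min_child_weight`) keep their
usual meaning; the class ratios, which are what the loss sees, are
unchanged.

Training uses a stratified 70/30 split, gradient-boosted trees
(multi-class softprob) with a small grid — depth {3, 6}, learning rate
{0.05, 0.1}, rounds {100, 300} — selected by 3-fold stratified
cross-validation on balanced accuracy (mean per-class recall). The backend
is pluggable (any function returning a probability-matrix predictor), and
evaluation reports one-vs-rest ROC-AUC and PR-AUC per class on the held-out
set. Attributions come from the tree-path (SHAP) contributions of the
fitted booster; **directional importance** is, per class, the mean absolute
attribution per feature min-max scaled to [0, 1] across features, times the
sign of the correlation between feature value and attribution. Its signs
and rankings are verified in the tests against brute-force exact Shapley
values (enumeration over all coalitions with marginal expectations) on
small additive models.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes:

* **Kinetics.** Four templates peaking at 0.5, 1, 2 and 4 h over the
  {0, 0.5, 1, 2, 4} h grid (configurable), each a log-time Gaussian bump of
  1.5 natural-log units above a common baseline of `log(50)`; with the
  default depth multiplier 4 this puts resting counts near 200 and peak
  counts near 900 per CRE — deep, high-quality ChIP-seq territory.
* **Wiring.** Kinases drive TF programs; each program owns a disjoint CRE
  subset (60% of the universe covered by default); inhibitors receive one
  intended target (potency U(0.7, 1)) round-robin over the wired kinases —
  so target families arise naturally — plus Binomial(n_kinases − 1, 0.1)
  off-targets with potency U(0.2, 0.8), reflecting that off-target
  engagement of clinical kinase inhibitors is often comparable to on-target.
* **Effects.** For a CRE in program *p* and inhibitor *X*,
  `effect = direction_p · effect_scale · Σ potency(X, kinase_p)`, applied to
  the log-mean at the CRE's *induced* time points (at least half-maximal
  induction). 20% of programs are up-regulatory (`up_frac`), the rest
  down — perturbation of stimulus-induced acetylation is predominantly a
  loss. `effect_scale = 1` means full inhibition costs one natural-log unit
  (~e-fold) of induced signal.
* **Noise.** Negative-binomial counts (dispersion 50 by default; the
  NB → Poisson limit is tested) with per-sample log-normal(0, 0.15) depth
  multipliers so normalization has real work to do.
* **Annotations.** Each program's TF carries a 200-bp central peak on member
  CREs with probability 1 − fnr and on non-members with probability fpr.

What the fixture does **not** emulate: replicate structure (the design is
replicate-free, as screens of this size are), fragment-level read placement,
GC/mappability bias, peak-boundary uncertainty, correlated off-target
spectra, and amplitude-only (proportional) inhibition — a purely
multiplicative attenuation of the induced component is largely absorbed by
row standardization and is deliberately not the default effect model, so
passing tests say nothing about that regime. Truth is recorded per
(CRE, inhibitor) pair with signed effect sizes, cluster assignments and the
depth multipliers actually drawn.

## Problem sizes and numerical choices

The test suite runs the full analysis at 2,000 CREs × 12 inhibitors
(the package's reference fixture), recovery studies at 400–800 CREs over 20
seeded replicates, and permutation calibration at 10 tables × 500 CREs × 5
time points with 500 permutations — sizes chosen so the whole suite and the
end-to-end pipeline each complete in a few minutes on a single core while
keeping every statistical check adequately powered. Degenerate inputs have
defined behaviour throughout: constant CRE rows are dropped with a report,
zero tables and zero-sd distance pools are errors, empty invariant sets
instruct a wider sigma window, zero-spread nulls flag `SES = 0` /
`z = 0, p = 1`, and zero distances are floored before logs. All RNG flows
through explicit seeds and every stage records them; the pipeline manifest
checksums its outputs, and rerunning a configuration reproduces them
byte-identically.
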