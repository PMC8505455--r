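---
title: "Methods: neurosemantic factor analysis and decoding of concept-evoked fMRI activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neurosemantic factor analysis and decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

When a trained physicist thinks about *torque* or *dark matter*, the
evoked fMRI activation pattern is not arbitrary: across stimulus
repetitions and across people, concept-evoked patterns are organized along
a small number of latent semantic dimensions (measurability of a
magnitude, association with a mathematical formulation, periodicity, and a
classical-versus-post-classical contrast, plus a nuisance dimension driven
by the visual length of the printed word). `neurosem` implements the full
analysis chain used to establish and exploit that organization:

1. **Stable-voxel selection** — a voxel is useful only if its tuning curve
   over the 45 concepts replicates across presentations. Stability is the
   mean pairwise Pearson correlation between the voxel's concept-activation
   profiles across all presentation pairs of the training data.
2. **Two-level exploratory factor analysis** — per participant and lobe, a
   factor analysis of the correlation matrix of the 120 most stable voxels'
   profiles; then a group-level factor analysis of the pooled individual
   factor scores, which finds the dimensions common across lobes and
   participants. Voxels are mapped back onto factors by thresholded
   absolute loadings and spatially clustered.
3. **Concept decoding** — Gaussian naive Bayes (GNB) classification of the
   45 concepts within and across participants, scored by normalized rank
   accuracy with permutation tests.
4. **A forward (encoding) model** — ordinary least squares from mean expert
   ratings of each concept on the four semantic dimensions to the mean
   activation of the factor clusters, evaluated by leave-one-concept-out
   prediction (squared correlation `R^2` and correlation-distance rank
   accuracy).
5. **Group discrimination** — expert-versus-novice classification on the
   shared elementary concepts, with a reiterative stepwise search for the
   most discriminating concepts.

Because the human fMRI data behind these analyses are not openly
distributable, the package ships a first-class synthetic-data generator
with known ground truth; every pipeline stage is validated against planted
structure.

## The generative model behind the synthetic data

`sample_ground_truth()` draws, for `C` concepts and `D` latent dimensions:

* **concept scores** `S` (`C x D`), each column z-scored. The
  `word_length` nuisance column is the z-scored character count of the
  concept label; when the concept table carries classical/post-classical
  tags, the `classical_postclassical` column is (a lightly jittered)
  z-scored binary contrast, making the category signal a planted binary
  dimension.
* **voxel loadings** `L` (`V x D`), nonzero only inside planted clusters:
  face-connected voxel sets grown inside a single lobe, with per-voxel
  magnitudes drawn from U(0.6, 1.0) and a common sign per cluster.
  Semantic dimensions cycle over the three non-occipital lobes (so each
  dimension is expressed in several lobes, which is what lets the
  group-level analysis find it as a common factor); `word_length` clusters
  are planted only in the occipital partition.

A participant's tensor is

```
psc[c, p, v] = sum_d S[c, d] * (L[v, d] + E[v, d]) + N(0, noise_sd)
```

with `E` a participant-specific N(0, `participant_sd`) perturbation of the
nonzero loadings, and independent Gaussian presentation noise. Ratings are
generated per rater as `round(4 + 1.5 * z + N(0, rater_noise_sd))` clipped
to 1..7 (so ±2 sd of the latent score map to the scale endpoints — the
scale's semantics fix only the endpoints, so a linear map with saturation
is the minimal choice), then averaged over raters.

**Default conditions.** 45 concepts x 6 presentations, 10 faculty + 9
students, a 12 x 12 x 8 grid (1,152 voxels; the smallest desk-scale grid
whose octant lobes comfortably hold 120 candidate voxels each) with
3.125 x 3.125 x 6 mm voxels, 3 clusters per dimension with 3–9 voxels,
`noise_sd = 0.1` and `participant_sd = 0.1` (one tenth of the typical
loading magnitude), and one relocated cluster per semantic dimension in
the student group. Trial-level noise magnitudes are not published for the
original data, so these defaults are calibrated only to reproduce the
qualitative regimes: near-ceiling decoding at low noise, exact chance at
pure noise. Consequently the decoding and group-classification accuracies
that the pipeline reports on synthetic data sit near ceiling and are not
estimates of the values attainable on real recordings.

**What the generator does not emulate:** hemodynamic convolution, scanner
noise spectra, motion, spatial autocorrelation of noise, and
participant-specific anatomy (a single shared geometry stands in for
post-normalization voxel correspondence). Passing tests therefore
demonstrate correctness of the algorithms under the assumed low-rank
model, not robustness to acquisition artifacts.

All randomness flows from one integer seed through a counter-based
splitting hash, so participant `i` is bit-reproducible independently of
cohort size and across platforms.

## Numerical and statistical choices

* **Factor extraction** is single-pass principal-axis factoring: squared
  multiple correlations (SMC) on the diagonal, eigendecomposition of the
  reduced matrix, no communality iteration. A `method = "pca"` flag is
  available. With more variables than observations (120 voxels, 45
  concepts) the correlation matrix is singular; the SMC computation then
  uses a small ridge (`1e-6` of the mean diagonal), the priors saturate
  near 1, and extraction approaches principal components — this is
  reported via a message and is the expected regime for the per-lobe
  analyses. Eigenvalues below `1e-10` of the leading one produce zero
  loading columns with a warning.
* **Varimax** uses Kaiser row normalization and a `1e-8` criterion
  tolerance; column signs are fixed so each column's largest-|loading|
  entry is positive, making rotations reproducible. Rows with zero
  communality and all-zero columns are passed through untouched.
* **Factor scores** use the regression (Thurstone) estimator
  `Z R^{-1} L`, with the same ridge fallback for singular `R`. The
  estimator is not prescribed by the protocol; the regression method is
  the common default and is exact in the noiseless limit.
* **Group-level factor retention** keeps factors whose sum of squared
  loadings (eigenvalue, in units of one standardized input column) is at
  least `variance_threshold = 1` — the Kaiser rule. A threshold
  proportional to the total input variance was considered and rejected:
  with ~120 input columns it cannot simultaneously retain the word-length
  factor (3 supporting columns) and reject pure-noise residual factors in
  the small secondary analysis, whereas the eigenvalue-unit rule does both
  and is scale-free in the number of inputs. Spurious factors that pass
  the rule are harmless downstream: planted-structure validation matches
  factors to dimensions greedily by |r|, and an uninterpretable surplus
  factor is an expected outcome of exploratory FA.
* **Clustering** uses 6-connectivity (face adjacency) by default, with
  26-connectivity behind a flag; minimum cluster size 2; centroids are
  means of member mm coordinates; clusters are ordered by factor and
  smallest member index so results are invariant to voxel enumeration
  order.
* **GNB** uses pooled within-class variance by default (with 4 exemplars
  per class a per-class variance is far too noisy; a `per_class` option
  exists), uniform priors, and a variance floor of `1e-6` of the feature's
  overall variance (absolute floor `1e-12`) so constant features never
  divide by zero.
* **Rank accuracy** is `(n - rank) / (n - 1)` with tied ranks averaged,
  giving an exact chance mean of 0.5 under uniformly random orderings.
* **Cross-validation** uses all `choose(6, 2) = 15` two-presentation test
  folds by default (a disjoint-pairs scheme is available); stability and
  feature selection are recomputed inside every fold from training data
  only. Top-`n` selections break ties by ascending voxel index. Whether
  the 120 decoding features should be selected whole-brain or per lobe is
  ambiguous in the protocol; whole-brain is the default, per-region
  selection is available via `select_stable_voxels(..., lobe = )`.
* **Permutation tests** shuffle concept labels independently per
  presentation (a coherent shuffle of the whole tensor would merely
  relabel classes and leave accuracy unchanged) and report the add-one
  p-value `(1 + #{perm >= obs}) / (1 + n_perm)`, which is never zero.
* **Forward model**: independent OLS per cluster with intercept; cluster
  features average the `n_voxels = 5` most stable voxels inside a cuboid
  of half-width `cuboid_radius = 1` (3 x 3 x 3; the cuboid size is not
  stated in the protocol and 1 is the smallest neighborhood that can
  complete an irregular cluster) around the centroid; clusters smaller
  than 5 voxels are excluded. `R^2` is the squared Pearson correlation
  between predicted and observed cluster vectors — scale-free, hence
  invariant to affine miscalibration of the prediction.
* **Group comparison**: cluster replication across participants is judged
  by same factor identity and centroid distance of at most one voxel per
  axis (the published criterion is qualitative); features are top-6 stable
  voxels per cluster on the 15 shared concepts. The stepwise concept
  search implements the quoted rule exactly — survivors are extensions at
  least as accurate as the previous iteration's best, stopping when every
  extension strictly decreases accuracy — with an optional deterministic
  beam cap (`beam_width`), because on cleanly separable synthetic data
  ties at accuracy 1.0 otherwise make the exact rule combinatorial. The
  pipeline default is a beam of 10; oracle tests run the exact rule.
* **Factor alignment** across solutions is greedy maximum-|r| matching of
  factor-score columns (the qualitative description of the original
  alignment); an exhaustive permutation check in the tests confirms the
  greedy matching on small problems.

## Pipeline protocol

`run_pipeline(run_config(...))` chains the stages with the protocol's
parameter defaults (120 voxels per lobe, 10 individual factors, 0.4
loading threshold, minimum cluster size 2, 5- and 6-voxel cluster means,
≥4-participant replication): within-participant decoding picks the 3 most
accurately classified faculty members; their data feed the two-level FA;
retained factors are matched to the rated dimensions; the forward model is
fit on the grand mean of the remaining 7 faculty datasets; the group
comparison runs separate per-group factor analyses on the 15 shared
elementary concepts, aligns them, unions the replicated clusters and
classifies group membership leave-one-participant-out.

Problem sizes were chosen so the full default pipeline completes in about
a minute on one CPU: the permutation stage uses 99 permutations of the
best participant under the disjoint-fold scheme, and the test suite runs
its planted-recovery checks on a 144-voxel grid with 20 concepts except
for the full-scale two-level FA check, which uses the default 1,152-voxel
cohort.

## Known limitations

* The two-level FA depends on the planted dimensions being expressed in
  more than one lobe; a dimension confined to a single lobe in a single
  participant may fall below the retention rule.
* With `p >> n`, factor scores from the ridge-regularized regression
  estimator are shrunk; validation uses correlations, which are invariant
  to that shrinkage.
* The stepwise search is a heuristic; its equivalence to exhaustive search
  is guaranteed only on the small problems where the tests verify it.
* Bundles store tensors as text for portability; they are
  bit-exact but large for big cohorts.
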