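---
title: "Methods: co-alteration networks, spin nulls, and gradient decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-alteration networks, spin nulls, and gradient decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalt)
```

# The model

`coalt` treats parcel-wise case–control effect sizes (Cohen's *d* of
cortical thickness) for several disorders as a parcels × disorders matrix
and asks how illness effects covary across the cortex. The analysis chain
is:

1. **Co-alteration matrix.** For parcels *i*, *j*, the entry is the Pearson
   correlation between their disorder-wise effect profiles. With six
   disorders each correlation rests on six observations; the matrix is
   therefore noisy by construction and all downstream inference is
   explicitly spatial (spin tests), never parametric on these correlations.
   A weighted variant (weights ∝ per-disorder total sample size, via
   `cov.wt`) is available for sample-size robustness checks and is off by
   default.

2. **Hubs and hit map.** Hubs are parcels with many strong co-alteration
   connections: the matrix is thresholded (by default globally, keeping the
   top 20% of upper-triangle entries by signed value) and degree centrality
   is the *weighted sum* of retained edges. A binary edge count is exposed
   as an option; both modes are tested against a brute-force recount.
   "Strong" is read on the signed scale, so strong negative correlations are
   dropped rather than counted — configurable at the call site by
   pre-transforming the matrix. The hit map z-scores each disorder map
   across parcels and sums them; z-scoring is the minimal normalization that
   makes disorders with different effect-size scales commensurable. Signed
   sub-maps (`part = "reductions"` / `"increases"`) zero the other sign
   before z-scoring.

3. **Epicenters.** A seed region (68 cortical parcels, 14 subcortical
   structures) is a candidate disease epicenter when its normative
   connectivity profile correlates with the hub map. For cortical seeds the
   self-entry is excluded from both vectors (the diagonal is undefined and
   would inflate the correlation). The spun object is always the hub map:
   only cortical maps have spherical coordinates, and spinning one side
   keeps a single null for all 82 seeds. No multiple-comparison correction
   is applied across seeds by default (an FDR option exists); ranks are
   assigned among significant seeds by descending r with deterministic
   label-order tie-breaks.

4. **Gradients.** The co-alteration matrix is row-thresholded (top 20% per
   row — the embedding-toolbox convention, deliberately different from the
   global scope used for hubs), converted to a normalized-angle affinity
   `1 − arccos(cosine)/π`, and decomposed by diffusion map embedding:
   `W' = D^−α W D^−α` with α = 0.5 (density influence halved; robust to
   noise while retaining global relations), row-normalized to a Markov
   operator, eigendecomposed, trivial stationary component dropped, and
   eigenvectors scaled by λ/(1−λ) (the diffusion-time-zero rule of the
   reference implementations; plain eigenvectors are an option). Variance
   explained is reported as λ_k over the sum of the *retained* non-trivial
   eigenvalues (negative eigenvalues clipped at zero); the denominator
   convention is documented here because reference tools differ and the
   choice rescales all fractions by a common factor.

5. **Contextualization.** Gradients are stratified by the five von
   Economo-Koskinas cytoarchitectonic classes (descriptive only); term maps
   are decoded by averaging each term's parcel z-values within 20
   five-percentile gradient bins and ordering terms by their
   center of gravity (positive-part weights — negative associations would
   otherwise push centers outside the bin range); gene expression maps are
   correlated with a gradient, screened by a two-sided spin p < 0.01 spatial
   null, and the resulting candidate set is tested against (i) equal-size
   gene sets matched on mean absolute coexpression via decile histograms and
   (ii) equal-size sets drawn from brain-expressed genes only.

6. **Disorder embedding.** Each disorder is positioned by its map's
   correlation with the hub map, the percent overlap of its own significant
   epicenters with the transdiagnostic ones (denominator = transdiagnostic
   set size; Jaccard would double-penalize disorders with many specific
   epicenters), and its correlations with G1/G2. Within-disorder covariance
   uses negated absolute differences −|d_i − d_j|; because the coupling map
   correlates rows, any monotone "inversion" convention gives the same
   result up to sign, and negation is the simplest. Disorder similarity uses
   average-linkage hierarchical clustering on 1 − r (complete linkage as
   option) with deterministic cluster relabeling by smallest member index.

# Spin permutation machinery

All spatial p-values come from one engine: uniform random 3D rotations are
applied to left-hemisphere centroids and their x-mirrored counterparts to
the right hemisphere, and each parcel takes the value of the nearest
original centroid of its hemisphere (great-circle distance, duplicates
allowed, no rejection). The add-one estimator
`p = (1 + #qualifying)/(1 + n_spins)` is used everywhere, so p = 0 cannot
occur. The default ensemble size is 1000; bounds such as p < 10⁻⁴ require
10000 spins.

Two empirical properties, measured by the test suite, bound what these
p-values mean:

- A continuum rotation (re-evaluating a smooth field at rotated
  coordinates) is calibrated at the nominal level. The discrete
  nearest-centroid reassignment attenuates null correlations slightly
  (surrogate maps lose roughly a fifth of their Moran-type autocorrelation
  on a 68-parcel lattice), so the realized type-I error at α = 0.05 sits
  near 0.065 rather than 0.050 — the known mild anticonservatism of
  non-bijective parcel-level spins. Users needing strict level control
  should interpret p-values near the threshold cautiously or raise the
  ensemble size and lower α.
- Because rotations are mirrored across hemispheres, the null preserves
  *homotopic* structure. Maps whose autocorrelation crosses the midline
  without mirror symmetry are not in the null's invariance class and are
  tested slightly more liberally; the synthetic generator therefore builds
  bilaterally symmetric autocorrelation (below), which is also what
  meta-analytic cortical maps look like.

# What the synthetic generator emulates

`sim_config()` defaults define the study conditions exercised everywhere:

- **Atlas**: 34 parcels per hemisphere on a deterministic Fibonacci lattice
  over each half-sphere, right hemisphere mirrored from left;
  cytoarchitectonic classes assigned by inferior–superior latitude
  quintiles.
- **Effects**: each disorder map is a loading-weighted sum of three fixed
  smooth latent patterns (anterior–posterior, inferior–superior,
  medial–lateral harmonics of the centroid coordinates) plus spatially
  autocorrelated noise (angular kernel, length scale 0.4 rad, residual SD
  0.5 in Cohen's d units — the scale of the between-parcel spread of real
  meta-analytic maps). Three disorders (BD-, OCD-, SCZ-like) share latent 1
  with loadings 1.1–0.8; the remaining disorders load 0.5 on distinct
  latents. Cross-disorder correlation sees only the loading *variance*
  across disorders, so a shared mean pattern alone produces no
  co-alteration; the defaults make latent 1 dominate, giving a first
  gradient near 30% variance explained and a second near 20%. An optional
  binarized latent (`latent1_binary = TRUE`) plants an exact two-block
  structure for block-recovery validation.
- **Noise kernel**: geodesic plus homotopic (x-mirrored) proximity, so
  fields are smooth within hemispheres and correlated between homotopic
  parcels — matching both real cortical maps and the spin null's invariance
  class.
- **Connectome**: a distance-modulated multiplicative degree model whose row
  sums track the target hub map, with two cortical and two subcortical
  planted epicenter seeds whose profiles are the hub map plus noise
  (relative SD 0.2).
- **Annotations**: 24 term maps whose peaks march monotonically along the
  target gradient; 500 genes of which 20 correlate with the gradient at
  r ≈ 0.8 and the rest are autocorrelated noise, with brain-expressed flags.

What it does **not** emulate: site effects, subject-level sampling noise,
non-stationary smoothness, the lognormal weight distribution of real
connectomes, realistic gene–gene coexpression modules (coexpression arises
only through shared smoothness), or any planted hub–hit-map alignment. On
the last point: the planted latents are sign-symmetric, so the hub map
(even in the latent) is nearly orthogonal to the hit map and to individual
disorder maps (odd in the latent); the pipeline reports these correlations
but the generator makes no claim about their size, unlike real data where
consistent thickness reductions align with covariance hubs. Passing tests
therefore demonstrate recovery of *planted* structure and honest
calibration, not real-data effect sizes.

# Numerical choices and edge cases

- Thresholding ties are broken by value, then lower label index; retained
  counts use the ceiling. Re-thresholding a thresholded matrix at the same
  sparsity is a fixed point when retained edges are positive (zeros outrank
  retained negative edges otherwise).
- The dense symmetric eigensolver is exact at n = 68; no iterative solver is
  used. Adjacent eigenvalue gaps below 1e-10 are flagged as degenerate.
  Component signs are arbitrary in theory and fixed in practice by a sign
  anchor (pipeline default: the x-centroid axis); without an anchor the
  largest-magnitude entry is made positive.
- Gradient bins are rank-based; tied values share the lower bin; binning is
  invariant to monotone transforms.
- Missing values propagate pairwise-complete through correlations; any map
  with more than 10% missing parcels aborts the stage. Constant profiles
  yield NA correlations with a warning rather than an error.
- Leave-one-disorder-out stability compares G1 (and G2) with sign
  alignment. With six disorders the first two eigenvalues can sit close
  together, and dropping a disorder that anchors the dominant latent can
  rotate the near-degenerate pair; calibration over 30 generator seeds shows
  the per-seed *median* |r| across exclusions always above 0.8 while single
  exclusions can fall much lower. The tests assert the median property;
  treating a single low exclusion as instability of the method would
  misread eigenvector rotation as signal loss.
- Per-gene spatial screening at r ≈ 0.8 against smooth bilaterally
  symmetric nulls detects an individual planted gene only 50–70% of the
  time at p < 0.01 — the spatial null is doing its job, since smooth maps
  correlate strongly by chance. Recovery is therefore assessed at the set
  level: planted genes enter the candidate set at ≥ 25-fold the null rate
  and the set passes both gene-specificity nulls.

# Problem sizes used by the tests

The suite runs the full 68-parcel pipeline throughout; replicated checks
use 1000-spin ensembles with 2500 replicates for spin calibration, 50
generator seeds for epicenter recovery, 100 for cluster recovery, 10–20 for
block recovery, gene calibration and gene recovery, and 50 random 20×20
affinities for the eigen-oracle comparison. The whole suite completes in
well under a minute on one core; `scripts/acceptance.R` in a few seconds.

# Known limitations

Spin tests are defined on the cortical sphere only; subcortical seed
profiles are never spun (the hub-map side of each correlation is). The
coexpression-matched null reproduces the *idea* of coexpression-level
matching via decile histograms, not any external tool's exact algorithm.
Developmental enrichment of candidate gene sets is out of scope; the
candidate list is exported for external tools. Variance-explained fractions
depend on the retained-spectrum denominator convention documented above
when compared across software.
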