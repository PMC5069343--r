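---
title: "Statistical parametric mapping of bodily sensation drawings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical parametric mapping of bodily sensation drawings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsmap)
```

## The problem

In bodily sensation mapping (BSM) experiments, participants draw where on
their body they feel something — for instance the composite needling
sensation (*DeQi*: numbness, heaviness, spreading, pricking, ...) evoked by
acupuncture or by a matched tactile control at defined acupoints (HT7, PC6,
ST36, SP10). Each drawing is an intensity image on a fixed two-view
(front/back) human body template, and a study yields one baseline drawing
plus one drawing per stimulation condition for each subject, together with
an ordinal 13-item sensation questionnaire (each item scored 0–3).

Two statistical questions follow:

1. **Where** on the body does a condition produce sensations beyond chance
   (and beyond the non-specific baseline pattern, e.g. the bilateral palm
   sensations that appear whenever people attend to their body)?
2. **How strongly** do the questionnaire items differ by stimulus type and
   stimulus location?

`bsmap` answers the first with mask-restricted pixel-wise t-statistics plus
a Monte-Carlo cluster-extent correction, and the second with item-wise
two-way ANOVA under a Bonferroni family correction. Everything is validated
on synthetic studies with known planted effects, because raw drawings from
published studies are generally not deposited.

## The mapping pipeline

For one condition with \(n\) subjects the pipeline is:

1. **Unit-range normalization** of each session drawing: divide by the
   in-mask maximum, so values span \([0,1]\). Unmarked pixels are 0, so the
   minimum needs no shifting; dividing by the maximum is the convention that
   keeps unmarked skin at exactly 0 and makes the step idempotent and
   scale-invariant (it also absorbs any per-subject "marking vigor" gain).
2. Optional **baseline subtraction**: the subject's normalized baseline map
   is subtracted pixel-wise from the normalized stimulation map. Differences
   keep their sign — truncating at zero would silently discard information
   about baseline-dominant regions; one-sided selection is deferred to the
   cluster-extraction stage.
3. **Pixel-wise one-sample t-test** within the body mask against a null
   mean of 0 (a random-effects group analysis; the paired comparison of two
   sessions reduces to the one-sample test on differences, df \(= n-1\)).
   Pixels with zero variance across subjects — typically: nobody marked
   anything there — are flagged *invalid* and excluded rather than set to
   \(t = 0\), since 0/0 is undefined; this mirrors the usual treatment of
   degenerate voxels in neuroimaging.
4. **t → Z transformation** for display and thresholding:
   \(z = \operatorname{sign}(t)\,\Phi^{-1}(1 - p_{two}/2)\), the
   standard-normal deviate with the same two-sided tail probability.
   Computed on the log scale so that extreme \(|t|\) does not saturate to
   \(\pm\infty\); \(|z| \le |t|\) for df \(\ge 2\) because the t
   distribution is heavier-tailed.
5. **Cluster-extent correction** (next section) and rendering of the
   surviving clusters as a Z-colored topography on the body outline.

## Monte-Carlo cluster-extent correction

Pixel-wise testing over ~10^5–10^6 body pixels needs a multiple-comparison
correction. The package re-implements the classic simulation-based
cluster-extent approach: threshold pixels at an uncorrected per-pixel
`voxel_p` (default 0.05), then keep only connected components whose size
strictly exceeds an extent cutoff \(k\), where \(k\) is calibrated so that
under a global null the probability of *any* surviving cluster is at most
`corrected_alpha` (default 0.05) — family-wise error (FWE) control.

Each of the `n_iterations` (default 10,000) null iterations:

1. draws an iid standard-normal field on the full canvas;
2. smooths it with a Gaussian kernel of the configured `fwhm_px`
   (reflecting boundaries, so no edge dimming inside the body);
3. re-standardizes the in-mask values to zero mean, unit variance;
4. thresholds at the normal quantile matching `voxel_p`;
5. labels connected components *per view* and records the maximum size.

\(k\) is then the smallest integer whose null exceedance fraction is
\(\le\) `corrected_alpha`; data clusters must satisfy size \(> k\)
(strictly), matching the convention of reporting thresholds as
"cluster size > k pixels".

Design choices that were genuinely open:

* **Sidedness.** With the default `sides = "two"`, the simulation
  thresholds \(|z|\), so the suprathreshold pixel rate equals `voxel_p`
  across both tails. On data, extraction defaults to positive-t clusters
  only ("sensation present"); since the null maximum over both tails is at
  least the positive-tail maximum, the calibrated \(k\) remains valid
  (mildly conservative) for one-signed extraction. A `sides = "one"`
  configuration is available when a strictly one-sided analysis is wanted.
* **Connectivity.** Default 8 (edges + diagonals), the conventional, more
  permissive 2D choice; 4-connectivity is available. Connected components
  are computed per body view: front and back panels sit side by side on one
  canvas, and adjacency across the panel gap is an artifact of layout, not
  anatomy, so clusters never span views.
* **Smoothness of the simulated nulls.** The extent threshold grows with
  field smoothness, so the simulation must be told an FWHM. Drawings carry
  no acquisition FWHM, so the default is to estimate it from the data: the
  variance-of-first-differences estimator on the mean-removed subject maps
  (neighbour correlation \(\rho = 1 - \mathrm{var}(\Delta X) /
  (2\,\mathrm{var}(X))\), inverted to the kernel sigma). Uncorrelated
  residuals give FWHM ≈ 0; calibrating with an FWHM *larger* than the true
  data smoothness is conservative for FWE.
* **Reproducibility.** The whole simulation is driven by one RNG seed
  (saved and restored around every simulation call). A reference value
  often quoted for this procedure at full acquisition scale — cluster size
  > 1089 pixels on a 1024×1024 canvas at voxel p < 0.05 — depends on the
  original mask and smoothness settings, which are not recoverable; it is
  carried in this documentation as context, not asserted by the package.

## Questionnaire analysis

Each of the 13 items is analysed with a classical fixed-effects two-way
ANOVA with interaction (stimulus type × location, via `stats::aov`; the
sequential decomposition equals the textbook sums-of-squares split on the
balanced design). The design is actually within-subject, so a
repeated-measures variant with subject as an additive blocking factor is
available behind `repeated = TRUE`; the fixed-effects analysis remains the
default because it is the analysis conventionally reported for this kind
of table. Item-level p-values carry both uncorrected (α = 0.05) and
Bonferroni (α/13) flags; corrected significance implies uncorrected by
construction. Scores are validated as integers 0–3 but real values are
accepted with a warning. When the within-cell variance vanishes (everyone
answered identically) F is undefined and the row is flagged `degenerate`
rather than reporting 0/0.

## The synthetic-study generator

The generator emulates the structure of a typical BSM experiment — by
default 25 subjects × (1 baseline + 2 stimulus types × 4 locations) — with
known ground truth:

* **Effects** are Gaussian blobs (sensation at/near the stimulated point,
  baseline palm sensations) or constant-width line kernels along waypoint
  paths (sensations propagating along a limb, the line-like percepts
  classically described along meridian courses). Each effect has an
  amplitude, a spatial scale, a per-subject expression probability
  (*prevalence*) and a per-subject positional jitter (re-drawn up to 10
  times if it would leave the body, then clipped). The ground-truth support
  of an effect is the pixel set at or above half its core amplitude.
* **Noise** is additive Gaussian truncated at zero (drawings cannot be
  negative), plus a lognormal per-subject marking gain (default σ = 0.2)
  mimicking idiosyncratic drawing vigor; normalization absorbs the gain
  exactly. Defaults: noise sd 0.1–0.15 against unit-amplitude effects.
* **Questionnaires** are drawn per cell as Binomial(3, mean/3), so any
  target cell-mean matrix in \([0,3]\) is directly parameterizable.
* Baseline effects enter *every* session, so baseline subtraction is
  testable: with noise off, stimulation-minus-baseline cancels exactly.

What the generator does **not** model: reporting and recall biases,
stroke-level drawing mechanics (strokes are modelled as already-rasterized
intensity fields), spatially correlated pixel noise, and physiologically
realistic propagation geometry. Passing tests therefore demonstrate the
*statistical* correctness of the pipeline under a plausible noise model,
not the fidelity of any specific physiological claim about real drawings.

## Validation and problem sizes

The test suite validates every stage against independent oracles at sizes
chosen to keep a full run in a few minutes on one CPU:

* connected-component labeling against a brute-force flood fill (200
  random 12×12 grids, both connectivities, exact agreement);
* the simulated max-cluster-size null on an 8×8 mask against a
  200,000-iteration oracle using a different (label-propagation) algorithm,
  compared by a two-sample Kolmogorov–Smirnov bound at α = 0.01;
* t→Z against direct tail-probability inversion (1e−6 over
  \(t \in [-6,6]\), df ∈ {2, 5, 24, 100}) and against numeric integration
  of the t density with root-finding on the normal CDF;
* the ANOVA against a hand-written sums-of-squares decomposition (50
  random balanced 2×4 datasets, 25 per cell, 1e−8);
* FWE control end-to-end: a 64×64 single-view mask, extent threshold from
  10,000 fwhm-8 null iterations at voxel p < 0.05, then 1,000 simulated
  null studies (n = 25) through the full normalize → subtract →
  t-map → extract chain; the surviving-cluster rate must stay within the
  corrected level (plus 3 binomial standard errors);
* recovery: a planted torso blob (σ = 5 px on a 64×64 view, amplitude 0.6
  against noise sd 0.15 — giving a per-pixel standardized effect of ≈ 1.5
  over the interior of its support at the difference-map stage) must be
  found, with ≥ 50 % truth overlap, in ≥ 90 % of 100 replicate studies at
  n = 25, while the same analysis with no planted effect keeps its
  family-wise error at the corrected level.

The amplitude/noise choice deserves one note: because the baseline drawing
is pure truncated noise normalized to its own maximum, the baseline's
contribution to the difference-map variance is *scale-free* (≈ 0.16 in
normalized units regardless of the noise sd). Planted effect sizes are
therefore quoted as the standardized per-pixel effect actually measured on
difference maps, not as a raw amplitude-to-noise ratio.

## Numerical choices

* Smoothing uses cached separable reflect-boundary convolution operators;
  reflection conserves total mass exactly and a constant field is a fixed
  point. `fwhm = 0` is the identity.
* Cluster labels are ordered by decreasing size with ties broken by the
  component's first pixel in row-major scan order, so labelings are
  deterministic and comparable across implementations.
* All coordinates are 1-based (row, column) from the top-left, R's native
  matrix convention.
* CSV map round trips are bit-exact (`%.17g`); PNG is 8-bit, exact to
  1/255. All-zero maps normalize to themselves with a warning; degenerate
  ANOVA cells and zero-variance pixels are flagged, never silently zeroed.

## Limitations

* The builtin 1024×1024 humanoid template is synthetic: it has the
  right canvas size and layout conventions but is not any published
  template pixel-for-pixel, and its region atlas is schematic.
* Fixed-template analysis assumes all subjects draw on the same canvas; no
  spatial registration between subjects is attempted (none is needed for
  template-locked acquisition, but free-hand sketches would need it).
* The pixel-level model is a t-test; mixed-effects or permutation
  alternatives are out of scope.
* Cluster-extent calibration assumes stationary field smoothness; strongly
  non-stationary drawing noise would make the correction locally
  conservative or liberal.
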