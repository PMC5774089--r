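---
title: "Quantifying PET and DW-MRI therapy response: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PET and DW-MRI therapy response: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petdwi)
```

## The measurement problem

Targeted therapies often change tumor physiology long before they change
tumor size, so morphology-based response criteria miss early effects.
Two functional imaging readouts fill that gap in preclinical oncology:

* **Tumor glucose uptake by ^18^F-FDG-PET**, summarized as the
  *tumor-to-liver ratio* (TTL): the hottest voxel inside a manually drawn
  tumor VOI divided by the mean activity of a small liver background VOI,
  $\mathrm{TTL} = \mathrm{VOI}^{max}_{tumor} / \mathrm{VOI}^{mean}_{liver}$.
  Because it is a ratio of activities in the same image, injected dose,
  body weight, and scanner calibration cancel. Alongside it, the
  *metabolic tumor volume* (MTV) is the volume of the voxel set whose
  activity reaches a fixed fraction (30% by default) of the VOI maximum.
* **Tumor cellularity by diffusion-weighted MRI**, summarized as the
  *apparent diffusion coefficient* (ADC) of the mono-exponential signal
  model $S(b) = S_0\, e^{-b\,\mathrm{ADC}}$ fitted voxel-wise across
  b-values, with the VOI **median** as the per-tumor statistic. Densely
  cellular tumors restrict water diffusion (low ADC); effective therapy
  tends to raise ADC.

The package implements these quantifications, the delta-response metrics
(follow-up minus baseline per animal), and the small-sample nonparametric
inference used to compare a therapy and a control arm, and ships the
per-animal tables of a 21-animal melanoma xenograft study (12 animals on a
BRAF + CDK4/6 inhibitor combination, 9 on placebo, imaged at day 0 and day
7) as plain-text fixtures so the entire published analysis can be
regenerated from scratch.

## PET semiquantification

`segment_mtv()` reads "threshold at 30% of the hottest voxels" in the
conventional fixed-percentage sense: keep voxels with intensity at least
`fraction` × (VOI maximum). Ties at the threshold are kept (`>=`), which
guarantees the maximum voxel is always inside its own mask and the result
is never empty. No connected-component filtering is applied — nothing in
the emulated protocol selects components. The alternative reading, the top
30% of VOI voxels by rank, is available behind `mode = "top-count"` for
sensitivity analyses but is not the default.

`make_liver_voi()` builds the 9 mm³ liver background as a voxelized
sphere: the voxel count is the integer whose total volume is closest to
the target (for 0.5 mm isotropic voxels that is exactly 72 voxels; for
0.4 mm voxels, 141 voxels = 9.024 mm³), and the voxels chosen are those
nearest the requested center, ties broken by array order so the mask is
reproducible. A placement whose bounding sphere crosses the grid edge is
rejected rather than silently truncated. The source protocol states only
the VOI volume, not its shape; a sphere is the natural reading.

`compute_ttl()` divides the tumor-VOI maximum by the liver-VOI mean and
refuses non-positive liver means (a corrupt background would silently
invert the meaning of the ratio). TTL and the MTV mask are invariant under
positive rescaling of the volume, which the tests assert.

## ADC mapping

The default fit is **unweighted log-linear least squares**: OLS of
$\ln S$ on $b$, slope $-\mathrm{ADC}$, intercept $\ln S_0$. With three
b-values this is the standard deterministic choice; the alternative
**nonlinear** path (Levenberg-Marquardt on the exponential model,
initialized from the log-linear solution) is provided because the source
protocol says only "least-squares fitting" without specifying the domain.
On noiseless data the two agree to at least 10 significant digits, which
the tests check. All frames enter the fit symmetrically; there is no
b = 0 special-casing.

Failure handling is deliberately two-tier:

* a voxel with any non-positive signal cannot enter the log fit and is
  *flagged invalid*, not raised as an error — in magnitude MR data such
  voxels are background or noise floor;
* fitted ADC values outside the physiological window (0, 4 × 10⁻³) mm²/s
  (the free-water ceiling) are retained in the map but flagged invalid, so
  VOI medians are protected without discarding information.

The per-tumor statistic is the median over valid VOI voxels, midpoint
convention for even counts. ADC is carried in mm²/s everywhere internally;
the ×10⁻³ scale familiar from the literature is applied only when
reporting.

## Exact nonparametric inference

At n = 12 vs 9 the choice between exact and asymptotic nonparametric tests
visibly moves p-values, so the package implements the exact versions from
first principles with mid-rank (average rank) tie handling throughout and
a stated two-sided convention: p = min(1, 2 × min(lower tail, upper
tail)).

* `mann_whitney_exact()` enumerates all $\binom{m+n}{m}$ assignments of
  the pooled mid-ranks — for 21 animals that is 293,930 assignments —
  conditioning on the observed tie pattern. Beyond a combined n of 25 it
  switches to the tie-corrected normal approximation (no continuity
  correction) and labels the result `asymptotic`.
* `wilcoxon_signed_rank_exact()` drops zero differences (the classical
  convention; the Pratt variant is behind `zero_method = "pratt"`) and
  computes the exact null distribution of W⁺ over all $2^n$ sign
  assignments by convolving per-rank generating functions on doubled
  ranks, which is mathematically identical to literal enumeration; the
  tests verify that equality against a brute-force $2^n$ oracle.
* `spearman_cor()` computes ρ as the product-moment correlation of
  mid-ranks (reducing to $1 - 6\sum d_i^2 / (n(n^2-1))$ without ties),
  with an exact permutation p-value for n ≤ 10 (complete n! enumeration in
  C++) and the t approximation above that.
* `bonferroni_adjust()` applies min(1, m·p); the family size is explicit
  because the emulated analysis does not enumerate its confirmatory
  family.

Enumerated null distributions are memoised on the pooled mid-rank
multiset, so simulation studies with continuous (tie-free) data reuse a
single enumeration; cached and uncached calls return identical p-values.

One practical consequence the analysis scripts surface: for the
intergroup ΔADC comparison the tie-aware exact p is 0.00033 while the
normal approximation gives 0.00107 — on the wrong side of the 0.001
bound the published abstract prints. Only the exact computation
reproduces the published claim.

## The packaged study tables and their two anomalies

The fixtures transcribe the published per-animal tables cell by cell
(PET, MRI, and IHC; 21 animals). Deltas are **always recomputed** from the
timepoint columns because of a documented typographical sign flip: one
animal's printed ΔTTL is +0.06 while follow-up − baseline gives −0.06, and
only the recomputed value reproduces the printed therapy-group mean of
−1.00. The printed delta columns are retained in the fixtures purely for
cross-checking (a test asserts agreement within print-rounding slack of
0.015 everywhere except that cell).

Summaries use the arithmetic mean and the sample (n − 1) SD, which
reproduces every printed SD; comparisons against printed values round
half-away-from-zero at each statistic's printed precision (TTL and
×10⁻³-scale ADC at 2 decimals, volumes at 1, IHC counts at 0, ρ at 2).
All 56 printed summary cells match at printed precision. Three published
correlation coefficients (TTL–CD31 0.79, ADC–Ki-67 −0.42, ΔTTL–ΔADC
−0.75) differ from the mid-rank recomputation by exactly one unit in the
last printed digit (0.785, −0.415, −0.745); the published computation is
not exactly recoverable, so these rows are whitelisted with notes in the
comparison report rather than silently passed or failed. Published
p-values are compared by significance decision at α = 0.05 (and by the
printed bound where one is given), since the original analysis software's
exact/asymptotic behavior is unknown; every decision agrees.

Which imaging timepoint enters the IHC correlations is not stated in the
emulated protocol; the follow-up scan is used because it is acquired hours
before explantation and it reproduces the printed coefficients.

## Synthetic data: what the phantoms emulate and what they do not

The generators exist so every downstream stage is testable with known
ground truth; they are deliberately minimal.

* **PET phantom**: tumor and liver ellipsoids (voxel-center-inside
  rasterization, so MTV voxel counts are exactly reproducible) in a
  uniform background, 0.5 mm isotropic voxels by default, additive
  Gaussian noise truncated at zero. The tumor is either uniform at the
  peak activity or a parabolic radial falloff; the falloff is a stand-in
  heterogeneity profile, not a model of melanoma biology. No scatter,
  attenuation, partial-volume, or reconstruction effects are simulated.
* **DWI phantom**: per-voxel $S_0 e^{-b\,\mathrm{ADC}}$ at
  b = 0/200/800 s/mm² on a 0.3 × 0.3 × 2 mm grid, constant or
  two-compartment true ADC, Gaussian or Rician noise (Rician — the
  magnitude of a complex Gaussian perturbation — is the physically
  faithful model for magnitude MRI; Gaussian is the default for analytic
  tractability at the SNR used here). No k-space, eddy-current, or motion
  effects.
* **Cohort generator**: baseline values per biomarker from a common
  Gaussian (the groups are randomized, so a shared baseline distribution
  is the right null structure), follow-up = baseline + a group-specific
  Gaussian effect, IHC counts per group rounded to non-negative integers.
  The defaults are the observed study conditions: n = 12/9 and the
  printed group means/SDs (e.g. ΔTTL −1.00 ± 0.53 vs +0.85 ± 1.21; ΔADC
  +0.12 ± 0.14 vs −0.12 ± 0.06 ×10⁻³ mm²/s; CD31 147 ± 48 vs 287 ± 92).
  Baseline means/SDs, which the study reports only per group, are pooled
  round numbers within the printed ranges (TTL 4.0 ± 0.95, ADC
  0.785 ± 0.10 ×10⁻³, metabolic volume 185 ± 115 mm³, morphological
  volume 112 ± 80 mm³). Values are truncated to their physical domains
  (volumes ≥ 0, ADC in (0, 4 × 10⁻³), TTL ≥ 0.05); truncation is
  negligible at these settings.

Every generator call derives all randomness from one explicit seed and
restores the caller's RNG state, so identical configs and seeds give
bit-identical outputs.

Passing tests on these phantoms therefore demonstrate correctness of the
*quantification and inference machinery* — threshold segmentation, ADC
fitting, exact tests — under known truth. They do not demonstrate
robustness to the things real scans contain: partial-volume effects,
motion, registration error between timepoints, heterogeneous uptake, or
reconstruction artifacts.

## The end-to-end pipeline

`run_phantom_pipeline()` closes the loop: a simulated cohort fixes each
animal's true TTL, MTV, and ADC per timepoint; each animal/timepoint is
rendered as a PET phantom (tumor peak = true TTL × liver mean; tumor
radius chosen so the voxelized sphere matches the true MTV, clamped to
the 1–6.4 mm the default grid can hold) and a constant-ADC DWI phantom;
the phantoms are quantified exactly as real data would be; and
`run_study()` runs on the measured table. Noiselessly, TTL is recovered
exactly, ADC to machine precision, and MTV within voxelization error.
Morphological volumes pass through from the simulated truth: they would
come from T2w segmentation, which is out of scope.

## Problem sizes and runtime choices

The test suite and analysis scripts use sizes chosen to exercise every
code path while staying desk-scale: 8³–40·28·28-voxel phantoms, the full
C(21,12) enumeration for the study-sized U test (cached after first use),
literal 2^n and n! oracle enumerations capped at n ≤ 12 and n ≤ 6, 200
replicates for power, and 400–1000 replicates for type-I calibration.
The complete suite runs in well under a minute on one CPU.

## Known limitations

* The MTV threshold is applied inside the guidance VOI only; whether the
  emulated protocol dilated the region is unknowable from its description.
* SUV normalization is intentionally absent: TTL is a pure ratio. Absolute
  SUVmax/SUVmean are out of scope.
* IVIM/kurtosis models, motion/eddy-current correction, and image-derived
  morphological volumetry are out of scope.
* The exact tests enumerate up to a combined n of 25; beyond that the
  normal approximation is used and labelled, but no exact mid-p or
  network algorithm is provided.
* The phantom pipeline validates recovery of configured effects, not
  realism of the imaging physics.
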