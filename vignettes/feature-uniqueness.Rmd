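---
title: "Screening radiomic features for uniqueness by ROI translocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening radiomic features for uniqueness by ROI translocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radUnique)
```

## The question: is a feature unique to the structure it was measured on?

Radiomic features are scalar descriptors computed from the voxels inside a
region of interest (ROI), usually a tumor. Most quality screens ask whether a
feature is *reproducible* — stable across scanners, protocols or repeated
segmentations. `radUnique` asks a complementary question: is the feature
*unique* to the underlying structure at all? If the identical ROI shape,
parked over adipose tissue, heart, normal lung or muscle in the very same
image set, returns values that agree closely with the tumor's, the feature
mostly reflects the ROI geometry or the feature's own normalization — not
tumor biology — and should be excluded from modeling.

The screen works per patient:

1. the tumor mask is translocated rigidly (no rotation, no rescaling) into
   each of four other tissue regions of the same volume, so shape effects
   cancel by construction;
2. 123 radiomic features are extracted from all five placements;
3. the **coefficient of variation** (CV, percent) of each feature across the
   five placements measures whether the feature varies between tissues at
   all, and **Lin's concordance correlation coefficient** (CCC) between the
   tumor values and each tissue's values measures pairwise agreement;
4. thresholds and patient-level aggregation turn these into per-feature
   verdicts per cohort, and a combination rule merges cohorts.

A feature is flagged in a patient when CV < 10% (agreement across all five
placements) or CCC > 0.85 (agreement with one tissue). A feature flagged in
at least half of the patients fails; a CCC failure in two or more of the four
tissue pairs makes the feature CCC-nonunique. The combined nonunique set
contains the features that fail both metrics in every cohort.

## The statistics

For feature values $x_1,\dots,x_5$ over the five placements of one patient,

$$\mathrm{CV} = 100\,\frac{s}{|\bar x|},$$

with $s$ the $n-1$ sample standard deviation. We use $|\bar x|$ because many
features (skewness, cluster shade, HU statistics) are legitimately negative;
a CV is undefined (and never counts as a flag) when $|\bar x| <
10^{-9}\,s$, or when fewer than two values are defined.

For paired series $x$ (tumor) and $y$ (one tissue), Lin's estimator with
biased ($n$-denominator) moments is

$$\rho_c \;=\; \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}.$$

It is bounded by the Pearson correlation in magnitude and penalizes location
and scale shifts. Two identical constant series get $\rho_c = 1$; two unequal
constant series carry no agreement information and get 0.

What the CCC is computed *over* follows the feature's variant structure.
Directional features (the co-occurrence families, run lengths) and
percentile-based features produce several values per ROI; for these, the CCC
is computed per feature across its variants, matched by variant id. Features
with a single value cannot support a correlation on their own, so scalar
features receive a category-level CCC computed across the scalar members of
their category, every member receiving the same value. This is why scalar
families (the Gaussian-fit block, for instance) fail or pass as whole
blocks, which is exactly the failure pattern visible in the published
per-feature tables. The alternative — category-level CCC for everything — is
available as `cccTable(..., grouping = "category")`. The category-level CCC
is computed on raw feature values without rescaling, so large-magnitude
features dominate it; this magnitude dominance is inherent to the design and
documented rather than corrected, since no normalization is specified for
the procedure being modeled.

The per-patient CV of a multi-variant feature is the mean of its per-variant
CVs (each taken across the five placements); features are reported at the
123-feature level throughout, matching the layout of the published heatmaps.

## The feature bank

The registry (`featureRegistry()`) fixes 123 features in seven categories:
Intensity Direct (34), Intensity Histogram (9), Intensity Histogram Gauss
Fit (6), gray-level co-occurrence 2D + 3D (22 + 22), gray-level run length
2D (11), neighborhood gray-tone difference 2D + 3D (5 + 5), and gradient
orientation histogram (9). Every feature named in the published per-feature
tables is present under its listed category; the remainder of the Intensity
Direct and Intensity Histogram memberships is not recoverable from the
tables alone and is filled from the IBEX feature lineage under the count
constraint — those rows carry `reconstructed = TRUE` in the registry.

Numerical conventions, chosen once and recorded here because these feature
names are conventional in the field but not uniquely defined:

* **Quantization**: 64 equal-width gray levels over the ROI's own min–max,
  separately per ROI. $N_g$ enters the normalized homogeneities explicitly,
  so it is part of the model, not an implementation detail.
* **Co-occurrence**: distance-1 offsets; 4 in-plane directions (2D,
  per-slice pair counts pooled before normalization) and 13 unique 3D
  directions; symmetric accumulation. Entropies use log base 2 with
  $0\log 0 = 0$.
* **Run lengths**: 4 in-plane directions pooled across slices; out-of-mask
  voxels terminate runs.
* **NGTDM**: 8-neighborhood per slice (2D) or 26-neighborhood (3D),
  restricted to in-mask voxels; Coarseness uses $\varepsilon = 10^{-6}$ in
  its denominator, capping it at $10^6$ for constant regions.
* **First-order statistics**: kurtosis is non-excess (normal = 3); mean and
  median absolute deviations are unscaled, about the mean and median
  respectively; the percentile grid is 10–90% in steps of 10; entropy and
  uniformity use 1-HU-wide histogram bins. Local entropy/range/std use a
  3×3 in-plane window restricted to the mask — the smallest nontrivial
  window, which stays meaningful for the 4 mm nodules at the bottom of the
  study's size range.
* **Gaussian fit**: a 1–3 component univariate mixture selected by BIC
  (`mclust`), deterministic evenly-spaced-subset initialization; the
  histogram is on 1-HU bins so `HistArea` equals the ROI voxel count —
  which is why, with the same translocated shape everywhere, `HistArea` is
  structurally nonunique (the screen's own tables show it; a config flag
  can exclude it as a same-shape artifact).
* **Gradient orientation**: per-slice central differences; orientation
  angles in degrees, binned into 36 magnitude-weighted bins of 10°; the
  nine descriptive statistics are computed on that weighted distribution.
  An all-zero gradient field degenerates to a point mass, for which every
  spread statistic is 0, and skewness/kurtosis of a zero-variance
  distribution are set to 0 by convention.
* **Undefined values** (single-level ROIs, empty co-occurrence matrices,
  single-voxel neighborhoods) are carried as `NA`, never as zero, and are
  dropped pairwise by the statistics downstream.

## Why IDMN and IDN are the interesting case

The co-occurrence homogeneities come in two flavors:
$\mathrm{H}_1 = \sum_{ij} p_{ij}/(1+|i-j|)$ and
$\mathrm{H}_2 = \sum_{ij} p_{ij}/(1+(i-j)^2)$, and their normalized forms

$$\mathrm{IDN} = \sum_{ij} \frac{p_{ij}}{1+|i-j|/N_g}, \qquad
  \mathrm{IDMN} = \sum_{ij} \frac{p_{ij}}{1+(i-j)^2/N_g^2}.$$

Dividing the gray-level difference by $N_g$ shrinks every denominator toward
1, so termwise $\mathrm{IDN} \ge \mathrm{H}_1$ and $\mathrm{IDMN} \ge
\mathrm{H}_2$ on any input — an order invariant the test suite asserts on
every phantom ROI. With $N_g = 64$ and distance-1 offsets, level differences
of neighboring voxels are small relative to $N_g$, so IDMN and IDN compress
toward 1 for *any* tissue, while the unnormalized homogeneities still
separate tissues. That compression is the mechanism by which these two
features (and only these two, among the co-occurrence family) turn up
nonunique in both cohorts: the normalization itself, not the tissue,
dominates the value.

## The decision rules

`DecisionConfig()` holds the thresholds: CV < 10%, CCC > 0.85, patient
fraction 0.5, at least 2 failing tissue pairs, combination rule
"CV-nonunique in every cohort AND CCC-nonunique in every cohort". Two rules
deserve justification because the prose description of the procedure is
ambiguous:

* **The patient fraction is inclusive** (`count >= 0.5 n`). The published
  per-cohort totals are only reproducible this way: the larger cohort's CV
  table contains entries at exactly 9/18 that are counted as failures, while
  the smaller cohort's totals are unaffected (no 7/14 entries exist there).
  The strict variant is available (`inclusiveFraction = FALSE`).
* **The combination rule is the double intersection.** Among the candidate
  readings ("both metrics in both cohorts", "either metric in both
  cohorts", "both metrics in any cohort"), only the double intersection
  reproduces the published 9-feature combined set — it correctly excludes
  the CCC-only features (Quantile, Skewness of the gradient-orientation
  family) and the CV-only ones (the 2D normalized homogeneities, HistArea).
  The alternatives remain selectable via `combineRule`.

Verdicts are monotone in every threshold (tightening a threshold never
enlarges a nonunique set), and the combined set is contained in each
intermediate set; both properties are tested.

The published per-feature counts ship as plain-CSV fixtures and can be
replayed through the engine with `replayUniqueness()`, which reproduces the
headline numbers: 12 and 29 CV-nonunique features in the two cohorts (9.8%
and 23.6% of 123), 18 and 16 CCC-nonunique (14.6% and 13%), 11 overlapping
CCC features, and 9 features (7.3%) nonunique overall.

## The synthetic phantom

Because no imaging data is distributed, the package ships a deterministic
phantom generator (`generatePhantom()`) that emulates what the pipeline
needs from a CT volume: five labeled tissue classes with distinct means and
textures, and a nodule that the translocation and extraction stages can
exercise end to end.

* **Geometry** is four equal slabs along the row axis (adipose, heart,
  muscle, lung) with a spherical nodule centered in the lung slab. Equal
  slabs maximize the smallest region, so every tissue can host the
  translocated ROI across the study's full 4–31 mm nodule-size range on the
  default 48×128×128 grid (1 mm isotropic). Nothing downstream depends on
  anatomical realism — only on disjoint regions large enough to host the
  ROI.
* **Attenuation** defaults are textbook values: lung −800, adipose −100,
  heart +40, muscle +50, nodule +20 HU. **Texture** is Gaussian white noise
  smoothed with a Gaussian kernel of a per-tissue correlation length (2
  voxels for most tissues), standardized within each region so the region
  mean and standard deviation are exact, then added to the tissue mean.
  Noise levels (15–40 HU) are free knobs chosen to give the five classes
  clearly distinct first- and second-order statistics; no quantitative
  per-tissue texture statistics exist to calibrate them against, so they
  are fixed once here and not tuned.
* The **nodule** carries an optional mean-centered radial ramp (default
  30 HU center-to-rim) so gradient-orientation features see non-degenerate
  structure.
* **Determinism**: the volume is a pure function of the spec including its
  seed; per-patient sub-seeds in the pipeline are derived by a stable string
  hash of (master seed, patient id), so cohort results are independent of
  patient order.

What the phantom does *not* emulate: reconstruction kernels, beam hardening,
dose modulation, anatomical boundaries, partial-volume mixtures at tissue
interfaces, or inter-patient anatomical variability. Pipeline tests on
phantoms therefore demonstrate that the machinery (translocation geometry,
feature definitions, statistics, decision rules) is correct and
deterministic — not that real NSCLC cohorts would yield any particular
uniqueness pattern. The quantitative claims about the published cohorts are
carried by the replayed per-feature counts, not by phantoms.

## Translocation mechanics

`findPlacements()` translates the tumor mask rigidly. Candidate positions
are evaluated for full containment in the target tissue label by an FFT
cross-correlation of the label indicator with the ROI shape (equivalent to a
binary erosion), which scores every offset at once; the brute-force
enumeration serving as its test oracle is exact but only feasible on small
grids. In-plane positions (zero slice offset) are preferred; only when none
contains the ROI does the search widen to slice offsets of growing
magnitude — the least-biased mechanization of "choose an appropriate
z-location". Among the valid positions of the first non-empty group, one is
drawn uniformly at random under the seed, because the placement procedure
being modeled is explicitly random. Non-tumor placements may overlap one
another — only containment in the target tissue is enforced — and the
placement log records the overlap flag, the offset, the fallback flag and
the seed.

## Problem sizes and costs

The defaults (48×128×128 voxels, 64 gray levels) extract all 123 features
from a 16 mm nodule in well under a second per ROI; a full two-cohort
phantom study of 5 + 5 patients (50 extractions) completes in a few minutes
on one core. The test suite and the acceptance script use 20×64×64 grids
with 6–14 mm nodules — the smallest sizes at which every stage (multi-slice
ROIs, all four slabs hosting placements, non-degenerate textures) is still
exercised — so the whole suite stays fast while covering the same code
paths.

## Known limitations

* The exact membership of the Intensity Direct / Intensity Histogram
  categories beyond the printed names is reconstructed, and the per-feature
  variant expansion (558 values here) intentionally does not chase any
  particular tool's internal variant enumeration.
* DICOM series reading delegates to SimpleITK through the bundled Python
  helper; NIfTI is the native interchange format. RT-STRUCT contours are
  out of scope — masks are the exchange format.
* Shape features are excluded by design (the translocated ROI is identical
  everywhere, so they are trivially nonunique), as are wavelet/Gabor/Laws
  filtered features.
* No confidence intervals or hypothesis tests are attached to CV/CCC; the
  screening procedure is a deterministic rule set, and that is what is
  implemented.

## A worked example

```{r example, eval = FALSE}
library(radUnique)

# replay the published per-feature counts through the decision engine
report <- replayUniqueness()
report
lengths(reportSets(report))

# or run the full synthetic pipeline
cfg <- runConfig(cohorts = list(GE = list(n = 5, diameterRange = c(11, 31)),
                                Siemens = list(n = 5,
                                               diameterRange = c(4, 22))),
                 outputDir = "run_out", seed = 1)
phantomReport <- runPipeline(cfg)
reportSets(phantomReport)$combined
```
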