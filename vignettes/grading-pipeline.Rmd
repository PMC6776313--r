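---
title: "Methods: automated two-tier nuclear grading of ccRCC histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated two-tier nuclear grading of ccRCC histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rccgrade)
```

## The problem

Fuhrman nuclear grading of clear cell renal cell carcinoma (ccRCC) rests on
nuclear size, nucleolar prominence and membrane irregularity, and is known
for mediocre inter-observer agreement. `rccgrade` implements an automated
alternative: hematoxylin-and-eosin (H&E) tumor regions are tiled into
patches, nuclei are segmented, 72 quantitative nuclear features are
extracted per patch, summarized to the region-of-interest (ROI) level, and
an L1-penalized logistic model maps the summarized features to a two-tier
grade (low = Fuhrman 1–2, high = 3–4). The package also provides the
statistics used to evaluate such a system: inter-rater agreement (Cohen's
and Fleiss' kappa), confusion-matrix metrics, and Kaplan–Meier / Cox
proportional-hazards analysis of the prognostic value of predicted grades.

Because whole-slide cohorts cannot ship with a package, every stage is
exercised against a synthetic fixture generator that renders H&E-like
patches with known nuclei and simulates case cohorts with grade-dependent
hazard.

## Color model

Analysis uses three channels per patch: the HSV value channel, the Lab
lightness (L*, D65 white point, rescaled to [0, 1]) — the two
lightness-like channels of those spaces — and the hematoxylin optical
density (OD) from color deconvolution. Deconvolution projects per-pixel OD,
defined as `-log10((p + 1)/255)` (the +1 keeps zero pixels finite; negative
OD from near-white pixels is clipped to 0), onto the inverse of the
standard Ruifrok–Johnston H&E stain basis completed by a normalized
residual vector. The synthetic renderer uses the exact inverse
(Beer–Lambert with the same basis), so deconvolution∘reconstruction is
identity to within one gray level on noiseless fixtures — a property the
tests assert.

Stain variation across slides is handled by `normalize_stain()`: a monotone
quantile map of each stain channel's OD distribution onto a reference
patch's. The exact published normalization behind the original workflow is
not specified at this level of detail; the quantile map is this package's
declared stand-in from the standard nonlinear-normalization family, and it
is configurable. Tied source values map to one output value, so the map is
a well-defined monotone function; it is near-identity on the reference
itself and idempotent up to 8-bit quantization.

## Nuclei segmentation

Two steps, as in the classical H&E pipelines:

1. **Adaptive thresholding** in HSV with a k-of-3 channel vote (default
   2-of-3): value below the local box-filter mean minus `offset_v`
   (nuclei are dark), saturation above the local mean plus `offset_s`
   (nuclei are strongly stained), and hue inside the hematoxylin
   (blue-violet) band. Defaults: window 101 px, `offset_v` 0.02,
   `offset_s` 0.01, hue band (0.5, 0.8). The hue band was set from the
   rendered chromogens: pure hematoxylin sits near hue 0.68 while the
   eosin background sits near 0.84, so the band accepts the former and
   rejects the latter.
2. **Marker-controlled watershed**: markers are the h-maxima (depth
   `h_min = 2` px) of the Euclidean distance transform; flooding of the
   negated distance map is restricted to the foreground, so background is
   never claimed.

Refinement fills holes per label and applies a 3×3 binary opening; labels
with refined area outside [200, 2000] px are removed (the published
in-range band for nuclear detection), and survivors are renumbered in their
original order. Border-touching nuclei are kept, subject to the same area
filter — keeping them is deterministic and maximizes counts. All parameters
live in `segmentation_params()` and are dumped into every pipeline run's
resolved configuration.

## The 72 histomics features

Per nucleus: 9 morphology, 5 intensity × 3 channels, 16 texture × 3
channels (9 + 15 + 48 = 72). Naming is `morph_*`, `int_<stat>_<ch>`,
`tex_<stat>_<ch>` with channels `hsv`, `lab`, `he`; `feature_manifest()`
ships the machine-readable table.

* **Morphology**: area (pixel count); Crofton perimeter (run counts along
  the four principal directions, diagonals rescaled by their line
  spacing); equivalent spherical radius `sqrt(area/pi)` and its perimeter;
  roundness = equivalent spherical perimeter / perimeter; ellipse axes =
  4·sqrt of the pixel-covariance eigenvalues, elongation = major/minor.
  Flatness is defined equal to elongation: the three-axis flatness
  degenerates in 2D, and the published coefficient on flatness MAD
  (−4.2e−16) is numerically null, consistent with a redundant feature.
* **Intensity**: mean, median, SD (n − 1), skewness (g1) and excess
  kurtosis of channel values in the nucleus; constant regions return 0 for
  the latter three by convention.
* **Texture**: gray-level co-occurrence (GLCM) and run-length (RLM)
  statistics after min–max quantization to Q = 32 levels within each
  nucleus (Q is a logged, configurable choice; the source workflow does
  not state one). The GLCM uses distance 1, four directions accumulated
  and symmetrized; entropy uses the natural log; zero-variance regions
  return 0 for the two correlation statistics. Note that the "Haralick
  correlation" formula on a symmetric matrix is algebraically identical to
  GLCM correlation; both are computed as specified and coincide
  numerically. RLM accumulates maximal same-level runs along the four
  directions and evaluates the eight Galloway/Chu emphases normalized by
  total run count, levels indexed 1..Q.

Nucleus-level values are aggregated to the patch by the mean (median
available); the source workflow does not state its aggregator, so this is
a declared choice. The test suite checks every GLCM/RLM statistic against
an independent brute-force enumeration oracle at 1e−10 on random regions,
and shape features against analytic disk/ellipse values.

## ROI summarization and case grades

ROIs are tiled into 2000×2000 patches from the top-left grid (tiles are
configurable for desk-scale work); a right/bottom remainder strip is kept
and reflection-padded when it spans at least half a tile, else dropped —
the tile size is the stated convention, the remainder rule is this
package's declared completion of it. Each of the 72 features is summarized
across a ROI's patches by the median and the raw median absolute deviation
(no 1.4826 consistency factor — the plain MAD is what the method names),
giving 144 features. Even-count medians are the mean of the middle two.

A case's designated grade is the maximum over its ROI grades; the two-tier
split maps 1–2 to low, 3–4 to high. When several ROIs carry the maximal
grade, the representative ROI minimizes Euclidean distance to the
per-feature median of those top-grade ROIs, computed on the raw summarized
features (summarization precedes z-scoring in the pipeline order); ties go
to the smallest ROI id. Whether the original selection used all 144
features is unstated; all 144 is the default here and configurable.

## The grade classifier

Features are z-scored (sample SD; constant columns pass through as zero
with a warning). "Lasso" is implemented as L1-penalized **logistic**
regression — the outcome is binary and model selection uses ROC AUC, which
requires class probabilities — minimizing mean negative log-likelihood +
λ‖w‖₁ with an unpenalized intercept (glmnet backend, warm-started path
ending exactly at the requested λ). λ is tuned by 100 stratified random
90/10 holdouts (stratification prevents single-class validation folds at
cohort sizes in the low hundreds), maximizing mean validation AUC; exact
ties prefer the larger, sparser λ. The classification threshold is 0.5,
configurable. Properties asserted by the tests: intercept-only fit above
the analytic λ_max, monotone support growth along a decreasing λ path,
recovery of ≥ 4/5 informative features with few false positives on the
synthetic cohort, and chance-level AUC on signal-free cohorts.

The published 26-coefficient set (18 unique base features, λ = 0.0101)
ships as packaged data, checksummed and loadable with
`load_published_model()`. Its training z-score means/SDs were never
published, so it cannot produce calibrated probabilities on new data; it is
provided for transcription checks and relative ranking, and
`predict_grade()` treats its missing `zscore_params` as "input already
standardized".

## Agreement and survival statistics

Cohen's kappa is unweighted for both the 2- and 4-tier scales (no weighting
is ever mentioned in this setting); report rounding is two decimals, half
away from zero. Fleiss' kappa requires a complete cases × raters matrix.
Consensus re-assignment is a majority vote, intended for an odd rater
count.

Survival uses the product-limit estimator with Greenwood-based bands, and
Cox proportional hazards with Efron ties (a `ties = "breslow"` option
exists; duplicating a cohort creates ties, under which only the Breslow
equation is exactly invariant — the tests use it for that property). Grade
is coded high vs low so HR > 1 means worse survival for high grade. Stage
enters as a factor with levels I–IV and stage I as reference (an ordered
factor in R would imply polynomial contrasts, which is not what "stage I
reference" means). `grade_prognosis_report()` emits the crude (A), age- and
gender-adjusted (B), and additionally stage-adjusted (C) hazard ratios per
grade source.

## The synthetic fixture generator

`render_patch()` draws elliptical nuclei (semi-axes a ≥ b, arbitrary
orientation) as hematoxylin OD over a uniform eosin background, with
multiplicative chromatin texture: band-limited Gaussian noise (Gaussian
blur σ = 1.5 px, standardized, clipped to ±1 at 2.5 SD) scaled by a
contrast amplitude, plus optional additive OD noise (default SD 0.01).
Rendered disk areas match πab within 3% for a ≥ 8 px. The generator is a
test instrument, not a histology simulator: it has no cytoplasm, stroma,
overlapping chromatin patterns, or scanner artifacts, so passing
segmentation tests demonstrate correctness of the algorithmic chain, not
performance on real slides.

`generate_cohort()` simulates case tables: features are standard normal
with informative features' means shifted by their effect size in
high-grade cases (the simplest model under which L1 support recovery is
well-posed); survival is exponential with the high-grade hazard multiplied
by the configured ratio, and censoring is independent exponential with its
rate set so the expected censored fraction equals `censor_rate` (schemes
that censor uniformly on (0, T) are not independent and would bias hazard
estimation). Defaults mirror the evaluation-cohort conditions reported for
this kind of system: 160 cases, true hazard ratio 2, censoring ~0.6
(≈ 65 events per 160 cases), baseline median survival 60 months, stage
distribution ≈ (52, 11, 23, 14)% and a two-thirds male cohort. No nuclei
density or size distribution is published for ccRCC patches, so the patch
fixture defaults (radius 9–16 px, ~200–800 px² areas) are realistic free
parameters, not calibrated values.

## Numerical choices and problem sizes

Fixed tolerances and conventions, all asserted or logged: OD epsilon 1;
texture oracle agreement 1e−10; glmnet convergence threshold 1e−9 with
1e5 iterations; kappa degenerate case (chance agreement 1) defined as 1
for perfect agreement else 0, with a warning. The test suite runs at desk
scale — patches up to 400², cohorts up to 5000 cases, 100-region texture
oracles, 200-replicate Cox coverage — sizes chosen so the whole suite
completes in a few minutes while keeping Monte-Carlo error well inside the
asserted bounds.

## Known limitations

* The packaged published model cannot be calibrated without the original
  training standardization parameters.
* The stain-normalization method is a declared stand-in; the original
  nonlinear mapping is not reproduced.
* Segmentation defaults are tuned on the synthetic chromogens; real slides
  will need the window, offsets and hue band revisited.
* The pipeline starts from exported ROI images; whole-slide formats
  (SVS/NDPI) and automated ROI detection are out of scope.
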