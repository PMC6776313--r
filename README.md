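# rccgrade

Automated two-tier nuclear grading of clear cell renal cell carcinoma
(ccRCC) from H&E histology, with the statistics needed to evaluate such a
system.

Fuhrman grading of ccRCC (nuclear size, nucleolar prominence, membrane
irregularity, grades 1–4) suffers from poor inter-observer agreement even
between experienced pathologists. `rccgrade` implements a quantitative
alternative for researchers in computational pathology:

* **Segmentation** — H&E patches are converted to HSV, adaptively
  thresholded per channel with a 2-of-3 vote, and touching nuclei are
  split by marker-controlled watershed on the distance transform; nuclei
  outside the 200–2000 px area band are excluded.
* **Histomics** — 72 features per patch: 9 morphological (area, roundness,
  elongation, flatness, perimeter, equivalent spherical perimeter/radius,
  ellipse axes), 15 intensity (mean, median, SD, skewness, kurtosis × 3
  channels) and 48 texture (8 gray-level co-occurrence + 8 run-length
  statistics × 3 channels), on the HSV value, Lab lightness and
  color-deconvolved hematoxylin channels.
* **Summarization** — per-ROI median and raw MAD of each feature (144
  summarized features); the case grade is the maximum over its ROIs and
  the representative ROI minimizes Euclidean distance to the top-grade
  median.
* **Classification** — an L1-penalized logistic model
  (minimize mean NLL + λ‖w‖₁) over the 144 features, with λ tuned by 100
  stratified random 90/10 holdouts on mean ROC AUC; low = grades 1–2,
  high = 3–4. The published 26-coefficient set (18 unique features,
  λ = 0.0101) ships as packaged data.
* **Evaluation** — confusion-matrix metrics, ROC AUC, Cohen's and Fleiss'
  kappa, majority-vote consensus, Kaplan–Meier curves and crude/adjusted
  Cox proportional-hazards models of grade vs overall survival.
* **Synthetic fixtures** — `render_patch()` draws H&E-like patches with
  ground-truth nuclei masks via inverse Beer–Lambert staining;
  `generate_cohort()` simulates feature/grade/survival tables with a
  configurable true hazard ratio, so the whole pipeline is testable
  without slide data.

## Worked example

```r
library(rccgrade)

# Render a synthetic H&E patch with 8 nuclei, segment, extract features
specs <- random_nucleus_specs(8, size = c(300, 300), radius = c(10, 16),
                              seed = 1)
sp <- render_patch(specs, size = c(300, 300), seed = 1)
mask <- segment_patch(sp$image, segmentation_params())
max(mask)
#> [1] 8
feats <- patch_features(sp$image, mask)
round(feats[c("morph_area", "morph_elongation", "int_mean_he",
              "tex_energy_he")], 3)
#>       morph_area morph_elongation      int_mean_he    tex_energy_he
#>          427.125            1.369            0.789            0.005
```

All 8 rendered nuclei are recovered; the mean nucleus covers 427 px with
elongation 1.37, a mean hematoxylin OD of 0.79, and low GLCM energy
(0.005, i.e. textured chromatin). Summaries and the agreement/survival
statistics follow the same style:

```r
p1   <- c(rep("low", 162), rep("high", 115), rep("high", 90), rep("low", 28))
tcga <- c(rep("low", 162), rep("high", 115), rep("low", 90), rep("high", 28))
tab <- cross_tabulate(p1, tcga, levels = c("low", "high"))
round(agreement_frequency(tab), 2); round(cohen_kappa(tab), 2)
#> [1] 0.7
#> [1] 0.41

co <- generate_cohort(n_cases = 2000, hazard_ratio = 2, censor_rate = 0.3,
                      n_features = 2, seed = 1)
cox_fit(co, covariates = "grade", grade_col = "grade_true")
#>         term       hr ci_lower ci_upper           p
#> 1 grade_high 1.994705 1.787815 2.225536 4.34757e-35
```

The two-rater table reproduces moderate two-tier agreement (0.70, kappa
0.41), and the Cox model recovers the simulated hazard ratio of 2 for
high-grade cases.

A thin command-line wrapper over the same functions is installed at
`inst/cli/rccgrade.R` with verbs `simulate`, `segment`, `features`,
`summarize`, `predict`, `evaluate`, `agree`, `survival` and `run`; the
`run` verb drives `run_pipeline()` end to end from a ROI table and writes
summaries, predictions, evaluation and prognosis reports plus a checksum
manifest.

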