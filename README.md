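# qustc — quantitative ultrasound descriptors for breast lesion characterization

Breast tumors alter the microstructure of the tissue they grow in, and that
microstructure leaves quantitative fingerprints in raw ultrasound
radiofrequency (RF) echoes — fingerprints that survive where B-mode images
depend on scanner settings and reader experience. `qustc` implements the
three descriptor families used to characterize breast lesions from
intratumoral RF data, and the machinery to evaluate them as a classifier of
benign versus malignant tissue:

* **Spectral parameters** — a line `P(f) = I + s·f` is fitted to the dB power
  spectrum of sliding Hamming-windowed RF segments (2.4 mm, 87.5% overlap)
  over the −6 dB band, giving spectral slope (SL), intercept (INT) and
  midband fit `M = I + s·f₀` (MBF) parametric images, with linear
  frequency-dependent attenuation compensation `s′ = s + 2αd`
  (α in dB/MHz-cm, d = one-way depth). Features: intratumoral mean and sd of
  each image.
* **Envelope statistics** — Nakagami shape and scale by intensity moments
  (`Ω = E[R²]`, `m = Ω²/var(R²)`, constrained `m ≥ 0.5`), the derived
  effective cross-section `α_s = ½√(Ω(1−m)/(2m))`, and homodyned-K
  parameters `k` (coherent-to-diffuse ratio), `μ` (effective scatterer
  number) and `h = 1/(k+1)`, estimated by matching SNR/skewness/kurtosis of
  fractional-order moments (ν = 0.72, 0.88) against a Monte-Carlo level-curve
  table.
* **Texture** — gray-level co-occurrence features (contrast, correlation,
  energy, homogeneity) of the 16-level-quantized envelope in the lesion's
  bounding rectangle, averaged over distances 1–5 and angles 0°–135°.

Around the 16-feature table the package provides SMOTE and Tomek-link
resampling (and their exact-balance hybrid) for imbalanced cohorts,
Wilcoxon rank-sum screening, sequential forward selection, and KNN
(Mahalanobis) / linear-SVM / random-forest evaluation under holdout,
stratified 10-fold and leave-one-out validation with ROC/AUC reporting.
A synthetic-RF generator with known ground truth makes every stage testable
without clinical recordings. It is aimed at QUS researchers who want a
tested, scriptable reference implementation of this pipeline in R.

## Worked example

Simulate a balanced 48 benign / 52 malignant cohort at the feature level,
screen the features, select with SFS on a stratified 60% training split and
evaluate on the held-out 40%:

```r
library(qustc)

ft  <- simulate_feature_table(n_benign = 48, n_malignant = 52, seed = 1)
res <- run_study(ft, "study_out", classifier = classifier_spec("knn"), seed = 1)

res$sfs
#> <sfs_trace>
#>   1. nak_alpha            criterion 0.1500
#>   2. mbf_mean             criterion 0.1000
#>   3. mbf_sd               criterion 0.0833

res$reports$holdout
#> <eval_report holdout(0.6)> accuracy 80.00%  sensitivity 66.67%  specificity 94.74%  AUC 0.855 (95% CI 0.722-0.956)

subset(res$screen, tier == "**")
#>      feature            p tier
#> 10     nak_m 9.159729e-07   **
#> 11 nak_omega 2.332271e-08   **
#> 12 nak_alpha 1.623282e-10   **
```

The SFS trace reads: the Nakagami cross-section alone misclassifies 15% of
training lesions under 10-fold CV; adding the mean midband fit drops that to
10%, a third feature to 8.3%, after which no candidate improves. The holdout
report gives pooled test-set metrics (malignant is the positive class) with
a stratified-bootstrap AUC confidence interval. The screen flags the
envelope-statistics features as the strongest discriminators on this
simulated cohort — consistent with how the class separation was generated.

The same functions run from RF data: build lesions with
`simulate_lesion_cohort()` (or `load_rf_dataset()` for the plain-text
container dialect), extract the 16 descriptors per lesion with
`extract_all_features(lesions, build_hk_lookup())`, and pass the result to
`run_study()`. For an imbalanced cohort, `resample = "smote_tomek"`
additionally evaluates the selected features under 10-fold stratified CV
and LOOCV after exact-balance hybrid resampling.

## Layout

```
R/                  implementation (data model, synthetic RF, spectral,
                    envelope statistics, texture, resampling, model
                    evaluation, pipeline)
tests/testthat/     unit, property and acceptance tests with independent
                    oracles (brute-force GLCM counting, greedy-search
                    replay, quadrature of the homodyned-K density)
vignettes/          methods vignette: models, estimators, design decisions
scripts/            acceptance script
```
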