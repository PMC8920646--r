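---
title: "Intratumoral QUS descriptors: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intratumoral QUS descriptors: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`qustc` computes quantitative ultrasound (QUS) descriptors of breast lesions
from raw radiofrequency (RF) echo frames and evaluates them as classifiers of
benign versus malignant tissue. This vignette is the package's account of the
underlying models, the estimators and their numerical details, and the design
decisions taken where the methodology was genuinely open.

## The three descriptor families

**Spectral parameters.** A Hamming window of 2.4 mm slides down each RF line
with 87.5% overlap. The one-sided periodogram of each windowed segment is
expressed in dB and a line

$$P(f) = I + s f$$

is fitted by ordinary least squares over the usable band, defined as the
contiguous interval within 6 dB of the spectral peak of the frame-averaged
spectrum. The slope $s$ (dB/MHz), intercept $I$ (dB, value at $f = 0$) and
midband fit $M = I + s f_0$ (dB, $f_0$ = band center) form three parametric
images on the window grid. Frequency-dependent attenuation, assumed linear in
frequency with coefficient $\alpha$ (dB/MHz-cm, default 1.0, a muscle-like
effective value), tilts the measured spectrum by $-2\alpha d$ over a one-way
depth $d$; the intercept is invariant under such attenuation. The correction
adds $2\alpha d$ back to the slope (`correction_sign = "compensate"`). The
sign of this term is printed ambiguously in parts of the QUS literature, so
the subtractive form is available as `"paper_literal"`; only the compensating
sign makes the corrected slope depth-stationary on attenuated simulated
frames, which is what the package's tests verify. The lesion features are the
intratumoral mean and standard deviation (n−1 denominator) of the MBF, INT
and SL images — six numbers.

**Envelope statistics.** The echo envelope is the magnitude of the per-line
analytic signal. Two amplitude models are fitted on *all* intratumoral
envelope samples (whole-tumor fitting; windowed fitting is a deliberate
non-goal — pooling all samples stabilizes the estimates at the cost of
ignoring intra-tumor attenuation):

* *Nakagami*: $\Omega = E[R^2]$ and $m = \Omega^2 / \mathrm{var}(R^2)$ by
  intensity moments (population denominator). In constrained mode $m$ is
  clipped from below at 0.5, the lower bound of the Nakagami family, with a
  flag. The derived effective scatterer cross-section uses the K-distribution
  correspondence $M = 2m/(1-m)$, giving
  $\alpha_s = \tfrac12\sqrt{\Omega(1-m)/(2m)}$, defined only for $0 < m < 1$.
* *Homodyned K*: parameters $k = s/\sigma$ (coherent-to-diffuse ratio),
  $\mu$ (effective scatterers per resolution cell) and $h = 1/(k+1)$
  (diffuse-to-total power ratio, an exact identity of the estimate). The
  estimator matches SNR, skewness and kurtosis of the fractional-order
  amplitude moments $A^{0.72}$ and $A^{0.88}$ against a Monte-Carlo level-curve
  table (below).

**Texture.** The envelope inside the minimum bounding rectangle of the lesion
mask is linearly quantized to 16 gray levels over its own range (which makes
the features invariant to amplitude offset and scale). Directed gray-level
co-occurrence matrices are accumulated at distances 1–5 pixels and angles
0°/45°/90°/135° — 20 matrices — and contrast, correlation, energy and
homogeneity are averaged over all 20. The homogeneity kernel uses
$1/(1+|i-j|)$; the asymmetric form sometimes printed ($1+i-j$) can be
nonpositive. Correlation is undefined for degenerate marginals and such
matrices are excluded from its average.

The canonical feature order is fixed package-wide
(`qus_feature_names()`): six spectral statistics, $k, \mu, h$,
$m, \Omega, \alpha_s$, then the four texture features.

## The homodyned-K lookup table

Closed-form fractional-moment statistics of the homodyned-K family are
awkward; the package instead builds the level curves by Monte Carlo.
At every node of a grid over $k \in [0, 3]$ (61 linear nodes) and
$\mu \in [0.01, 10^4]$ (81 log-spaced nodes), $10^5$ amplitudes are drawn
from the compound sampler ($A = |k\sigma + g(z_1 + i z_2)/\sqrt2|$ with
$g^2 \sim \Gamma(\mu, \sigma^2/\mu)$) at $\sigma^2 = 1$; SNR, skewness and
kurtosis of $A^{0.72}$ and $A^{0.88}$ are tabulated. All three statistics are
scale invariant, so one table serves any amplitude scale; a fixed seed makes
the table bit-identical. The sampler itself is validated in the test suite
against deterministic quadrature of the homodyned-K density (the conditional
Rician density integrated over the gamma mixing law), keeping the estimator's
correctness independent of any special-function implementation.

Estimation minimizes the summed squared *relative* deviation of the six
statistics over the grid. Two numerical details matter:

* **Rayleigh-limit guard.** Near $k = 0$ and large $\mu$ the model is weakly
  identified: a ridge of $(k, \mu)$ pairs with growing $k$ and growing $\mu$
  reproduces Rayleigh-like statistics almost exactly, so the raw argmin can
  report spurious coherence ($k \approx 0.45$) for a genuinely diffuse
  envelope. The estimator therefore estimates the per-statistic sampling
  error from the sample (10-block splitting, inflated for the table's own
  Monte-Carlo error) and, whenever some purely diffuse node ($k = 0$)
  reproduces *every* statistic within three standard errors, prefers that
  diffuse explanation. Because the amplitude SNR is measured to a relative
  precision of about 0.2% at $n = 10^5$, genuinely coherent envelopes
  (e.g. $k = 0.5$) reject $k = 0$ decisively and are unaffected. This is
  also why the $\mu$ grid extends to $10^4$ rather than stopping at the
  largest physically interpretable values: the top decades exist so the
  grid can represent "Rayleigh or beyond" at $k = 0$.
* **Sub-grid refinement.** The winning coordinates are refined by parabolic
  interpolation of the objective along each axis ($\mu$ on the log scale),
  with the offset clamped to half a cell; edge nodes are not refined.

Parameter-recovery accuracy is bounded by the grid pitch (0.05 in $k$,
factor 1.19 in $\mu$) plus Monte-Carlo noise; the tests require median
errors below 0.1 in $k$ and below a factor 1.5 in $\mu$ over a
$3 \times 3$ design at $n = 10^5$, and the observed medians are several
times smaller.

## The synthetic-RF generator

`simulate_rf_frame()` emulates only what the descriptor pipeline consumes: a
Gaussian-modulated cosine pulse (−6 dB fractional bandwidth 0.5 by default)
convolved with a sparse scatterer train per line — Poisson counts per axial
sample at the density implied by `scatterers_per_cell`, standard normal
amplitudes — plus an optional constant-phase periodic component (one spike
per resolution cell, amplitude $k\sqrt{\mu_{\text{cell}}}$, which sets the
coherent-to-diffuse energy ratio to approximately $k^2$), and linear
frequency-dependent attenuation applied in the frequency domain per depth
block with the round-trip factor 2 ($10^{-2\alpha d f/20}$ in amplitude,
$d$ one-way depth in cm). An axis-aligned elliptical lesion occupies the
middle of the frame and may carry different scatterer statistics. Default
acquisition values (40 MHz sampling, 10 MHz center frequency, 1540 m/s)
mirror a modern linear-array breast acquisition.

The resolution cell is the pulse's −6 dB envelope length. Because the
Gaussian pulse weights scatterer contributions smoothly, the *effective*
number of scatterers per cell is roughly 2.5 per nominal unit density times
the cell length — lower than the nominal `scatterers_per_cell` — so nominal
counts understate the effective count and `scatterers_per_cell = 10` still
produces a visibly pre-Rayleigh envelope ($\hat m \approx 0.75$). Tests that
need fully developed speckle use dense settings (60 per cell). Ground truth
(all generating parameters plus the realized cell length) is returned with
every frame.

What the generator does *not* model: diffraction and beam formation, a
depth-dependent point-spread function, electronic noise, tissue
inhomogeneity outside the lesion ellipse, and scan conversion. Passing tests
on simulated frames therefore demonstrate the *estimators'* correctness
under the stated scattering model, not clinical-grade realism.

`simulate_feature_table()` bypasses RF entirely: it draws independent normal
feature values per class around the class means and standard deviations
observed on a balanced clinical breast cohort (its defaults), clipped to
each feature's valid range, with configurable class counts — 104/26
reproduces the 4:1 imbalance scenario. It exists so the resampling/selection/
evaluation stages can be exercised at scale; its independence assumption
(no inter-feature correlation) is a known simplification.

## Resampling, selection, evaluation

**SMOTE** synthesizes minority samples by convex interpolation toward one of
the $T = 5$ nearest minority neighbors, base samples cycled round-robin,
$\lambda \sim U[0,1]$. **Tomek links** are mutual-nearest-neighbor pairs of
opposite classes; undersampling removes the majority member of each link.
Both use Euclidean distance on z-scored features, because the 16 descriptors
span about six orders of magnitude and unscaled distances would be dominated
by $\Omega$. The **hybrid** applies Tomek first and then SMOTE up to the
reduced majority count, leaving the classes exactly balanced (104/26 with 11
links removed becomes 93/93); the reverse order is available behind a flag.
Full-dataset resampling before cross-validation replicates the study design
it models and is the default for that purpose, but it leaks synthetic
samples into test folds — the package warns, and a `"within_fold"` mode
confines resampling to each training fold.

**Sequential forward selection** is a greedy wrapper: a candidate feature is
accepted only if it strictly lowers the misclassification rate, ties broken
toward the lower feature index; the default evaluator is pooled 10-fold
stratified CV error with fold assignment fixed by the seed (the criterion's
estimation protocol is otherwise unspecified in the methodology the package
follows). **Classifiers**: 5-NN with Mahalanobis distance (whitening by the
Cholesky factor of the ridge-regularized training covariance; the score is
the malignant vote fraction), linear SVM (cost 1 on standardized inputs,
signed margin as score), and a 100-tree seeded random forest (malignant tree
fraction). **Evaluation** pools out-of-fold scores and computes one ROC,
trapezoidal AUC with a stratified-bootstrap 95% CI (2000 replicates,
seeded), and confusion-derived accuracy/sensitivity/specificity in percent,
with malignant as the positive class throughout. Rank-sum screening uses the
two-sided Wilcoxon test (exact enumeration for combined n ≤ 12 without
ties; normal approximation with tie correction otherwise) with tiers `~`
(p ≥ 0.05), `*` (p < 0.05), `**` (p < 0.001).

## Numerical choices and degenerate inputs

* Variance denominators: population ($n$) inside the Nakagami moment
  estimator and the fractional-moment statistics; descriptive ($n-1$) for
  ROI statistics. Mixing the two silently is a classic source of
  irreproducibility, so both are documented and tested.
* All-zero spectra are floored at a configurable dB floor and flagged; a
  single-pixel ROI has sd defined as 0 with a warning; constant ROIs
  quantize to level 1 with a degenerate flag, and their all-undefined
  correlation is an error at the averaging stage.
* The usable band is fixed once per frame from the frame-average spectrum,
  keeping $f_0$ constant within a frame; spectra are computed per line with
  no lateral averaging.
* The intratumoral mask drawn on the RF grid maps to the window grid by the
  nearest-window rule (mask value at the RF sample nearest each window
  center).
* Depth is measured from the first axial sample to the window center,
  one-way, in cm.
* Seeds propagate to every stochastic stage (samplers, table construction,
  fold assignment, resampler, bootstrap); fixed seeds give bit-identical
  artifacts.

## Problem sizes used by the test suite

The suite validates estimator recovery at $n = 10^5$ envelope samples (the
scale of a whole-tumor fit), RF frames of 48–128 lines × 1536–3000 samples,
a $3\times3$ homodyned-K design with 20 seeds per cell, 60 constrained
Nakagami fits at $n = 10^4$, 200 random images for the GLCM oracle, and 10
replicate 4:1 cohorts for the imbalance study. These sizes were chosen as
the smallest at which the Monte-Carlo tolerances above are comfortably
resolved.

## Known limitations

* No reference-phantom normalization: spectra are raw dB periodograms; a
  hook for reference-spectrum subtraction exists but system and diffraction
  effects are otherwise uncompensated (appropriate when lesions lie at
  similar depths).
* Whole-tumor envelope fitting ignores intra-tumor attenuation gradients.
* The feature-table simulator draws features independently; real QUS
  descriptors are correlated (e.g. $h$ is a deterministic function of $k$).
* Near the Rayleigh ridge the homodyned-K $(k, \mu)$ decomposition is
  intrinsically ill-posed; the diffuse-preference rule is a documented
  convention, not extra information.
* MAT/HDF5 RF containers are out of scope for I/O; the plain-text directory
  dialect (`write_rf_dataset()`) covers the package's own round-trip needs.
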