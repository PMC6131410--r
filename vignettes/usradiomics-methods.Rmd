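---
title: "Texture radiomics for breast ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture radiomics for breast ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usradiomics)
```

## The problem

Triple-negative breast cancer (TNBC) frequently presents on grayscale
ultrasound with the morphology of a benign lesion — oval or round shape,
circumscribed margins — and is therefore at risk of being mistaken for a
fibroadenoma and worked up too slowly. The premise of texture radiomics is
that even when the *shape* is uninformative, the spatial statistics of the
echo texture inside the lesion still carry class information that the eye
cannot use. This package implements that analysis end to end: a
730-dimensional texture signature per lesion, a sparse logistic "radiomics
score" trained on it, a score-to-probability conversion, and the
reproducibility and reporting analyses that belong with such a score.

Because patient ultrasound images cannot be redistributed, the package
also contains a first-class synthetic lesion simulator. Every claim the
test suite makes is made against simulated cohorts whose generating
process is documented below — which is exactly what the tests do and do
not show about clinical data (see *Limitations*).

## The feature signature

The signature is `14 + 132 + 584 = 730` named features per lesion, built
from an 8-bit grayscale image and a binary ROI mask.

**First-order (14).** Statistics of the raw in-ROI intensity multiset:
energy, entropy, kurtosis, maximum, mean, mean absolute deviation,
median, minimum, range, root mean square, skewness, standard deviation,
uniformity, variance. Moments are population (1/N) moments and kurtosis
is non-excess (a Gaussian scores 3). Entropy and uniformity are computed
from an equal-width histogram with `Ng` bins over the in-ROI range, the
same `Ng` used for the texture matrices, so that the two feature families
share one discretization. A zero-variance ROI defines skewness and
kurtosis as 0 rather than NaN so downstream standardization never
propagates non-finite values.

**Texture (132).** In-ROI intensities are quantized to `Ng` equal-width
gray levels over the in-ROI range (`level = 1 + floor((x - min)/w)`,
capped at `Ng`; a constant ROI maps to level 1). From the quantized patch
we build, at each of the four directions 0°, 45°, 90°, 135°:

* a symmetric, normalized gray-level co-occurrence matrix (GLCM) at
  distance 1, counting only pixel pairs with **both** endpoints in the
  ROI, and 22 features on it (autocorrelation, the three cluster moments,
  contrast, correlation, difference entropy, dissimilarity, energy,
  entropy, two homogeneities, IMC1/IMC2, IDMN/IDN, inverse variance,
  maximum probability, sum average/entropy/variance, variance);
* a gray-level run-length matrix (GLRLM) of maximal equal-level runs,
  broken by the mask boundary and the image edge, and 11 features on it
  (SRE, LRE, GLN, RLN, run percentage, LGLRE, HGLRE and the four joint
  emphases).

Image rows grow downward, so the direction offsets are 0° = (0, 1),
45° = (−1, 1), 90° = (−1, 0), 135° = (−1, −1). Gray-level indices run
1..`Ng` in every formula; all logarithms are base 2 with an additive
guard of 1e−12; correlation is defined 0 when a marginal SD is 0 and
IMC1 is 0 when both marginal entropies vanish.

**Wavelet (584).** A one-level separable 2-D coiflet decomposition
splits the image into LL/LH/HL/HH subbands (first letter = filter along
the row index). The ROI is mapped to the half-resolution grid by 2×2
max-pooling, and the 146 features above are recomputed on each subband:
first-order on the raw in-mask coefficients, texture on coefficients
re-quantized to `Ng` equal-width levels over the in-mask coefficient
range (subband coefficients are signed, so the 8-bit binning cannot be
reused).

### Numerical choices

* **Quantization level `Ng = 64`** by default, configurable. Equal-width
  binning over the in-mask range is the common radiomics convention; it
  makes the texture block invariant to affine intensity shifts that do
  not clip.
* **Coiflet order**: `coif1` (6 taps) by default, `coif2` available. The
  filter coefficients are the standard published values and are
  orthonormal to machine precision.
* **Wavelet boundary**: the default is **periodization**, which makes the
  one-level transform exactly orthogonal — the inverse transform
  reconstructs the image to machine precision and the four subband
  energies sum to the image energy. A half-point symmetric extension is
  also implemented (analysis only) for users who prefer it near strong
  boundary gradients, but it inflates the coefficient count and breaks
  exact energy bookkeeping, which is why it is not the default. Odd image
  dimensions are padded by edge replication and cropped on
  reconstruction.
* **Ties and degenerate inputs**: single-pixel ROIs cannot form pixel
  pairs and are rejected with the direction named; ROIs below 16 pixels
  are rejected outright; a constant ROI is legal everywhere and produces
  the degenerate feature values stated above.

## The radiomics score

Let \(x\) be the 730-vector of features, \(z\) its per-feature z-score
under training-set statistics, and \(y \in \{0, 1\}\) the pathology
(1 = TNBC). The model is L1-penalized logistic regression

\[
\min_{\beta_0, \beta}\;
\frac{1}{n}\sum_i \log\!\left(1 + e^{\beta_0 + z_i^\top\beta}\right)
 - y_i(\beta_0 + z_i^\top\beta)
\; + \; \lambda \lVert \beta \rVert_1 ,
\]

solved by coordinate descent inside iteratively reweighted least squares
with an unpenalized intercept, warm starts along a decreasing
\(\lambda\) path, strong-rule screening with KKT verification, an
active-set inner loop, and convergence when the largest coefficient
change falls below 1e−7. Inside CV folds the tolerance is relaxed to
1e−5: fold fits only feed the AUC ranking of the grid, which we verified
is unchanged by the relaxation, and the final refit always uses 1e−7. The tuning parameter
\(\lambda\) is chosen to **maximize the mean out-of-fold AUC** under
stratified 10-fold cross-validation; standardization and the AUC are
computed inside each fold from fold-training statistics only, so no
information leaks from held-out lesions. The test suite verifies this
with a permuted-label check read in the sparse (1–30 selected) regime of
the CV curve: leakage through fold-external standardization or selection
inflates exactly that regime, whereas the two chance artifacts of a
p ≫ n path — the winner's curse at the selection maximum and the
below-chance drift of the deeply overfit tail — are properties of an
honest CV curve, not of leakage, and are excluded by construction. The grid is 100 log-spaced values from
\(\lambda_{\max}\) — the smallest \(\lambda\) whose solution is all-zero,
\(\max_j |\langle z_j, y - \bar y\rangle| / n\) — down to
\(10^{-3}\lambda_{\max}\); ties on the CV curve break toward the larger
(sparser) \(\lambda\).

The **radiomics score** of a lesion is the pure linear combination
\(s = \sum_k \beta_k z_k\) over the selected features. The intercept is
deliberately excluded: the score is mapped to a predicted malignancy
probability by a separate univariate logistic calibration with its own
intercept,

\[
\hat p = \frac{e^{a + b s}}{1 + e^{a + b s}} \times 100 ,
\]

whose default constants \(a = 0.6985\), \(b = 1.6381\) are the published
conversion for this signature; `calibrate_score()` refits \((a, b)\) on a
new cohort. AUCs are tie-corrected Mann–Whitney statistics with DeLong
confidence intervals (the CI method is this package's choice). Cohort
comparisons use the conventional tests: pooled-variance Student's t and
chi-square for split balance, Kruskal–Wallis for scores across machines,
Mann–Whitney for scores by pathology within subgroups.

Two design questions had no authoritative answer and were decided here:
whether the score uses standardized or raw features (standardized — the
penalty is only meaningful on a common scale), and whether CV folds are
stratified (yes — with a 20% event rate, unstratified folds at cohort
sizes of a few hundred regularly produce event-free validation folds).

## The synthetic cohort generator

The generator is the package's stand-in for the non-deposited patient
images and defines the conditions under which every downstream claim is
tested.

* **Speckle.** B-mode texture is simulated as the modulus of a complex
  Gaussian field smoothed by an isotropic Gaussian kernel whose width
  `correlation_length_px` is the speckle correlation length. This is the
  simplest model with Rayleigh-type amplitude statistics and a tunable
  spatial correlation — precisely the property the texture features
  measure. It deliberately omits beam physics (no point-spread
  anisotropy, no attenuation, no harmonic imaging).
* **Lesion geometry.** A perturbed ellipse (radial Fourier harmonics 2–5,
  amplitude `boundary_irregularity`, clamped positive) centered in a
  128×128 image, full axes drawn from 20–50 px — a loose analogy to a
  15 mm mean lesion at typical linear-array resolution. Zero
  irregularity gives the exact discretized ellipse. The lesion interior
  is hypoechoic (mean 70 vs background 110 before speckle modulation).
* **Class effect.** The benign-like class draws long correlation lengths
  (2.2–3.0 px) and a homogeneous interior; the malignant-like class
  draws shorter lengths (1.5–2.4 px) and a smooth intra-lesion
  heterogeneity field of amplitude 8–18 intensity units. These ranges
  deliberately border the benign ranges so the classes overlap: a
  perfectly separable default would make the probability calibration
  degenerate and every downstream comparison trivial. The paper
  motivating this package reports no quantitative texture statistics of
  the real classes, so these effect sizes are free parameters chosen
  once to produce clearly separable but overlapping classes — they are
  the *test conditions*, not estimates of clinical reality.
  `default_lesion_priors(effect_size = 0)` removes every between-class
  difference and is the null condition used in the leakage tests.
* **Machines.** Three simulated platforms in proportions 54.6% / 36.1% /
  9.3%, each applying gamma, then gain, then offset, then clipping to
  [0, 255]. The reference machine is the identity; the other two apply
  mild brightness/contrast/gamma shifts. Machine effects act on the
  image only, never the mask.
* **Labels.** Malignancy is Bernoulli(0.206), the TNBC fraction of a
  186-in-901 case mix; BI-RADS categories are drawn from a conditional
  table whose benign column concentrates on 3/4a — this is what makes
  the low-suspicion (3 + 4a) subgroup genuinely harder and reproduces
  the qualitative AUC drop in that subgroup.
* **Determinism.** Every output is a pure function of the supplied
  seeds; lesion seeds are drawn once from the cohort seed, so metadata
  are identical whether or not images are written.

## Interobserver agreement

Feature reproducibility between two ROI readers is summarized by
ICC(2,1): two-way random effects, single measurement, absolute agreement
(the published description says only "two-way random effect model";
absolute agreement is this package's reading, since a systematic offset
between readers *should* count against reproducibility — the test suite
checks that a constant offset strictly lowers the ICC). Confidence
intervals use the F-based formulas with Satterthwaite degrees of freedom.
Since only one human ROI per lesion can exist in a synthetic cohort, the
second reader is simulated by seeded mask perturbation (one-pixel
dilation/erosion plus boundary flips). The summary grid reports min and
max ICC per direction × subband; the 70 first-order features carry no
direction and are reported in a separate row rather than being forced
into a direction (how the original tabulation assigned them is not
stated anywhere we could follow).

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to make the statistical
checks sharp while staying desk-sized: oracle equivalence on 100 random
8–16 px patches; wavelet round-trips on 50 random images; LASSO recovery
on 20 replicates of a 200×50 design with 5 planted signals; an injected
effect cohort of 600 lesions and a null cohort of 400 with a 50/50
split; 5000 null replicates per statistical test for the type-I error
calibration. The demo configuration of `run_all()` uses 300 lesions.

## Limitations

Passing tests on synthetic cohorts demonstrates that the *pipeline* is
correct — the features compute what their definitions say, the CV is
leakage-free, the score separates classes when a second-order texture
difference exists, and machine effects of the modeled kind shift scores
detectably. They do **not** demonstrate clinical performance: real
speckle is anisotropic and depth-dependent, real lesions contain
structures (septa, posterior enhancement) the simulator omits, and the
published clinical AUCs depend on the original patient images, which are
not available. The specific features a refit selects on synthetic data
have no clinical meaning. The interobserver analysis measures
sensitivity to the modeled contouring perturbation, not to human
readers.

## The command surface

The package is library-first: `generate_cohort()` → `extract_cohort()` →
`split_train_validation()` → `fit_lasso_logistic()` /
`radiomics_score()` / `score_to_probability()` → `run_analysis()`, with
`run_all()` orchestrating the whole pipeline from a single `run_config()`
(YAML round-trip, manifest with MD5 hashes, byte-reproducible under a
fixed configuration). `scripts/acceptance.R` recomputes the published
worked-example probabilities from an installed copy of the package.
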