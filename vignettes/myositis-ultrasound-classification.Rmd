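---
title: "Quantitative muscle ultrasound for myositis classification: methods and design"
author: "myoUS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative muscle ultrasound for myositis classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoUS)
```

## The problem

Inflammatory myopathies — polymyositis (PM), dermatomyositis (DM) and the
treatment-refractory inclusion body myositis (IBM) — change the appearance of
muscle on B-mode ultrasound: chronic disease replaces muscle with fat and
fibrous tissue, raising echointensity; acute edema alters texture without
necessarily raising brightness. `myoUS` implements a semi-automated,
feature-based pipeline for classifying muscle ultrasound images into
diagnostic groups, together with a synthetic speckle-phantom generator so the
whole pipeline can be exercised and validated without clinical images.

The acquisition protocol the package models images **seven muscle groups
bilaterally** (deltoid, biceps, flexor carpi radialis, flexor digitorum
profundus, rectus femoris, tibialis anterior, gastrocnemius), up to **three
transverse views** per muscle, at 4 cm depth (476 × 499 pixels) except the
rectus femoris at 6 cm (318 × 499). Each image comes with a clinician-drawn
segmentation of the muscle belly and the overlying subcutaneous fat
(background = 0, muscle = 1, fat = 2; PNG/TIFF label rasters or ITK-Snap
NIfTI exports are accepted).

Three binary problems are studied on one cohort of 80 subjects
(33 N / 14 PM / 14 DM / 19 IBM):

| Problem | Cohort | Contrast | Subjects |
|---|---|---|---|
| A | all | normal vs any myositis | 80 |
| B | N + IBM | normal vs IBM | 52 |
| C | PM + DM + IBM | other myositis vs IBM | 47 |

The positive class (A: affected; B and C: IBM) is the package's convention —
the clinically natural "disease present / refractory subtype" direction —
and is overridable in `problemSpec()`.

## The 22-element feature vector

For each image, `assembleFeatureVector()` computes, in fixed order:

1. **Echointensity (5):** mean and sample SD of muscle and of fat pixel
   intensities, and the ratio of the two means. The ratio normalizes for
   gain differences between acquisitions.
2. **Nakagami speckle parameters (4):** shape `m` and scale `ω` for muscle
   and for fat. The Nakagami distribution (support `m ≥ 0.5`,
   `ω = E[X²]`) models ultrasound echo amplitude; `m` indexes scattering
   conditions (m = 1 is fully developed Rayleigh speckle) and `ω` the
   backscattered energy. We use the closed-form inverse-normalized-variance
   moment estimator `ω̂ = mean(x²)`, `m̂ = ω̂²/var(x²)` — deterministic,
   fast, and accurate to a few percent at region sizes of 10³–10⁵ pixels
   (verified against simulation in the test suite). Estimates below 0.5 are
   clamped to the support bound with a warning. Pixel intensities are
   treated directly as amplitude samples; real B-mode pixels are
   log-compressed, so on clinical data the fitted parameters are effective
   descriptors of the compressed image rather than of the raw echo — a
   deliberate simplification consistent with feeding the same pixels to the
   other features.
3. **Haralick texture (13):** the classical gray-level co-occurrence (GLCM)
   statistics — angular second moment, contrast, correlation, sum-of-squares
   variance, inverse difference moment, sum average, sum variance, sum
   entropy, entropy, difference variance, difference entropy, and the two
   information measures of correlation. The 14th classical feature (maximal
   correlation coefficient) is excluded; the feature set is defined as 13.

### GLCM conventions

No standard fixes every GLCM detail, so the package pins them in
`glcmConfig()` and logs them with every run:

* **32 gray levels**, uniform bins over the *region's own* min–max (hence
  invariance to adding a constant to all pixels);
* distance 1, four directions (0°, 45°, 90°, 135°), **symmetric**
  accumulation, counting only pairs with *both* pixels inside the requested
  tissue label (muscle by default — configurable, since computing texture on
  fat or the whole image are defensible alternatives);
* each directional GLCM is normalized to sum to 1 before statistics; the 13
  statistics are averaged across directions;
* natural logarithms; levels indexed 1..G; *sum variance* is taken about the
  sum average (not Haralick's original sum-entropy reference point);
  correlation and IMC1 of a single-level (constant-region) GLCM are defined
  as 0, where the textbook formulas are 0/0.

Every statistic is verified against a brute-force pair-enumeration oracle to
10⁻¹⁰ in the test suite.

Open interpretation: with 22 = 5 + 13 + 4, the Nakagami pair must be fitted
to **both** tissues; the ordering of the vector and the muscle-region default
for Haralick are package conventions.

## Classification

`trainEnsemble()` fits a random forest (Breiman's original algorithm via the
`randomForest` package): 500 trees, `floor(sqrt(22)) = 4` candidate features
per split, unlimited depth, bootstrap resampling. These are standard-practice
defaults; no hyperparameter search is performed, and the acceptance
properties below are expected to hold across reasonable settings. The score
of an image is the fraction of trees voting for the positive class;
the label is positive at score ≥ 0.5 (majority vote — a single fixed
operating point, no threshold tuning). Training is deterministic given the
recorded seed.

## Evaluation: grouped five-fold cross-validation

The unit that must never straddle a train/test boundary is the **muscle
entity** — one subject's one muscle on one side — because its 1–3 views are
near-duplicates. `assignFolds()` shuffles entities (seeded), stratifies by
class label, and deals them round-robin to `N = 5` folds; fold sizes differ
by at most one entity. Stratification is an addition over plain random
splitting, disclosed here because it prevents single-class folds in small
cohorts; a fold whose test images carry a single truth class is a hard
error, not a silent NaN.

Each fold's held-out images are predicted by a forest trained on the other
folds; per-fold confusion counts give the eight metrics: accuracy,
sensitivity, specificity, PPV, NPV, Cohen's κ (chance-corrected agreement
with expected agreement from the marginal products), LR+ = sens/(1 − spec)
and LR− = (1 − sens)/spec. The report contains the **mean and sample SD
across folds** (under a Gaussian reading, ±2 SD approximates a 95%
confidence band). Averaging per-fold values, rather than pooling
predictions, matches the protocol being modelled; note it makes the mean
LR+ differ from the LR+ of the mean sensitivity/specificity. A perfect fold
yields the `Inf` sentinel for LR+, which then propagates to the mean — this
is reported as-is rather than masked. Metrics are per image; no per-muscle
or per-patient vote aggregation is performed.

### The subject-identity leakage channel

Entity-level grouping still allows the *other* muscles of a test subject to
appear in training. If features carry a subject-specific signature (as real
echointensity does), a classifier can partly *recognize the subject* rather
than the disease, inflating CV estimates even when the class signal is nil.
The package demonstrates this on synthetic data: with between-subject echo
variability switched on (`subjectSD = 0.15`) and **no class signal at all**
(the `null` preset), entity-grouped CV scores meaningfully above chance
while `grouping = "subject"` returns to chance (a fixed-seed property test
in the suite measures both). For this reason `crossValidate()` exposes
`grouping = "subject"` as a stricter option, with `"muscle"` remaining the
default protocol.

## The synthetic speckle phantom

`generatePhantom()` builds an image whose top `thicknessFraction` (default
25%) is a subcutaneous fat band (label 2) over muscle (label 1); each pixel
is an independent Nakagami draw from its tissue's `(m, ω)`, optionally
Gaussian-smoothed, clipped to [0, 255] and quantized to 8 bits. The mask is
exact. `generateStudy()` replicates the full acquisition design —
subjects × 7 muscles × 2 sides × ≤3 views, per-muscle depth and image size —
and writes PNG images, label masks and a manifest CSV, or returns the study
in memory. With the default 3 views the clinical-roster design yields
80 × 7 × 2 × 3 = 3360 records (the real study had 3214 because a few muscles
had only two views).

Class presets (`classPreset()`) share a fat band (m = 1.2, mean 120) and
differ in muscle speckle:

* `separable` — normal m = 1.8, mean 50; affected m = 0.8, mean 110
  (mimicking the clinical direction: fatty-replaced muscle is brighter and
  its speckle less pre-Rayleigh);
* `overlapping` — affected differs in mean only (70 vs 50), same shape;
* `null` — identical parameters for every diagnosis.

All values are generator conventions, chosen once; they are not clinical
measurements. By default all images of a class are i.i.d. — classes are
pure distributions, so `separable` and `overlapping` are both classified
near-perfectly and `null` sits at chance. Optional lognormal per-subject and
per-entity factors on mean echo (`subjectSD`, `entitySD`; ω scales by the
squared factor) add biological heterogeneity: they make `overlapping`
genuinely intermediate, and they open the leakage channel described above.
Each record draws from an independent substream keyed by
(seed, subject, muscle, side, view), so datasets are bit-reproducible and
changing one diagnosis' parameters regenerates only that diagnosis' images.

What the phantoms deliberately do **not** model: acoustic point-spread
functions, attenuation with depth, bone shadowing, fascia lines, log
compression, or per-muscle anatomy. Passing tests on phantoms therefore
validates the *statistical machinery* (estimators, texture code, grouping,
metrics) — it does not certify clinical performance, which depends on the
real images' far richer structure. Published accuracies on the clinical
dataset (mid-80s % for normal-vs-IBM) are not reproducible from phantoms and
are not targets of this package's checks.

## Numerical and degenerate-input choices

* Sample (n − 1) standard deviations everywhere (features and across-fold
  SDs).
* `fitNakagami()` requires ≥ 10 pixels and non-constant intensities;
  `echoFeatures()` requires ≥ 2 pixels per region and a non-zero fat mean
  (the ratio guard).
* A fat band that rounds to zero rows is a geometry error; an absent tissue
  label is an empty-region error; every error is a classed condition tagged
  with the offending record.
* Fold counts exceeding the number of entities, single-class cohorts,
  single-class folds, and single-class training sets are all hard errors.
* All stochastic stages (generation, fold shuffling, forest training) take
  explicit seeds; per-fold training seeds are `seed + fold`.

## Problem sizes used in the automated checks

The test suite exercises the full pipeline at reduced scale: 256 × 256
phantoms with 20 + 20 subjects and two views (1120 images) for the
end-to-end separable/null checks, and 128 × 128 phantoms with three muscle
groups for the separation-ordering check; unit tests use 24–64 pixel
phantoms. These sizes were chosen so the phantom regions (≥ 10⁴ pixels)
estimate Nakagami and texture parameters with small sampling error while a
full run stays interactive.

## Limitations

* Feature-based classification here is semi-automated: it presumes
  segmentation masks as input and does not attempt to produce them.
* No multi-class mode, no probability calibration, no ROC analysis, and no
  statistical test comparing classifier variants.
* The phantom generator targets the feature model's assumptions, not visual
  realism; conclusions about real tissue require real images.
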