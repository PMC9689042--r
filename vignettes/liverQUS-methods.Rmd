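---
title: "Quantitative ultrasound texture analysis for liver fibrosis staging: models and methods"
author: "liverQUS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{liverQUS methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

B-mode ultrasound of the liver is cheap, safe and ubiquitous, but visual
reading of parenchymal texture is operator-dependent and insensitive to
early fibrosis. Quantitative ultrasound (QUS) radiomics replaces the
visual read with numerical texture features measured in regions of
interest (ROIs), and uses simple supervised classifiers to map those
features to a probability of advanced fibrosis (METAVIR F2--4, class 1)
versus early fibrosis (F0--1, class 0). liverQUS implements that
pipeline end to end -- speckle-image simulation, 16-feature extraction,
Welch t-test screening, three classifiers, and an evaluation layer that
quantifies how train-test sampling choices move the AUC.

Because no public image set accompanies the modeled study design, the
package ships a first-class synthetic cohort generator whose study
conditions are calibrated to the published group moments of a rat
liver-fibrosis cohort; every downstream stage is testable against it
without any download.

## The speckle model

An image is generated as fully developed speckle: a complex
circular-Gaussian scatterer field is convolved with an isotropic
Gaussian point-spread kernel (sigma `psfSigma`, in pixels) and the
envelope magnitude taken. The envelope is then exactly Rayleigh
distributed with scale $\sqrt{\sum_k k^2}$ for the unit-sum kernel $k$,
and its spatial correlation length is set by `psfSigma`
(`rayleighField()` returns both the field and the theoretical scale, so
tests can check the distribution without estimating parameters). An
affine map onto 8 bits places the sample mean (echo intensity) and SD
(heterogeneity) on their targets; clipping and rounding perturb the
moments, so a short fixed-point iteration refines the map and an
explicit calibration-failure error is raised for infeasible target
pairs (e.g. an SD too large for a mean close to zero).

Advanced-class images additionally receive a collagen-septa overlay:
Poisson-distributed random-walk polylines, dilated by a Gaussian
profile and added with a fixed peak brightness. Septae are the
package's rendering of the hyperechoic connective-tissue strands that
make advanced fibrotic parenchyma coarse; early images receive none.

### Study conditions and their calibration

The generator's defaults are the study conditions:

* image 256 x 256, `psfSigma` 2.5 px, shared by both classes;
* early class: echo intensity 35.7 +/- 9.0, heterogeneity 16.9 +/- 2.9
  gray levels (class mean +/- between-image SD);
* advanced class: 56.8 +/- 10.2 and 22.5 +/- 2.6;
* septae (advanced only): density 8 strokes/image, peak brightness 63,
  thickness 1.5 px;
* 5 jittered, non-overlapping 64 x 64 ROIs per image; 100 images per
  class, 5 images per subject.

Per-image targets are drawn from the class Gaussians with the jitter
sample centered and rescaled, so a finite cohort reproduces the class
mean and spread exactly rather than only in expectation. Because ROI
averaging, clipping and the septa overlay bias the *extracted* features
relative to the raw targets, `calibrateGenerator()` iterates a small
pilot cohort and multiplies four gain corrections (echo/heterogeneity
per class) until the extracted class means land within tolerance
(default 5%); the achieved values and iteration count are recorded in
the configuration.

The septa parameters were fixed once, during development, by the same
logic applied to the texture structure: across a parameter grid the
choice minimizes the standardized between-class difference of
co-occurrence contrast (the one feature that should *not* separate the
classes, mirroring the modeled cohort) while keeping the remaining
texture features clearly separated. At the defaults, a calibrated
100+100 cohort typically shows 15--16 of 16 features significant at
p < 0.05, with contrast the weakest effect. The contrast match is a
knife-edge property: with 100 images per class the sampling SE of a
standardized mean difference is about 0.15, so individual cohorts can
show an apparent contrast difference of up to ~0.4 pooled SD even
though the design value is near zero.

What the simulator does *not* emulate: log-compression curves and
scanner post-processing, depth-dependent attenuation and focusing,
anisotropic point-spread functions, vessels and other anatomy, and
within-subject correlation of texture (subjects partition images purely
administratively). Passing tests therefore show that the analysis
pipeline behaves correctly on data with the published first-order
structure and a plausible speckle texture -- not that it would reach the
same numbers on real scanner images.

## Texture features

Sixteen features per ROI, aggregated to one vector per image by
unweighted mean (the image is the statistical unit):

* **First order** -- echo intensity (pixel mean), heterogeneity (sample
  SD), skewness $m_3/m_2^{3/2}$ and excess kurtosis $m_4/m_2^2 - 3$
  from central sample moments (both 0 for constant regions). Excess
  (Fisher) kurtosis is used so near-Gaussian log-compressed speckle
  sits near zero.
* **Run length** -- on the ROI quantized to Ng = 32 levels by per-ROI
  min-max (`floor((x - min) Ng / (max - min + 1))`), runs are maximal
  constant-level collinear pixel segments in each of four directions
  (0, 45, 90, 135 degrees). With $r(i,j)$ the count of runs of level
  $i$ and length $j$, $N_r$ total runs, $N_p$ pixels and $D$
  directions: SRE $= \frac{1}{N_r}\sum r/j^2$, LRE
  $= \frac{1}{N_r}\sum r j^2$, GLN $= \frac{1}{N_r^2}\sum_i(\sum_j
  r)^2$, RLN $= \frac{1}{N_r^2}\sum_j(\sum_i r)^2$, RP $= N_r/(N_p D)$.
  The $1/N_r^2$ (probability-squared) normalization keeps GLN/RLN in
  (0, 1].
* **Co-occurrence (Haralick)** -- symmetric GLCM at distance 1, counts
  pooled over the four directions before normalization. ASM
  $=\sum P^2$, contrast $=\sum(i-j)^2P$, dissimilarity
  $=\sum|i-j|P$, entropy $=-\sum P\ln P$ (natural log), GLCM mean and
  variance of the row marginal, and correlation (defined 0 when a
  marginal SD vanishes).

Numerical conventions worth noting: quantization of a constant ROI maps
to level 0; a ROI thinner than the co-occurrence distance in every
direction is an error ("no pairs"); GLCM/RLM implementations are
vectorized but verified against brute-force pair/run enumeration
oracles in the test suite.

## Feature screening and reporting

`groupCompare()` runs a two-tailed Welch (unequal-variance) two-sample
t-test per feature -- Welch rather than pooled because the modeled
cohort's group SDs are strongly unequal -- and flags p < 0.05. No
multiple-testing correction is applied, matching the modeled analysis;
the report metadata states this explicitly, and reports always carry
the group sizes actually used. `selectFeatures()` returns the
significant subset in canonical order, `normalizedGroupMeans()`
produces min-max-normalized class means for bar-chart comparison
(constant features are flagged and set to 0.5 by convention), and
`featurePerformance()` evaluates each feature as a univariate
classifier at its Youden-optimal threshold, sweeping both orientations
(a feature may decrease with disease) and breaking ties toward higher
specificity.

## Classifiers

All three models standardize features with training-fold statistics
only (no test leakage), and output P(advanced).

* **Logistic regression**: Newton iterations on the ridge-stabilized
  log-likelihood (ridge 1e-8), stopping at a log-likelihood change
  below 1e-8 or 100 iterations. Quasi-complete separation returns the
  ridge solution with a flag instead of failing. `coef()` returns
  coefficients back-transformed to the original feature scale; they
  match `glm()` to 1e-4 on well-conditioned data.
* **Gaussian naive Bayes**: per-class, per-feature Gaussian
  class-conditionals with empirical priors, evaluated in log space;
  variances floored at 1e-9 of the pooled feature variance.
* **Multilayer perceptron**: one hidden layer of
  `ceiling((p + 2) / 2)` sigmoid units (the classic "(attributes +
  classes) / 2" default), sigmoid output, full-batch backpropagation
  with learning rate 0.3 and momentum 0.2 for 500 epochs,
  uniform(-0.5, 0.5) initialization from an explicit seed. The loss is
  squared error with per-example gradients accumulated over the batch;
  during development this was compared with cross-entropy variants and
  was the only schedule that reliably solves replicated XOR within the
  fixed 500-epoch budget, besides being the faithful full-batch
  analogue of the classic stochastic backprop defaults.

Models serialize to versioned JSON at 17 significant digits, so a
round-trip reproduces predictions exactly.

## Evaluation

AUC uses the Mann-Whitney mid-rank formulation (ties count one half),
hence is exact under ties and invariant to monotone score transforms.
Sensitivity and specificity are 100 TP/(TP+FN) and 100 TN/(TN+FP);
undefined ratios yield NA with a warning, never a silent zero.

`makeSplits()` builds leave-one-out, stratified k-fold (fold sizes
differ by at most one) and stratified percentage splits, all
deterministic under a seed. For cross-validation schemes one AUC per
trial is computed from the pooled out-of-fold probabilities -- matching
how standard toolkits report a single cross-validated AUC -- rather
than averaging per-fold AUCs. Percentage splits default to 5 repeated
trials (the number of published trials per split; the modeled methods
text says three, and `nTrials` is configurable). `summarizeTrials()`
reports the mean, sample SD and CV = 100 SD/mean of the per-trial
AUCs, with CV rounded half-up to an integer percent from the unrounded
mean and SD, and mean/SD reported to two decimals -- exactly the
printed convention of the reference variability tables, whose
arithmetically self-consistent rows the test suite recomputes cell by
cell. The image is the sampling unit by default; `groupBySubject =
TRUE` keeps all images of a subject on one side of every split, which
is the stricter design acknowledged as a limitation in the modeled
study.

## Pipeline and reproducibility

`runPipeline()` chains calibrate, simulate, extract, compare, evaluate
and report; every stage seed derives from one master seed, so a rerun
with the same configuration writes byte-identical CSVs. The run log
records a config hash, the seed, cohort counts and achieved calibration
moments. `loadExternalCohort()` ingests a manifest of real 8-bit
grayscale PNG/TIFF exports with per-row validation, so real B-mode data
can replace the simulator behind the same interface.

Problem sizes used by the shipped tests: texture oracles run on 100
random regions up to 24 x 24 at up to 8 gray levels; the acceptance
checks build one calibrated 100+100-image cohort (5 ROIs each, about
half a minute of compute) shared across blocks; pipeline tests use
6+6-image cohorts at 128 x 128.

## Known limitations

* The contrast-matching property is statistical, not per-cohort (see
  above); single cohorts can show a nominally significant contrast
  difference in either direction.
* Published GLCM feature scales in the modeled tables are internally
  inconsistent (e.g. a gray-level mean of 2.1 in one class versus 146.0
  in the other), so absolute GLCM magnitudes are package conventions
  (Ng = 32, natural-log entropy) and only *relative* class structure is
  emulated; no check asserts absolute agreement with printed GLCM
  values, and printed per-feature sensitivities of the real data are
  likewise out of reach of a synthetic cohort.
* The MLP is deliberately minimal (fixed schedule, no early stopping);
  it is a faithful reference implementation, not a tuned model.
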