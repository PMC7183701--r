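---
title: "Radiomic classification of lymph-node metastasis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic classification of lymph-node metastasis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnradiomics)
```

## The problem

Preoperative CT staging of colon cancer hinges on deciding whether regional
lymph nodes are metastatic. The clinical convention classifies a node as
metastatic when its long-axis diameter exceeds 10 mm, but size
distributions of normal and metastatic nodes overlap heavily, so the rule
trades poor specificity for moderate sensitivity. `lnradiomics` implements
a texture-based alternative: a 146-feature panel is extracted from the
node's ROI on the single CT slice of maximal in-plane diameter, a LASSO
regression selects the informative features, and a kernel SVM classifies
the node. The package compares three models — the 10 mm size rule, an SVM
on demographic variables chosen by exhaustive subset search, and the
radiomic SVM — with accuracy, sensitivity, specificity and DeLong-tested
AUCs on a stratified 80/20 train/test split.

Because no patient images are distributed, the package ships a synthetic
cohort generator that reproduces the statistical structure the analysis
relies on, so the whole pipeline is exercised end to end by code alone.

## The synthetic cohort

Each case is one 2-D slice at 1 mm isotropic spacing holding one
elliptical node.

**Size law.** The long-axis diameter is drawn from a normal distribution
truncated below at 4 mm. The published per-class statistics
(normal 12.12 ± 5.74 mm, metastatic 17.37 ± 8.48 mm) are treated as
moments of the *truncated* distribution: the parent parameters are solved
by moment matching at generator construction. Using the printed values
directly as parent parameters would inflate the realized mean by ~0.9 mm
and shrink the SD by ~13%, so the sampled cohort would no longer match the
reported cohort; moment matching keeps the realized moments on target.
The short/long axis ratio is uniform on (0.55, 0.9), with the short axis
floored at 4 mm so that every mask spans at least four pixels in any
orientation — below that, the wavelet block (which needs a 4×4 bounding
box) and the LBP operator (which needs an interior pixel with a complete
8-neighborhood) are undefined.

**Texture.** Interior intensity is a constant base level plus a
stationary Gaussian random field with squared-exponential correlation
(correlation length 2.5 mm) plus white noise (SD 2). The field's
amplitude is `texture_contrast_scale` × 15 intensity units; normal nodes
use scale 0.4 and metastatic nodes 1.0, encoding the greater internal
heterogeneity of metastatic tissue. The study reports no interior
intensity statistics, so the base level, unit amplitude and noise SD are
free parameters of this package; all quantized-domain features are
invariant to positive affine maps of intensity, which makes the absolute
scale immaterial.

A consequence worth stating explicitly: because min-max quantization
removes the overall intensity scale, raising the field amplitude against
the fixed noise floor makes the *normalized* image smoother, so the mean
quantized GLCM contrast *decreases* monotonically in
`texture_contrast_scale`. The class signal is real and strong — it simply
appears as metastatic nodes having lower quantized co-occurrence contrast
(and higher raw-intensity variance), and the property tests assert this
monotone direction.

**Demographics** (age, gender, tumor location, histological grade) are
drawn independently of texture given the label, so only node size and
texture carry class information; associations such as perineural or
vessel invasion are deliberately not emulated because those variables
never enter any model.

What the generator does *not* emulate: Hounsfield calibration, partial
volume effects at node boundaries, neighboring anatomy, multiple nodes
per patient, or scanner-dependent noise texture. Passing tests on this
cohort therefore demonstrate the correctness and internal consistency of
the pipeline, not clinical performance on real CT data.

## The imaging front end

Slices are resampled in-plane to 1 mm by separable cubic-spline
interpolation (exact for polynomials up to degree 3; masks use nearest
neighbor so labels stay binary). The analysis slice is the one whose mask
has the largest maximal Feret diameter, ties going to the lowest slice
index. Within the mask, intensities are min-max normalized to [0, 1] and
quantized to B = 8 levels by `level = floor(v·B) + 1` with v = 1 mapped
to level B; a flat region maps to level 1. Normalization bounds are
computed from in-mask pixels only — the features should describe the
node, not surrounding fat or bowel — with whole-slice bounds available
via the `bounds` argument.

## The 146-feature panel

| Block | Indices | Content |
|---|---|---|
| First-order | 1–6 | mean, variance, skewness, kurtosis, energy, entropy (bits) of the quantized histogram |
| GLCM | 7–12 | energy, contrast, correlation, homogeneity, entropy, dissimilarity; distance 1, symmetric, normalized, averaged over 0°/45°/90°/135° |
| GLRLM | 13–19 | SRE, LRE, GLN, RP, RLN, LGLRE, HGLRE, direction-averaged |
| LBP | 20–29 | rotation-invariant uniform (riu2), P = 8, R = 1 histogram on the normalized continuous image |
| Fractal | 30 | box-counting dimension of the above-median set |
| Wavelet | 31–118 | single-level db2; per subband (LL, LH, HL, HH): FoS + GLCM + GLRLM on the re-quantized subband plus relative energy, log-energy, mean |coef| |
| Gradient | 119–137 | FoS + GLCM + GLRLM on the re-quantized Sobel magnitude within the 1-px-eroded mask |
| Shape | 138–146 | area, perimeter, major/minor axis, eccentricity, solidity, extent, equivalent diameter, circularity |

Design choices where the published description is silent:

* The identities of the six first-order, six GLCM and seven GLRLM
  features are not listed anywhere in the source description; the
  standard Haralick/Galloway panels above are used, ordered so that the
  five features the study *does* name land at their published indices
  (contrast = F8, run percentage = F16, gradient contrast = F126,
  gradient entropy = F129).
* Published index F96 ("low gray level run emphasis of the approximate
  wavelet image") cannot coexist with a contiguous LL-first subband
  layout; this package's canonical ordering places LL first, which puts
  that feature at index 48, and the alias lookup
  (`feature_index("Low gray level run emphasis of approximate wavelet image")`)
  resolves the published name to the package index.
* 4 subbands × 19 texture features = 76, not the printed 88; the
  shortfall of 12 is filled by three per-subband summary features
  (relative energy, log-energy, mean absolute coefficient), documented
  as a reconstruction.
* Daubechies order is unstated; db2 with symmetric boundary extension is
  used. LBP on continuous (not quantized) intensities; riu2 with P = 8,
  R = 1 is the only standard variant with exactly ten bins.
* Wavelet and gradient images are re-quantized independently of the
  intensity image because their dynamic ranges differ.
* Perimeter uses Moore boundary tracing with corrected chain-code
  weights (0.948 straight, 1.340 diagonal), which keeps the circularity
  of a digital disk within a few percent of 1; solidity rasterizes the
  convex hull of pixel centers, matching regionprops semantics.
* Degenerate inputs: a constant ROI has zero variance/entropy and unit
  energy; skewness and kurtosis of a zero-variance distribution are
  defined as 0; a GLCM direction with no valid pair is excluded from the
  average; if the 1-px-eroded gradient mask retains no co-occurring
  pair, the block falls back to the full mask; a median-threshold set
  with fewer than two occupied boxes at the coarsest scale yields
  fractal dimension 0 with a warning.

## Selection and models

**Clinical rule.** Metastatic iff long axis > 10 mm (strict); the
continuous long-axis diameter serves as its ROC score.

**LASSO.** Linear (squared-error) LASSO on the 0/1 label — matching a
cross-validation *mean-squared-error* selection curve — with 10-fold
class-stratified folds; λ is the minimizer of the CV MSE and the selected
features are the nonzero coefficients there. Logistic loss is available
behind a flag. Constant columns are dropped with a warning. On the
synthetic cohort the selected set is typically a few dozen features
rather than a handful: the simulated texture signal is strong and spread
over many correlated features, which squared-error LASSO at λ_min happily
retains. This is a property of the synthetic signal structure, not of the
selector.

**Exhaustive demographic search.** All 63 non-empty subsets of {age,
gender, histological grade, tumor location, short axis, long axis}
(categoricals one-hot encoded) are scored by 10-fold CV error of an RBF
SVM on shared folds. The winner is picked by the one-standard-error
parsimony rule — the smallest subset within one SE of the minimum CV
error, remaining ties broken lexicographically. Plain minimum-CV-error
selection lets fold noise drag uninformative variables into the model;
with the parsimony rule, a cohort in which only the short-axis diameter
differs between classes selects exactly {short_axis}.

**SVM.** RBF kernel by default ("kernel-based" read in the standard
way), linear available. Features are standardized by training-set
mean/SD; (cost, γ) are chosen on a small grid (cost 2^{-3..5}, γ
2^{-2..2}/d) by 10-fold stratified CV, ties toward the smaller cost then
γ; the final model is refit on the full training set and exposes
oriented continuous decision scores for ROC analysis. No test-cohort
statistic ever reaches a fitted parameter; the leakage test verifies
that shuffling held-out labels changes nothing.

## Evaluation

Accuracy, sensitivity and specificity are reported in percent to two
decimals. The inverse map from printed rates to integer counts uses
round-half-away-from-zero, which reproduces every published
count/rate pair exactly. AUC is the Mann–Whitney statistic with ties
counted one-half; its variance is DeLong's structural-components
estimator, the 95% CI is the symmetric normal approximation on the AUC
scale (logit-scale CI behind a flag), and paired model comparisons use
the DeLong covariance with a two-sided normal p. Cohort tables use the
Wilcoxon rank-sum test for numeric variables and a binomial test of the
metastatic-class proportion against the normal-class proportion for
categoricals; no multiplicity correction is applied, matching the
reporting convention of the source analysis. The size-histogram overlap
statistic bins pooled diameters in fixed-width bins (0.25 mm default)
anchored at the pooled minimum and reports the percentage of nodes in
bins occupied by both classes.

## Problem sizes and numerical conventions

The default study replica uses 196 normal + 194 metastatic cases, split
312/78 by class-stratified sampling — the same cohort geometry as the
published study. Property-style checks run at the sizes stated in their
tests (500 lesions per class for size-law recovery, 200 per class for
the heterogeneity signal, 1000 simulated datasets of n = 80 for CI
coverage, 100 seeded study replicates for the model-ranking property;
the replicate SVMs use a reduced 2×2 hyperparameter grid). Random-number
use is localized: every entry point takes a seed, derives per-stage and
per-case sub-seeds, and restores the caller's RNG state, so identical
configurations are bit-for-bit reproducible.

## Limitations

The generator's elliptical, single-node, noise-plus-Gaussian-field world
is far simpler than abdominal CT; absolute performance numbers obtained
on it (typically radiomic test AUC ≈ 0.95 against clinical ≈ 0.7) say
nothing about clinical accuracy and are used only to test the *ordering*
of the models and the machinery around them. The feature panel is a
faithful reconstruction, not an IBSI-certified implementation, and
3-D texture, size-zone matrices and DICOM handling are out of scope.
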