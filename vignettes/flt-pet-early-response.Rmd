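---
title: "Methods: early-response FLT-PET radiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early-response FLT-PET radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fltrad)
```

## The problem and the pipeline

Pathological response to neoadjuvant chemotherapy (NCT) in breast cancer is
only known after surgery, months into treatment. A proliferation tracer
(¹⁸F-fluorothymidine, FLT) imaged at baseline and after the first cycle can
anticipate that answer, but single uptake summaries such as SUV_max ignore
the heterogeneity of uptake inside the lesion. The pipeline in this package
therefore (i) extracts a panel of first-order and texture features from the
lesion VOI at both timepoints, (ii) keeps only features that are robust to
plausible contouring variability, (iii) codes PET and pathological response,
and (iv) fits sparse logistic models of both outcomes from the
percentage-change features.

The assumptions worth stating explicitly:

* PET and CT are already co-registered and the activity volumes are decay
  corrected; SUV uses body-weight normalization
  (`SUV = activity[kBq/ml] × weight[kg] / dose[MBq]`, density 1 g/ml).
* The two scans of a patient are acquired on the same scanner, so
  percentage changes cancel multiplicative scanner effects; absolute
  feature values across scanners are not assumed comparable.
* The lesion contour is trusted up to ±1–2 mm; the robustness screen below
  is the formal treatment of that uncertainty.

## Feature extraction conventions

**Resampling.** All feature extraction happens on a 1 mm isotropic grid
(`resample_mm`, default 1): the volume is interpolated trilinearly, the mask
linearly with a 0.5 threshold (volume preserving in expectation). The
extraction first crops to the mask bounding box plus `margin_mm` (default
8 mm — enough to contain the 6.2 mm SUV_peak sphere and the +2 mm contour
dilation); this is purely an efficiency measure and does not change any
value for interior lesions.

**Discretization.** Texture matrices and the IVH are computed after
fixed-bin-number quantization to `n_bins = 32` levels between the in-mask
minimum and maximum: `level = 1 + floor(32 (x − min)/(max − min))`, maximum
mapped to 32, constant VOI mapped to level 1. Intensity statistics (ID_\*)
are computed on the raw SUV values, not the quantized ones: quantization is
fixed "for second order features", and the first-order family is better
defined on the native scale.

**SUV_peak and the local intensity peak** use the EANM 1 cm³ sphere: all
voxels whose centres lie within 6.2 mm of the centre voxel's centre,
intersected with the volume. SUV_peak maximizes the sphere mean over in-mask
centres; the local intensity peak evaluates it at the global in-mask maximum
(first maximum in array order on ties).

**Texture aggregation.** All texture matrices use the 13 unique directions
of the 26-neighbourhood at Chebyshev distance 1 and are *merged* (summed)
across directions before features are computed, rather than averaged per
direction; the GLCM is additionally symmetrized. One convention is applied
consistently and pinned by brute-force oracle tests; with merged run-length
matrices the run percentage is normalized by `N_voxels × 13`. Zones (GLSZM,
GLDZM) are 26-connected components of equal level; the distance-zone matrix
uses the per-zone minimum Chebyshev distance to the VOI border, with border
voxels at distance 1 and the volume edge counting as border. The NGLDM
dependence count is the number of same-level 26-neighbours (coarseness
threshold α = 0, unstated in the source convention and chosen as the
strictest); the NGTDM coarseness guard is `1/(10⁻⁶ + Σ pᵢ sᵢ)` so constant
VOIs yield 10⁶ rather than infinity.

**Degenerate-VOI rules.** Constant VOIs define: information measure of
correlation 1 = 0 (0/0 rule), fractional intensity γ ≡ 1 (so the 90%-volume
fraction is 1), and the coarseness guard above. These rules keep downstream
ICC matrices and model design matrices free of NaN.

## Contour robustness

Each lesion is contoured four ways: original, +1 mm, +2 mm, −1 mm.
Perturbation is Euclidean distance-threshold morphology and is applied
*after* resampling, so ±1 mm is exactly one voxel on the default grid (the
ordering is not dictated by the source convention; grid-exact perturbation
was preferred). On the original anisotropic grids a 1 mm margin would be
sub-voxel and the perturbation ill-defined.

Robustness is quantified with ICC(A,1) — two-way random effects, single
measurement, absolute agreement — treating the four contours as raters, with
the F-based 95% confidence interval of McGraw & Wong. The screen retains a
feature when the *lower* confidence bound is ≥ 0.60, inclusive (a published
robust panel includes features whose lower bound prints exactly 0.60). The
screen is run on the percentage-change features, matching how the covariates
enter the models; per-timepoint absolute screening is available through the
same function. Negative ICCs are reported as computed, never clipped;
subjects with degenerate (emptied) contour variants are dropped per feature
and counted in `n_subjects`.

## Response coding

Percentage change is `(FLT1 − FLT2)/FLT1 × 100`; a baseline within 10⁻⁹ of
zero flags the change as undefined and the record is excluded from
modelling. SUV statistics are background-corrected by subtracting the same
statistic computed in the contralateral mirror VOI (reflection across the
volume midline — adequate for symmetric phantoms; real use can supply an
explicit plane), floored at zero.

EORTC classes after one cycle: CMR when the corrected follow-up uptake has
vanished into background (floored value ≈ 0; the convention chosen because a
complete response presents as disappearance of uptake rather than a numeric
threshold), PMD for a > 25% increase, PMR for a ≥ 15% reduction (the
one-cycle end of the 15–25% EORTC band; configurable), SMD otherwise. The
binary PET code is CMR vs rest; pathology is RCB-0/I vs RCB-II/III. Whether
the corrected or raw SUV_max drives the EORTC call is not settled by the
source convention; corrected is the default and both statistics are
exposed.

The PET-vs-pathology cross-table is tested with an exact two-sided Fisher
test implemented by hypergeometric enumeration (all tables with fixed
margins whose probability is at most the observed one, with a 10⁻⁷ relative
tie tolerance), cross-checked against `stats::fisher.test` in the test
suite.

## Models

Both outcomes (PET response, pathological response; complete response coded
1) are modelled with L1-penalized logistic regression via glmnet.
Covariates are standardized to mean 0, sd 1 before penalization (L1 is
scale-dependent) and the intercept is unpenalized; the λ grid is glmnet's
descending log-spaced grid of 100 values from the all-zero λ_max. λ_min
minimizes the leave-one-out binomial deviance, computed by an explicit
n-fold loop so that folds whose training outcome degenerates to one class
fall back to the fold prevalence instead of failing. The misclassification
rate is reported from the same leave-one-out probabilities at cutoff 0.5,
with ties predicted as class 1 (fixed rule). Deviance rather than error
rate tunes λ because it is the stabler criterion at n ≈ 15. Coordinate
descent runs at tolerance 10⁻⁷ with at most 10⁵ iterations. With no usable
covariate the fit collapses to the intercept-only model and reports the
prevalence error.

Reported coefficients are on the original covariate scale (glmnet
back-transforms its internal standardization), so published coefficients
from comparable cohorts are structural references — sign and selection —
rather than numeric targets.

## The synthetic cohort generator

`generate_cohort()` is the package's study stand-in, with defaults fixed at
the emulated study's conditions: 15 evaluable patients, 60% pathological
responders, two thirds of patients on scanner geometry A (3.9 × 3.9 ×
4.25 mm) and the rest on geometry B (4.1 × 4.1 × 3.0 mm), fractional
SUV_max declines after one cycle of 0.40–0.70 (responders) versus 0.00–0.10
(non-responders), and RCB categories drawn consistently with the true label
(responders RCB-0 with probability 0.9 else RCB-I; non-responders RCB-II
with probability 0.85 else RCB-III, mirroring observed 8:1 and 5:1
frequencies). Values the emulated setting does not pin down were chosen
once as clinically plausible and not revisited: ellipsoidal lesions with
8–14 mm semi-axes (T2-sized primaries), baseline SUV_max 3–10, background
SUV 0.6 ± 0.08, lesion texture from a Gaussian random field (white noise
smoothed at 4 mm correlation length, exponentiated with amplitude 0.6 for
positivity) scaled so the lesion maximum hits its target, additive Gaussian
background noise and multiplicative lognormal lesion noise (sd 0.05,
PET count noise being intensity-dependent). One cohort RNG stream is split
into per-patient sub-streams so individual patients regenerate
reproducibly.

What the phantoms deliberately do **not** emulate: scanner point-spread
functions, time-of-flight or reconstruction effects, attenuation and
scatter, irregular lesion shapes, necrotic cores, or uptake in normal
tissue structures. Consequently a passing robustness screen on phantoms
shows the *machinery* is correct (contour-stable features pass, noise
features fail), not that any particular real-world feature is robust; and
phantom lesions are more contour-stable than real ones — their SUV_max is
often exactly contour-invariant (ICC = 1). Note also that with declines
capped at 0.70 no phantom reaches a complete metabolic response, so the
PET-binary outcome is degenerate on default cohorts and the PET-response
model is skipped with a warning; the pathological outcome carries the
modelling demonstrations.

## Problem sizes and numerics

The test suite and the acceptance script run cohorts of 6–30 patients
(30 for the robustness-screen and signal-recovery demonstrations, matching
a realistic single-centre cohort; 8–15 for end-to-end runs), texture oracle
checks on ≤ 5×5×5 blocks against brute-force enumerations, and a 200-subject
null simulation for the ICC. Sphere means are computed by FFT convolution
with an edge-correcting count kernel (float error ~10⁻¹²); texture matrices
are integer-exact. All randomness flows from a single seed per cohort, and
pipeline artifacts are byte-identical across runs at a fixed seed.

## Known limitations

* The 42-feature panel covers the published robust set plus the remaining
  first-order statistics; morphological/shape features are out of scope (in
  the emulated setting none survived the robustness screen or entered any
  model).
* Fixed-bin-number discretization only; fixed-bin-size and filtered
  (wavelet) features are not implemented.
* The contralateral mirror uses the grid midline, not anatomy.
* The exact aggregation convention behind externally published texture
  values can differ (per-direction averaging, dependence-count offsets);
  this package's conventions are internally consistent and oracle-pinned,
  so cross-package numeric parity is not guaranteed feature by feature.
* With n ≈ 15 the models describe the cohort; no external validation or
  calibration is attempted.
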