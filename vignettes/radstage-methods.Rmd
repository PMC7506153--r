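---
title: "Staging nasopharyngeal carcinoma from PET/MR radiomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging nasopharyngeal carcinoma from PET/MR radiomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radstage)
```

## The problem

Nasopharyngeal carcinoma (NPC) is treated very differently in its early
(TNM I--II) and advanced (III--IV) stages: radiotherapy alone versus combined
chemoradiation. radstage implements a complete, testable radiomics pipeline for
that binary staging decision from co-registered ^18^F-FDG PET and T2-weighted
MR volumes of the primary lesion:

1. preprocessing (1 mm isotropic resampling, 0--255 grey normalisation),
2. a 396-feature-per-modality radiomic catalogue,
3. PET metabolic parameters (SUVmax, MTV at 40% of SUVmax, TLG),
4. two-step feature selection (mRMR, then lasso-logistic with cross-validation),
5. a logistic "radscore" staging model with ROC/calibration diagnostics, and
6. Pearson correlation of the selected features against the metabolic
   parameters.

Because no patient imaging is distributed with the package, a deterministic
phantom-cohort generator stands in for the clinical cohort; every stage is
exercised and tested against it.

## Preprocessing

Volumes are resampled to 1 mm isotropic spacing with trilinear interpolation
(nearest-neighbour for masks, which must stay binary). The grid convention is
explicit so shape arithmetic is unambiguous: voxel centres sit at
`origin + (k + 0.5) * spacing` with a half-open extent, and the resampled shape
is `ceiling(extent / target)` per axis. Grey levels are then min--max rescaled
to integers 0--255 over the *whole* volume (not the ROI): normalising inside
the lesion would pin every within-lesion minimum to 0 and destroy features
such as `MinIntensity`. Rounding is fixed as half-away-from-zero so results
are bit-reproducible. A constant volume cannot be rescaled and maps to all
zeros with a warning.

Texture features are computed on the normalised image; the metabolic
parameters are computed on the *un-normalised* SUV volume, since SUV units are
their whole point.

## The feature catalogue

The catalogue has exactly 396 named features per modality:

| family    | count | composition |
|-----------|------:|-------------|
| histogram |    42 | 23 first-order statistics + percentiles 5--95 by 5 |
| shape     |     9 | volume, surface area, sphericity, compactness, diameter, elongation, ... |
| Haralick  |    21 | 7 features on the direction-averaged GLCM x offsets 1, 4, 7 |
| GLCM      |   126 | 7 base features x offsets 1, 4, 7 x 6 direction variants |
| run-length|   198 | 11 base features x steps 1, 4, 7 x 6 direction variants |

Direction variants follow the 2D in-plane convention the feature names imply
(`angle0`, `angle45`, `angle90`, `angle135`, their mean `AllDirection`, and
the population SD over the four angles, `_SD`); matrices are accumulated over
axial slices. Grey-level matrices use L = 32 equal-width bins over the masked
intensity range by default (configurable). Run-length "steps" are scan-lattice
strides: a step-4 run table counts runs over every fourth voxel along each
line, the only reading under which a run-length matrix has an offset
parameter at all. Emphasis features index grey levels from 1
(`i = level + 1`), the standard convention that keeps low-grey emphasis
(division by i^2) defined.

Worked identities pin the implementations down in the tests: a constant image
has GLCM energy exactly 1 and entropy exactly 0; an enumerable 2x3 slice gives
energy 0.25 and entropy 2 bits; the run table {(i=2, j=2), (i=3, j=1)} gives
HGRE 6.5, LGRE 13/72 and SRHGE 5.0. Beyond the worked cases, vectorised GLCM
and RLM builders are checked *exactly* against independent brute-force
per-voxel enumerators on random masked volumes.

Two shape-feature caveats are worth knowing. Surface area counts exposed voxel
faces, which reproduces the analytic cube values (a 10 mm cube has A = 600
mm^2) but overestimates smooth surfaces by roughly 1.5x (the staircase
artifact), so digitised spheres score *lower* sphericity (~0.66) than cubes
(0.806). Within one convention the features remain comparable across lesions,
which is all a cohort analysis needs. Maximum 3D diameter is exact over
boundary voxel centres.

## PET metabolic parameters

The metabolic ROI is delineated with the adaptive threshold rule used
clinically: SUVmax is read inside a seed box (the anatomical mask's bounding
box dilated by 3 voxels in the pipeline), voxels at or above 40% of it are
kept, and the mask is restricted to the 26-connected component containing the
maximum voxel -- a deterministic stand-in for the operator's manual exclusion
of nearby hot normal tissue. Then SUVmean, MTV (voxel count x voxel volume, in
mL) and TLG = SUVmean x MTV are reported. MTV uses the metabolic (40%) mask
while texture features use the anatomical mask, mirroring the two segmentation
routes of clinical practice. The implementation is validated on a uniform
SUV-8 sphere of radius 10 mm: the threshold recovers the sphere exactly and
MTV lands within 2% of the analytic 4.189 mL, with TLG = 8 x MTV by
construction.

## Feature selection

The feature table is cleaned on the training split only: values more than 3
training SDs from the training mean are replaced by the mean of the
non-outlying values, columns are z-scored with training statistics, and test
rows are transformed with those same statistics (a leakage test asserts that
corrupting test rows changes nothing upstream). The z = 3 cutoff is this
package's choice; only "outliers replaced with the average" is externally
specified.

mRMR uses the canonical MID (difference) criterion -- first feature maximises
mutual information with the stage label, each next feature maximises
relevance minus mean redundancy against the already-selected set -- with MI
estimated by plug-in after equal-frequency 10-bin discretisation. Exactly 20
features are kept; ties break by catalogue order. The lasso step fits the
L1-penalised logistic path (glmnet) on those 20 and picks lambda by 10-fold
stratified cross-validated misclassification error at the 0.5 probability
cutoff, using the *minimum* rule, not 1-SE. The planted-signal property (5
informative features at effect d = 1 among 396; at least 4 recovered in the
top 20 in over 90% of 50 replicates) is tested at n = 140, where the plug-in
MI estimate separates signal from noise reliably; at n = 70 the 10-bin
estimator is too noisy for that bar, which is a real small-sample caveat of
mRMR rather than an implementation artifact.

## The staging model

The final model is an unpenalised maximum-likelihood logistic fit on the
selected standardised features (ridge-stabilised with penalty 1e-6 under
quasi-separation, with a warning). The radscore is its linear predictor. The
cutoff maximises the Youden index on the training scores (ties resolve to the
lower cutoff); headline test metrics use the *training* cutoff, and the
test cohort's own Youden cutoff is reported alongside, matching the
per-cohort reporting style of clinical radiomics papers while keeping the
methodology honest. Reports evaluate one frozen model -- the API takes a
fitted object, so refitting on test data is structurally impossible. AUC is
trapezoidal (equivalently Mann-Whitney with half credit for ties) and is
tested exactly against a pair-counting oracle and cross-checked against pROC.
Calibration uses 10 equal-width probability bins with a least-squares line
through the bin points.

## The phantom cohort

The generator emulates the study conditions the pipeline targets: 100
subjects, 27% early / 73% advanced (the stage I--II vs III--IV split of the
clinical cohort), a stratified 70/30 train/test split, and an overall SUVmax
scale near 11 (clinical scale 10.9 +/- 4.8). Each lesion is an axis-aligned
ellipsoid (per-axis radii jittered +/-20%) with a smooth radial uptake
profile multiplied by `1 + field`, where `field` is a Gaussian random field
(white noise smoothed to a controlled correlation length, variance-normalised,
winsorised at +/-2 so one extreme voxel cannot stretch the grey-level range).
The lesion is rescaled so its maximum equals the subject's drawn SUV peak;
background is flat with Gaussian noise. MR volumes carry an independent field
on an arbitrary 0--1000 scale -- only relative texture survives the 0--255
normalisation, so no MR unit semantics are pretended.

Class effects (defaults, chosen once): lesion radius 10 +/- 1.5 mm (early) vs
14 +/- 2 mm (advanced); SUV peak 9 +/- 3 vs 12 +/- 4; field correlation
length 6 vs 3 mm; relative field amplitude 0.15 vs 0.30. Age (normal 52,
SD 12.5, truncated 18--90) and gender (78% male) carry no class signal by
design, so the cohort-comparison stage has honest null variables.

The generator also plants the radiogenomic-style coupling the association
stage must recover: per subject, the field amplitude scales with relative
lesion volume and the correlation length shrinks with it (exponent -3/4) --
larger tumours are more and more-finely heterogeneous. One subtlety drove this
design: because grey-level discretisation adapts to the masked range, GLCM
entropy is nearly invariant to the field *amplitude* (we measured it
flat-to-slightly-decreasing in the amplitude over 0--0.5); what entropy
robustly tracks is texture *fineness* (7.98 bits at 2 mm correlation length
vs 7.29 at 8 mm under otherwise identical settings). The monotone-
heterogeneity property test therefore varies the correlation length, and the
volume coupling uses both channels so the planted entropy-vs-MTV/TLG
correlation is positive and significant, the qualitative pattern clinical
studies report.

What the phantom does *not* emulate: acquisition physics (attenuation,
partial volume, reconstruction), anatomical context (lymph nodes, air
cavities, skull base), non-ellipsoidal growth, and inter-scanner variation.
Passing tests therefore demonstrate correctness of the computational
machinery and recoverability of planted effects -- not clinical performance on
real patients.

## Numerical and design choices

- **Determinism.** One top-level seed; each stage derives its own seed by a
  stable hash of the stage name. Re-running a configuration reproduces every
  output file byte for byte, and the manifest (md5 per stage output) is the
  test's witness; wall-clock timestamps live only on the in-memory run object.
- **Problem sizes.** The default end-to-end run uses n = 100 subjects on
  64^3 1-mm grids (minutes on one CPU); unit tests use 20--48^3 phantoms
  (seconds). The anisotropic resampling fixture is 0.5 x 0.5 x 2 mm.
- **Degenerate inputs.** Constant volumes normalise to zero with a warning;
  empty masks error; a GLCM direction with no valid pair is excluded from
  AllDirection aggregates; GLCM correlation is 1 by convention at zero
  marginal variance; single-voxel masks report zero dispersion; disconnected
  masks compute shape on the union with a warning.
- **Percentiles** use linear interpolation between order statistics
  (`quantile` type 7), so P50 of 1..100 is 50.5.
- **Statistics.** The cohort-comparison t statistic is `(mean_test -
  mean_train) / se` with pooled variance, the order clinical tables print;
  chi-square is Pearson without continuity correction. Recomputing from
  *printed, rounded* clinical summaries reproduces published statistics to 3
  decimals for age and gender; for SUVmax the recomputed t is -0.898 where
  -0.899 was published from unrounded data -- an input-rounding limit, not a
  formula difference. Correlations are computed across the full cohort
  (train + test) to maximise n, and significance is starred at 0.05/0.01
  without multiplicity correction.
- **Interfaces.** Everything tabular is a tibble keyed by `subject_id`;
  fitted models have `tidy()`/`glance()` methods; ROC and calibration objects
  have `autoplot()` methods. The exported functions and `run_pipeline()` are
  the package's interface; there is no shell entry point.

## Limitations

The catalogue is a defined, reproducible composition (the commercial tool it
parallels does not publish its exact list); no wavelet-filtered features,
GLSZM/NGTDM families, or IBSI certification are attempted. The mRMR MI
estimator is the plain plug-in; at n near 70 its ranking noise is material
(see above). The 40% threshold is fixed rather than contrast-adaptive. The
phantom's limitations are listed in its own section -- conclusions about real
NPC staging require real cohorts.
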