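---
title: "Regional-homogeneity MVPA: models, parameters and design choices"
author: "rehomvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional-homogeneity MVPA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehomvpa)
```

# The analysis in one paragraph

`rehomvpa` implements a case-control discrimination pipeline for
resting-state fMRI.  Each subject's 4D BOLD series is temporally cleaned
(initial-volume discard, nuisance regression, 0.01-0.08 Hz band-pass), then
summarised as a voxelwise **regional homogeneity** (ReHo) map: Kendall's
coefficient of concordance W between each gray-matter voxel and its 26
nearest neighbours, normalised by the gray-matter mean.  The per-subject
maps become rows of a feature matrix on which a **linear support vector
machine** (after a lossless PCA rotation to N−1 dimensions) separates
patients from controls; accuracy is estimated by leave-one-out
cross-validation and summarised as generalization rate (GR), sensitivity
(SS) and specificity (SC).  The SVM weight vector is back-projected to voxel
space and its spatially contiguous extremes are tested by **label
permutation** at voxel and cluster level.  Finally, mean ReHo in 6 mm
spheres at cluster peaks is correlated (Pearson, Bonferroni-corrected)
with symptom severity across patients.

# Models and formulas

## Kendall's W (ReHo)

For K time series ranked over n time points with midranks,
$$W = \frac{12\,S}{K^2(n^3-n) - K\sum_j T_j},\qquad
S=\sum_t\Big(R_t - \frac{K(n+1)}{2}\Big)^2,$$
with $T_j=\sum_g (t_g^3-t_g)$ the tie correction of series $j$.  With no
ties the classical formula is recovered; W equals the tie-corrected
Friedman statistic divided by $K(n-1)$, which the test suite exploits as an
independent oracle (`stats::friedman.test`).  Under independence
$E[W] = 1/K$, i.e. 0.037 for the default 27-voxel neighbourhood — the
package verifies this on white noise.  A voxel is *computable* only when
its entire 3×3×3 neighbourhood lies inside the gray-matter mask (strict
edge rule); a permissive rule (any ≥7 in-mask series) is available via
`edgePolicy = "available_min7"`.  The mask-mean normalisation divides W by
the mean over the computable set, so normalised maps average exactly 1.

## Classification

With N subjects and D voxels (D ≫ N), PCA retains all d = N−1 directions of
nonzero variance; the projection $y = U^\top(x-\bar x)$ is an isometry on
the centered training span, so a linear SVM in the reduced space is
*identical* (to solver precision) to one trained on centered voxel
features — a property the tests assert at N = 12, D = 200.  The SVM is the
soft-margin C-classification of libsvm (`e1071`) with C = 1 and no feature
scaling.  In LOOCV the PCA is refit inside every fold on the N−1 training
subjects (d = N−2): fitting it once on all subjects would leak the held-out
subject into the mean and eigenvectors.  The leaky variant remains
available (`pcaGlobal = TRUE`) for comparison.  Metrics:
GR = (TP+TN)/N, SS = TP/(TP+FN), SC = TN/(TN+FP), as percentages;
decision ties (g = 0) go to the control class.

## Discriminative map and permutation inference

The full-data weight vector is back-projected, $w_{voxel}=Uw$, which
satisfies $\langle w_{voxel}, x_i-\bar x\rangle=\langle w,y_i\rangle$ and
$\|w_{voxel}\|=\|w\|$.  Significance is assessed by retraining on label
permutations (group sizes preserved, seeded stream).  Because PCA ignores
labels, its basis is computed once per data set.

One numerical property matters here: the scale of an SVM weight vector is
2/margin, not the strength of the pattern.  A strongly separable data set
yields a *wide* margin and hence *small* raw weights, while inseparable
permuted relabelings yield large ones — comparing raw weights would make
the test blind exactly when the signal is strongest.  The package therefore
normalises every map (observed and permuted) to unit L2 norm before
comparison; inference is on the pattern direction, and when margins are
comparable this reduces to the raw test.  Voxel p-values are two-sided
add-one empirical probabilities on |w|,
$p=(1+\#\{|w^{perm}|\ge|w^{obs}|\})/(n_{perm}+1)$, so they are never 0.
Candidate clusters are connected components (26-connectivity by default) of
$p<0.02$ with at least 10 voxels.  The cluster null records, per
permutation, the maximum component size after thresholding that permuted
map at its own rank-based top-`voxelAlpha` fraction of |w| (the
max-cluster-statistic convention); thresholding permuted maps against the
null's voxelwise critical values is available via
`thresholdBy = "observed_null"`.

## ROI correlation and behavioural scoring

Spheres of radius 6 mm are centred on the in-cluster voxel of maximal |w|
(ties broken deterministically to the lowest linear index) and resolved to
gray-matter voxel centres within the radius.  Mean *normalised* ReHo per
patient is correlated with symptom severity (NDI) and illness duration by
Pearson's r with a two-tailed t test on n−2 df; Bonferroni correction uses
m = (ROIs × variables) and the corrected level 0.01 (the
raw-threshold reading p_raw < 0.01/m is available via
`rawThreshold = TRUE`).  Zung depression/anxiety raw sums (20-80) are
converted to index scores by ×1.25, with normal-range cutoffs 53 (SDS) and
50 (SAS).

# The synthetic-data generator

No scan data ship with the package; every claim is exercised on simulated
cohorts with known ground truth (`simulateCohort()`).

* **Baseline**: independent Gaussian voxel noise (SD `noiseSD`, default 1)
  plus a subject-common slow drift — an AR(1) component (ρ = 0.3) and a
  small random linear trend — so nuisance regression and the band-pass have
  realistic work to do.
* **Planted effect**: within each effect ROI a patient's voxel noise is
  mixed with one shared regional series,
  $v' = (1-\lambda_i)v + \lambda_i s(t)$.  The shared series is per-ROI and
  per-subject, so the planted synchrony is *local* — exactly what ReHo
  measures.  In-ROI W rises monotonically with λ (verified over
  λ ∈ {0, 0.3, 0.6, 0.9}).
* **Per-subject levels**: $\lambda_i \sim U((1-j)\lambda, \lambda)$ with
  jitter j = 0.5.  Without between-patient variability a behavioural
  correlation target would be ill-defined; a uniform spread is the simplest
  law with a closed-form SD, $j\lambda/\sqrt{12}$.
* **Behaviour**: NDI = intercept + slope·λᵢ + ε.  Defaults (slope 120,
  noise chosen for theoretical r = 0.6) give a patient NDI mean of ≈48.7
  and SD of ≈17, matching realistic symptom-score scales; the generated
  score is truncated at 0 (probability ≪ 1% under defaults).  Zung scores
  and duration are realistic dressing without coupling.
* **Motion**: mean-reverting AR(1) walks (ρ = 0.97, step SD 0.05 mm/deg),
  so default cohorts pass the 1.5 mm / 1.5° gate while still drifting like
  real head motion; `injectHighMotion` plants one violator for QC tests.
* **Masks**: gray matter is the central box two voxels in from each face;
  white matter and CSF are thin slabs on opposite faces, disjoint by
  construction and used only for nuisance mean signals.

What the generator does **not** emulate: hemodynamic response shapes,
cardiac/respiratory physiological noise, spatial autocorrelation of the
scanner point-spread function, susceptibility artifacts, and
inter-subject anatomical variability (all cohorts share one grid and
mask).  Passing tests therefore demonstrate the *statistical machinery* —
calibration under exchangeability, recovery of planted local synchrony,
correct arithmetic — not performance on real scanner data, where
registration error and structured noise would lower accuracy.

# Defaults and units

| Parameter | Default | Units | Used in |
|---|---|---|---|
| discarded initial volumes | 10 | frames | `discardInitial` |
| pass band | 0.01–0.08 | Hz | `bandpassFilter` |
| motion gate | 1.5 / 1.5 | mm / degrees | `qcMotion` |
| ReHo neighbourhood | 27 | voxels | `rehoMap` |
| SVM box constraint C | 1 | — | `trainSVM` |
| permutations | 5000 | — | `permutationNull` |
| voxel / cluster level | 0.02 / 0.001 | probability | inference |
| minimum cluster | 10 | voxels | `extractClusters` |
| ROI radius | 6 | mm | `peakROI` |
| correlation level | 0.01 | probability (Bonferroni-corrected) | `roiCorrelations` |
| TR | 2 | s | acquisition |
| voxel size | 3 | mm | grid |

The rotation gate's unit is reported in degrees (the SPM convention for
realignment parameters); the QC comparison is a strict inequality, so a
value exactly at 1.5 passes.

# Numerical choices and degenerate inputs

* The band-pass is an ideal rectangular DFT filter (the convention of the
  classic ReHo tooling); DC is always removed because 0 Hz is outside the
  band.  A zero-phase Butterworth alternative sits behind
  `type = "butterworth"`.
* All-constant neighbourhoods make W 0/0 and raise a degenerate-input
  error; a *single* constant series among varying ones is handled by the
  midrank tie correction.  `tiePolicy = "error_on_ties"` refuses tied data
  outright.
* Empirical p-values use the add-one convention, so the smallest attainable
  p is 1/(n_perm+1).  Consequently the 0.001 cluster level requires
  n_perm ≥ 1000; scaled-down runs (n_perm = 200–500 in the test suite)
  assess cluster significance at 0.05 and the package warns whenever
  `nPerm < 1/clusterAlpha`.
* Peak ties (identical |w|) and the decision-value tie g = 0 are broken
  deterministically (lowest linear index; control class) and documented at
  the call sites.
* `permutationNull` stores the full n_perm × D null weight matrix; at
  desk-scale masks (10³–10⁴ voxels) this is a few hundred MB at most, but
  whole-brain masks at 5000 permutations would need streaming, which the
  package does not currently do.

# Problem sizes used by the validation suite

The test and acceptance runs use cohorts of 10+10 to 15+15 subjects on 16³
grids (≈1000 computable gray-matter voxels), 150 volumes at TR 2 s, and
200–500 permutations; null calibration aggregates 40 independent cohorts.
These sizes were chosen so the full suite exercises every stage end-to-end
at desk scale while keeping the statistical targets resolvable (binomial
and KS bounds are evaluated at the corresponding n).

# Known limitations

* LOOCV accuracy on truly exchangeable data sits slightly *below* 50%
  (each held-out subject shifts the training means away from itself); the
  suite asserts absence of above-chance bias rather than an exact 50%.
* Cluster-level inference is nonparametric only; no Gaussian-random-field
  or TFCE alternatives.
* Correlations are computed across patients only and are not corrected for
  anxiety/depression covariates.
* The pipeline assumes spatially aligned inputs; no registration,
  slice-timing or smoothing is performed (the generator produces aligned
  data, and smoothing is deliberately absent to preserve fine-grained
  local patterns).
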