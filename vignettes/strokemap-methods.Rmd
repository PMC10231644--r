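---
title: "Models and design choices in strokemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in strokemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(strokemap)
```

# Scope and model

strokemap relates binary lesion masks in a common space to a continuous
symptom score (the HADS-D depression subscale, 0–21) through four
inference routes: multivariate SVR lesion-symptom mapping (SVR-LSM), the
same machinery on normative-tractogram disconnection maps (SVR-SDSM),
lesion network-symptom mapping from a normative resting-state connectome
(LNSM), and a circuit-based network damage score (NDS). All four share
one statistical backbone: nonparametric permutation inference with
cluster-level family-wise-error control from the null distribution of
the maximum suprathreshold cluster size.

# The SVR mapping model

Patients are rows, coverage-mask voxels (damaged in at least
`min_lesion_overlap = 5` patients) are columns. Lesion volume is
regressed out of both the behavior and every feature column; behavior is
z-scored. The ε-SVR dual is solved on a precomputed kernel by coordinate
descent (`src/`). Because the response is centered, the intercept is
dropped, which removes the dual's equality constraint and leaves a
box-constrained separable problem — a deliberate simplification with a
provably convergent solver. The test suite checks the solution against
the Karush-Kuhn-Tucker conditions of the stated objective and against
planted-feature recovery rather than against any external solver.

Hyperparameters default to the published toolbox values C = 30, γ = 5,
ε = 0.1 with an RBF kernel; they are exposed in `analysis_config()` and
a linear kernel is available for validation. These values are assumptions
(the originating toolbox defers them to a supplement): notably, with
γ = 5 on binary lesion vectors the RBF kernel is nearly diagonal, so the
back-projected β-map approaches the mass-univariate covariance map — a
known property of these defaults, not a bug.

## Inference normalization

Two scale pathologies matter for the voxel-level permutation null of β:

* raw dual coefficients grow with fit difficulty, so permuted (hard to
  fit) responses produce systematically larger |β| than a well-fit
  observed response — ranking raw β can invert the test;
* z-scoring each β-map across voxels (the display convention) lets true
  signal inflate the map SD and deflate its own z.

The package therefore unit-normalizes each fit's dual coefficient vector
before back-projection; per-voxel permutation ranking is then scale-free.
The acceptance suite verifies the resulting familywise false-positive
rate against its binomial band on null cohorts. The *reported* z-map
stays the conventional within-mask z-score of β, sign-flipped so z < 0
means damage associated with higher scores.

## Permutation scheme

Behavior permutations are re-residualized against the nuisance columns
before refitting (Freedman–Lane); permuting the residuals alone (the
Kennedy scheme) proved markedly anticonservative at desk-scale n during
development and was rejected on the calibration criterion. Voxel p-values
include the observed map in the null set, so min p = 1/(P+1); cluster
p_FWE = (1 + #{perm max ≥ observed})/(P + 1). Cluster connectivity
defaults to 26 (configurable; the convention is unstated in the source
methods).

# LNSM

Preprocessing order is smooth (5 mm FWHM Gaussian, zero-padded
separable kernel) → multiple regression (intercept, 6 motion parameters,
mean WM, mean CSF, global mean) → zero-phase order-2 Butterworth
band-pass 0.01–0.08 Hz → censoring of frames with framewise displacement
above 0.5 mm. FD uses the Power convention (sum of absolute backward
differences, rotations on a 50 mm sphere) — the source cites FD without a
formula. The band-pass is designed by bilinear transform and applied
forward-backward with odd-reflection padding and steady-state initial
conditions (the standard zero-phase recipe); the tested contract is
amplitude retention ≥ 90 % at 0.04 Hz and ≤ 10 % at 0.2 Hz.
Censoring is applied after filtering, following the stated order of
operations; a run with fewer than 10 surviving frames is refused.

ROIs are the gray-matter portions of lesions (GM probability ≥ 0.10,
inclusive; empty results exclude the patient as a pure white-matter
lesion). The seed series is the first left singular vector of the
time × ROI-voxel matrix, unit-variance, sign-aligned with the ROI mean.
Seed maps are Fisher-z transformed with r clipped at ±(1 − 1e−7), and
averaged across all subjects and runs. The GLM tests the slope of
behavior on map value per voxel, two-tailed at p < 0.001 — the SVR
pipelines are one-tailed by the stated sign convention, but network maps
carry meaningful signal in both directions. The primary threshold is the
parametric t quantile applied identically to observed and permuted maps;
cluster-level inference is again the max-cluster-size permutation null.

# Disconnectome

Streamline-lesion intersection and voxel visitation use exact
segment-grid traversal (Amanatides–Woo), not vertex membership: a
vertex-only test misses voxels between consecutive points (a vertex mode
is kept for comparison). Per-subject binary maps are overlaid into a
percentage map (multiples of 100/n_subjects) and binarized at ≥ 60 %
(inclusive). Maps are built directly on the 2 mm analysis grid; the
native-to-standard transform of the original workflow is out of scope.
Patients whose binary map is empty are excluded with the fiber-tracking
failure reason recorded.

# Network damage score

The circuit map is the voxelwise one-sample t across normative subjects
of their (run-averaged) z-maps for a 9 mm-diameter spherical seed
(center-inclusion voxelization at voxel centers; diameter, not radius).
The score is the unthresholded sum of circuit t-values under the lesion —
no threshold is stated for the summation, and a positive-only option
exists for sensitivity analyses. Scores are residualized against lesion
volume; the group test is a two-tailed permutation t-test (pooled
variance), exhaustively enumerated when the number of label assignments
is at most 10⁶, Monte-Carlo otherwise, with the continuous variant using
the Pearson correlation as statistic.

# The synthetic world

The generators define one fixed "stated world" (24³ grid, 2 mm voxels,
n = 60 patients, 8 normative subjects, 120 timepoints at TR 0.72 s —
a desk-scale stand-in for two 15-minute runs):

* **Lesions** are connected random blobs grown by random-walk dilation
  with log-normal target volumes (median ≈ 110 voxels ≈ 0.9 ml on this
  grid, matching the ~1 % of brain volume typical of the target cohort).
  Seed voxels follow a Gaussian spatial weight centered on one vascular
  territory plus a uniform floor — a single dominant arterial territory,
  as in a middle-cerebral-artery stroke cohort. This clustering is what
  makes a ≥ 5-patient coverage mask non-trivial at n = 40–60; with
  uniform seeding, desk-scale cohorts produced unrealistically sparse
  coverage and ~45 % coverage exclusions (the realistic reference rate
  is ~5 %).
* **Scores** follow
  `round(clip(4.4 + effect_size · overlap_frac + N(0, noise_sd), 0, 21))`
  with defaults base 4.4 and noise SD 3.7 (the target cohort's observed
  moments) and effect_size 10.
* **Time series** are shared band-limited community signals (quadrant
  partition of gray matter) plus voxel noise; within-community
  correlation exceeds between-community correlation by construction.
  Motion is a slow random walk (translations SD 0.02 mm/frame, rotations
  0.0002 rad/frame) with optional injected step displacements that
  produce exactly one FD spike each.
* **Tractograms** are three straight bundles with per-streamline Gaussian
  lateral offsets and smooth bends; spread 0 makes every subject's voxel
  path identical.

What a green test does **not** establish: the world has no hemodynamics,
scanner artifacts, anatomical tract geometry, registration error, or
lesion-anatomy coupling beyond the single-territory bias; effect
recovery here shows the inference machinery is sound, not that the
method would detect effects of this size in real cohorts.

# Numerical choices and degenerate inputs

* Mask downsampling: block mean thresholded at 0.5 with ties → 1
  (preserves small lesions; the source never states its interpolation).
* Zero-variance voxels: set to 0 and logged (seed maps, circuit t-map);
  excluded and logged (GLM).
* p-maps store 1 outside the analysis mask; all permutation p-values lie
  in [1/(P+1), 1].
* The SVR solver stops at max dual-coefficient change < 1e−8 or 2000
  sweeps; kernels with zero diagonal entries (empty feature rows) pin
  the corresponding coefficient to zero.
* Exhaustive vs Monte-Carlo permutation switches at ≤ 10⁶ assignments;
  degenerate groups (zero pooled variance) give t = 0 (equal means) or
  ±∞, keeping p well-defined.
* All cross-map operations require identical shape and affine; nothing
  resamples implicitly.

# Known limitations

In-sample prediction performance only (no cross-validation, matching the
original operating point); the β back-projection is exact only for the
linear kernel; YAML configs are restricted to a flat key:value subset
(JSON is the first-class format); atlases are not shipped — the overlap
report takes any integer-labeled volume.
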