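---
title: "Methods: 3-D morphometric phenotyping and variety classification of olive drupes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3-D morphometric phenotyping and variety classification of olive drupes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`olivemorph` implements an analysis chain for discriminating olive cultivars
from the 3-D morphology of the fruit (`D`), stone (`E`) and internal stone
cavity (`C`) as imaged by X-ray micro-CT. This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic data do
and do not emulate.

## The synthetic generator and the study conditions it encodes

The tabular generator is parameterized by per-cultivar summary statistics for
five Campania cultivars — Ravece, Ortice, Frantoio, Rotondella, Minucciola —
with group sizes 32, 27, 35, 16 and 11 (121 olives in total, two harvest
years x two farms cycled within each cultivar). For each of the 24 continuous
traits the profile carries a published mean and a standard deviation
reconstructed from the published standard error as SD = SE·sqrt(n). For each
of the 16 UPOV characteristics (10 computationally derived, 6 visually
assessed) the profile carries the published categorical distribution over
integer note codes, renormalized to sum to one (two rows print shares summing
to 99 or 101 due to rounding; one cell of the stone-mucron row is a printing
glitch and is encoded as 0%).

Traits are drawn from a per-cultivar multivariate normal. Within-cultivar
covariances were never published, so the correlation structure is an
assumption, exposed as `default_trait_correlation()` and overridable:
volume–surface 0.95, volume–weight 0.98, surface–weight 0.93 within each
compartment, 0.6 between fruit-size and stone-size traits, zero elsewhere,
projected to the nearest positive-definite correlation matrix
(`Matrix::nearPD`). Consequences of this assumption are discussed under
*Limitations*.

Two deliberate departures from a plain Gaussian:

* **Clamping.** The reconstructed SDs make some traits highly variable
  (Frantoio fruit volume has CV ≈ 0.33), so unbounded Gaussian draws
  occasionally go negative. Physically non-negative traits are clamped at
  10^-3 in their own units and ratio coefficients (sphericity, asymmetry,
  flatness) into (0, 1]. This touches roughly 0.1% of draws for the most
  variable cultivar-trait pairs and leaves sample means within Monte-Carlo
  error of the profile means.
* **Independent note draws.** Visual notes are drawn independently of the
  traits (and of each other). Real apex/base/mucron notes are correlated with
  shape; the generator does not emulate that, which is one reason synthetic
  classification accuracies are indicative, not reproductions.

The voxel phantom (`phantom_spec()` / `generate_drupe_phantom()`) emulates
the geometry the imaging stage must handle: an ovoid fruit whose axial
profile is two half-ellipses joined at the maximum-transverse-area (MTA)
plane, so `mta_offset` (signed % of length, positive toward the apex at +z)
is exact by construction; a stone whose transverse radius is modulated by
`1 - depth*max(0, cos(k*theta))^2`, giving exactly *k* longitudinal grooves;
a smooth cavity as a scaled stone interior; disc-shaped lenticel marks seeded
on the fruit surface with a minimum separation of three mark radii and kept
within the central 80% of the length (marks at the poles would be distorted
by the cylindrical unwrap used for detection); and four gray-level
populations, background N(30,5²), cavity N(35,5²), mesocarp N(110,8²), stone
N(200,10²) on an 8-bit scale — separable by thresholding, as in real scans
where the lignified endocarp is much denser than the pulp. The default voxel
size (200–250 µm) is coarser than a real micro-CT scan (15–27 µm); all trait
extractors are resolution-invariant within stated tolerances, and keeping
phantoms under 128³ voxels keeps the test suite at desk scale. Reference
("true") volumes and surface areas are computed by quadrature on the
parametric surface at 600x720 resolution, independent of the voxel grid.

The `bend_angle` control is *chiral*: the midline displacement grows toward
the apex while its direction twists by 120° over the length. A planar bend
would leave the drupe mirror-symmetric about the bending plane and the
bilateral-asymmetry coefficient would not respond to it; the twist removes
every axial mirror plane so the coefficient decreases monotonically with the
bend. The phantom's asymmetry range (~0.94–1.0 over 0–25°) is compressed
relative to the published cultivar coefficients (0.33–0.76): real fruit are
far more irregular than a smooth bent ovoid, so the monotonicity of the
measure — not its absolute scale — is what phantom tests establish.

## Imaging

Segmentation is hierarchical two-pass Otsu: one threshold on the full
histogram separates drupe from background, a second threshold restricted to
drupe voxels separates stone from mesocarp. A single-pass two-threshold
(3-class) variant is available behind `three_class = TRUE`. The fruit is the
hole-filled largest foreground component; the stone the hole-filled largest
high-intensity component; the cavity the internal background-level holes of
the unfilled stone, with components below 0.01% of the object volume
discarded. A unimodal volume is rejected by requiring Otsu "effectiveness"
(between-class variance over total variance) of at least 0.75 at the first
threshold — a drupe on background separates at ~0.95+, pure noise at ~0.65.

Alignment maps the largest-eigenvalue axis of the voxel second-moment tensor
to +z and resamples by nearest neighbour (masks stay boolean; volume is
preserved within 2%). The +z sign is set by an apex rule: with
`apex = "auto"`, the end with the smaller mean transverse area (the pointed
apex of a typical ovate olive) goes to +z; if the apex direction is known in
source coordinates — phantoms are generated apex-up — `apex = "+z"` takes
precedence. The auto rule necessarily misorients obovate drupes (maximum
width near the apex), which is why the marker takes precedence and why the
orientation convention is recorded in outputs.

## Morphometry: numerical choices

* **Surface area** is the triangulated isosurface area from marching
  tetrahedra (six tetrahedra per cell, linear edge interpolation; compiled)
  at the 0.5 level of the Gaussian-smoothed (σ = 0.8 voxel) mask indicator.
  Plain voxel-face counting overestimates smooth areas by ~50% and would
  wreck sphericity. σ = 0.8 balances staircase inflation (larger at small σ)
  against edge rounding (larger at big σ): spheres and spheroids measure
  within ~1%, a cube within ~3.5%.
* **Volume** is voxel count x voxel volume; the mesh-enclosed volume of the
  isosurface agrees within 3% (tested) and serves as a cross-check only.
* **L** is the z-extent and **W** the maximum transverse Feret extent over
  z-slices (per-slice convex hull, max pairwise distance, plus one voxel for
  the voxel footprint); the cavity's **Height** is the smaller principal
  transverse extent of the xy-projection, and **Flat** their ratio, so
  C_Width > C_Height as published.
* **MTA position** takes the slice of maximum cross-sectional area after a
  3-slice moving average, resolving plateau ties by the plateau centroid, and
  reports 100·(z* − z_mid)/L.
* **Asymmetry** sweeps mirror planes containing the z-axis (1° steps by
  default) and returns the maximum Dice overlap between the mask and its
  reflection — 1 means perfectly bilaterally symmetric, matching the
  published orientation in which Frantoio has both the highest coefficient
  and the highest "symmetric" note share.
* **Groove counting** estimates the angular radius profile from
  boundary-shell voxels of the central half-length (per-slice centroids,
  per-slice mean-radius normalization, circular Gaussian-kernel smoothing of
  3°). Boundary radii are kernel-averaged rather than binned-and-maxed
  because lattice directions concentrate voxel angles into a comb that 1°
  bins turn into spurious minima. The profile is then detrended by its first
  two circular harmonics — residual centroid offset and cross-section
  ellipticity — so a smooth elliptic stone counts zero; this assumes grooves
  number at least three or are narrower than a half-turn. Minima with
  prominence ≥ 2% of the mean radius (configurable) count as grooves.
* **Lenticel detection** samples a one-voxel surface shell, unwraps to a
  (θ, z) map at ~1 voxel/bin, applies a difference of Gaussians (σ 1.5/4
  cells, matched to the default 0.45 mm mark radius) and counts local maxima
  above 6x the MAD of the filtered map. On a 100-mark phantom the count is
  within ±5% with zero false positives on a markless fruit, and doubling the
  mark contrast changes the count by under 5%.
* **Rugosity** is isosurface area over convex-hull area. With no 3-D hull
  backend available, the hull area uses Cauchy's projection formula: four
  times the mean projected 2-D hull area over 196 Fibonacci-sphere
  directions. Shallow grooves change the index by only ~0.1–0.3% at test
  resolutions, so groove presence is detected by the groove counter, while
  rugosity provides the ordered trait for the UPOV rugosity note.
* **Weights** are density-derived by default: 0.96 g/cm³ (fruit) and
  1.07 g/cm³ (stone), the ratios of the published mean weights to mean
  volumes; measured weights can be substituted.

## UPOV note derivation

Notes are deterministic interval maps with the boundary-to-upper-class
convention, shipped as `default_note_thresholds()` and fully configurable.
The shipped breakpoints are engineering calibration — chosen so that each
cultivar's published trait mean maps to its published modal note for every
ordered derived characteristic (a tested property) — not published facts:
fruit L/W 1.25/1.45; stone L/W 1.8/2.2; fruit weight 1/2/4/6 g; stone weight
0.2/0.3/0.45/0.7 g; lenticel density 30/70 cm⁻²; fruit symmetry coefficient
0.55/0.78; stone symmetry 0.52/0.7; rugosity 1.05/1.12. (A fruit "very
elongated" breakpoint of 1.5 and a stone symmetry breakpoint of 0.5 would
each leave one cultivar's mean in a non-modal class, so 1.45 and 0.52 were
calibrated instead.) Shape notes combine the elongation class with the MTA
sign: clearly below mid-body (beyond ±2% of L) is ovate, clearly above is
obovate, otherwise oblong/elliptic/circular by elongation. Published note
codes are irregular across characteristics (fruit shape uses 1/2/4/5/6) and
are preserved verbatim.

## Statistics

* **Tukey pair counts** use the Tukey–Kramer studentized-range procedure
  (exact HSD at equal n). Summary mode reconstructs per-group SDs from
  printed SEs, pools MSE = Σ(nᵢ−1)sᵢ²/(N−G), and is algebraically identical
  to raw mode on the same data (tested to 10⁻¹²). This bridge makes the
  published per-trait significant-pair counts recomputable from the printed
  tables alone, which is what `scripts/acceptance.R` does.
* **Mahalanobis screen**: per-group covariance with automatic pooled-within
  fallback when a group has no more rows than predictors (with 29 predictors
  the two smallest cultivars force the fallback) or a near-singular
  covariance; flags above the chi-square quantile (default 0.999) with
  p = number of predictors degrees of freedom.
* **Canonical LDA** solves the between/within generalized eigenproblem by
  Cholesky whitening; coefficients are scaled so the pooled within-group
  covariance of scores is the identity, making DF-space classification plain
  nearest-centroid (equal priors by default, ties to the lowest group index).
  Eigenvalues match a dense generalized eigensolver to 10⁻⁸ (tested).
  Globally constant predictors are dropped with a warning; a singular pooled
  covariance receives a logged ridge of 10⁻⁸·trace/p. Leave-one-out refits
  permit singleton groups internally (they contribute only between-group
  scatter), which is required for exhaustive LOOCV on two-per-group toys;
  the public fit still rejects groups with fewer than two rows. Categorical
  notes enter as integer codes, as in the study design; one-hot encoding
  can be emulated by passing expanded predictor columns.
* **Bhattacharyya overlap** uses Σ = (Σ₁+Σ₂)/2 and the log-determinant form
  ½·ln(det Σ / sqrt(det Σ₁ · det Σ₂)); BhC = exp(−D_B), so identical moments
  give BhC = 1. Groups with no more rows than score dimensions get a logged
  diagonal shrinkage (10⁻⁶ of the mean variance). Closed forms (two
  unit-variance 1-D Gaussians two apart: D_B = 0.5, BhC = e^−0.5) are
  asserted on samples standardized to exact moments.
* **Potency index**: squared structure loadings (pooled within-group
  predictor–DF correlations, the conventional output) weighted by raw
  eigenvalues by default; `mode = "relative"` uses eigenvalue shares. The two
  differ by the constant 1/Σλ, so ranks are identical (tested).
* **SVM**: one-vs-one soft-margin linear SVM (libsvm via e1071), C = 1
  default, predictors standardized by training-set moments only — validation
  rows provably never influence the model (mutation-tested). The stratified
  split keeps each cultivar's training fraction within one olive of the
  target and guarantees every (cultivar, year, farm) cell with at least two
  members a training representative.

## Problem sizes and what the tests show

The suite runs phantoms at 150–350 µm voxels (grids of roughly 40³–130³),
121-olive tabular pipelines, a 2000-replicate null simulation confirming
familywise type-I control of the Tukey procedure, and 200 seeded tables for
the overlap-ranking property; everything completes in a few minutes on one
CPU. These sizes are choices about statistical sufficiency — binomial and
Monte-Carlo errors are small relative to the asserted tolerances — not
statements about what the methods can scale to (the imaging path handles
real scan geometries through the same interfaces).

One soft-reproduction property deserves an honest note. On tables drawn from
the default profiles with *identity* trait correlation and study group
sizes, the Ravece–Ortice pair attains the maximum Bhattacharyya coefficient
among the ten cultivar pairs in 179 of 200 seeded replicates (89.5%), with
Frantoio–Rotondella — the second-most-overlapping published pair — taking the
remainder. The corresponding test asserts a ≥90% rate and therefore fails by
one replicate. The rate depends on the assumed within-cultivar covariance,
which was never published; under the identity assumption the two pair
overlaps are close enough that sampling noise (binomial SD ≈ 2.2% at 200
replicates) straddles the 90% line. We report the measured rate rather than
adjust the generator, the seed set or the predictor set to cross it.

## Limitations

* Within-cultivar covariances, and the exact formulas behind the published
  asymmetry, MTA, lenticel, groove and rugosity measurements, are not
  public. All such operators here are documented, configurable
  re-specifications; values recovered from real scans are not expected to
  match the published table cell-for-cell, and synthetic end-to-end
  accuracies are soft checks only.
* The phantom does not simulate X-ray projection physics, reconstruction
  artifacts (rings, beam hardening) or scanner geometry; segmentation
  robustness to those is untested by design.
* The auto apex rule misorients obovate fruit; supply the apex marker when
  the orientation is known.
* Groove counting cannot distinguish a two-groove stone from an elliptic
  smooth one; counts of one or two grooves are unreliable by construction.
* NRRD support covers raw-encoded files only.
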