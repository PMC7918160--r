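---
title: "Methods: pairwise GTV agreement and background-relative PET thresholding"
author: "gtvAgree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise GTV agreement and background-relative PET thresholding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`gtvAgree` analyses two linked questions about gross-tumor-volume (GTV)
definition in radiotherapy planning:

1. **How much do clinicians disagree?** With no gold-standard target volume,
   disagreement is quantified pairwise: every observer's contour is compared
   with every other observer's, giving k−1 comparisons per observer per
   patient for k observers (5 per observer per patient in the canonical
   6-observer design).
2. **Can a high-contrast PET tracer segment the tumor automatically?** The
   automatic GTV at multiplier m is the voxel set with
   SUV ≥ m × b, where b is the mean standardized uptake value in a
   healthy-tissue background region of the same patient. Three multipliers
   (1.5, 2.0, 2.5) produce three nested candidate volumes whose sizes are
   compared with the manual GTVs.

Because no patient imaging ships with the package, every stage is exercised
on synthetic PET/CT phantoms with known ground truth; the phantom module is
first-class, tested code.

# Data model and conventions

All volumes live on axis-aligned voxel lattices (`ImageGrid`: shape,
spacing in mm, origin). Voxel indices are 1-based in R; the world position
of voxel (i,j,k) is `origin + (c(i,j,k)-1) * spacing`, i.e. the origin is
the *center* of the first voxel, matching NIfTI center-of-voxel transform
semantics. Oblique acquisitions are rejected at read time
(`unsupportedOrientationError`); axis flips and permutations in the stored
transform are canonicalized so that world coordinates increase with index
along every axis. Masks are serialized as unsigned 8-bit 0/1 volumes.
Files are written with version-2 NIfTI headers, whose double-precision
geometry fields let spacing and origin round-trip exactly (version-1
headers store them as 32-bit floats); readers accept either version.

Grid equality is enforced with explicit tolerances — shape exact, spacing
within 1e-6 mm, origin within 1e-3 mm — so that masks resampled or read
back from storage compare as expected without bitwise fragility.

# Overlap metrics and the evaluation region

For an ordered pair (test, reference) on one grid the confusion counts are
plain voxel-set cardinalities; DSC, precision, sensitivity and specificity
follow the standard confusion-matrix forms. Two conventions required a
decision:

- **Specificity needs a finite negative region.** True negatives are counted
  inside an explicit evaluation region; by default the bounding box of the
  union of the two masks dilated by a 20 mm margin (configurable), clipped
  to the grid. Specificity is otherwise an artifact of the scanned field of
  view; the margin is exposed as a config knob precisely because reported
  specificities in multi-observer studies are very sensitive to it.
- **0/0 ratios return `NA`**, an explicit undefined flag excluded from
  downstream means — never a silent 0 or 1, which would bias per-observer
  summaries (e.g. precision of an empty test mask).

The first argument is always the observer being evaluated; precision of
(A,B) equals sensitivity of (B,A), and pooled over all ordered pairs the
grand means of precision and sensitivity coincide — a consistency check the
test suite enforces.

# Surface distance to agreement

Surfaces are the mask-true voxels with at least one face-adjacent (6-
neighbourhood) mask-false or out-of-grid neighbour. Distances are Euclidean
between surface-voxel *centers* in physical mm, reported in cm: for each
test-surface voxel the minimum distance to the reference surface, then mean
(mean DTA) and maximum (max DTA, the directed Hausdorff distance). Both
directed versions and their symmetrization are returned; the pairwise
design consumes the directed value with the evaluated observer as "from".
Center-to-center distances carry a known upward bias of at most half a
voxel diagonal relative to point-to-facet distances; this is accepted in
exchange for an exact, oracle-testable definition. The nearest-neighbour
search is brute force in compiled code — contractually required to equal
the all-pairs oracle exactly, with no approximation.

# Automatic segmentation

- The background statistic is the **mean** SUV over voxels whose centers
  fall in the ROI (median available); an ROI smaller than 10 voxels or a
  non-positive mean is a hard error.
- The threshold comparison is **inclusive** (SUV ≥ m·b), fixed arbitrarily
  and documented so tests can be bit-exact.
- Components are labeled with **26-connectivity**, the most permissive
  standard choice, so fragments touching only at edges or corners are not
  split. Components below `min_component_ccm` (default 0.1 ccm) are
  removed to suppress single-voxel noise islands; a search region, when
  given, restricts thresholding and drops components not intersecting it.
- Manual plausibility correction is modeled as a replayable **edit list**
  (remove component at seed / add component from donor / subtract mask)
  rather than interactive editing, so corrected runs remain reproducible.
  A remove edit whose seed hits no component warns and is a no-op.

Unedited GTVs at increasing multipliers are nested, so volumes are
non-increasing in the multiplier — the property behind the ordered size
medians such studies report.

# Rigid transfer

Transforms are *inputs* (per-patient 4×4 matrices in JSON), never
estimated: clinical registrations are manually adjusted, so estimation
would add an uncontrolled stage. Masks are carried to the planning grid by
mapping each target voxel center through the inverse transform and taking
the nearest source voxel. Nearest-neighbour (rather than
linear-interpolate-then-threshold) resampling keeps masks binary without a
threshold choice and reproduces the characteristic angular degradation of
contours transferred from a finer PET grid to 3 mm planning slices. On
study-like grids, spheres of radius ≥ 10 mm survive transfer with ≤ 15%
volume change and round-trip DSC ≥ 0.80 (tested).

# Statistics

- **Unit of analysis.** ANOVA observations are the per-comparison metric
  values (k−1 per observer per patient, pooled over patients); groups are
  observers. This is the simplest reading of "differences between
  observers" and deliberately ignores within-patient correlation, exactly
  as a naive one-way ANOVA would; a property test checks the design is not
  grossly anticonservative under a common error level. F is computed from
  the between/within sums of squares and the p-value from the F
  distribution (`stats::pf`, i.e. the regularized incomplete beta);
  degenerate inputs (all values equal, or zero within-group variance with
  unequal means) are hard errors rather than Inf/NaN.
- **Wilcoxon rank sum.** The statistic is the rank sum of the first sample
  with mid-ranks for ties. The two-sided p is exact by full enumeration
  when the total sample size is at most `exact_limit` and there are no
  ties, otherwise a normal approximation with tie and continuity
  correction. The default limit of 20 keeps the canonical 7-vs-7 patient
  volume comparison on the exact path.
- Two-sided tests throughout; no multiplicity correction by default
  (matching common practice in contouring studies), with Holm/Bonferroni
  available via `p_adjust`.
- Undefined metric values are dropped, never imputed; summary `n` columns
  report how many values actually entered each mean.

# The synthetic phantom cohort

The generator emulates a multi-observer contouring study, not PET physics.

- **Lesion profile.** SUV(x) = B + Σ (P−B)·exp(−d²/2σ²) plus optional
  Gaussian noise, clipped at 0. A Gaussian radial profile (rather than a
  hard-edged plateau) is essential: it makes the three thresholds produce
  genuinely different volumes. A low-uptake halo is expressible as a second,
  wider Gaussian component in the `lesions` list (off by default). With
  noise off, the threshold surface is the analytic sphere
  r_m = σ√(2 ln((P−B)/(B(m−1)))), the package's main closed-form oracle.
- **Default conditions.** PET grid 2 mm isotropic; planning-CT grid
  1×1 mm in-plane with 3 mm slices; background SUV 1.0; noise sd 0.1
  (about 10% of background, a plausible reconstructed-PET noise level);
  per-patient lesions with σ between 7 and 11 mm and peak SUV between
  roughly 7 and 11, chosen so manual GTVs span a clinically plausible
  15–50 ccm range; a ground-truth PET→CT transform of a 2° rotation plus a
  few-mm shift, emulating residual rigid-registration offset.
- **Observers.** The "true" GTV each observer contours is the threshold-2.0
  surface mapped into CT world. Parametric-sphere mode jitters center
  (isotropic Gaussian) and radius (Gaussian plus a systematic bias);
  distance-field mode thresholds the truth's signed Euclidean distance at a
  smooth Gaussian random field (white noise convolved with a separable
  Gaussian kernel of the requested correlation length, empirically rescaled
  to the requested sd), producing spatially correlated, non-spherical
  boundary errors. If a perturbation annihilates the mask the draw is
  retried up to 10 times with a shifted seed, then errors.
- **Calibration.** A requested mean pairwise DSC is translated into jitter
  sds by Monte-Carlo evaluation of the closed-form two-sphere Dice (lens
  intersection volume) with common random numbers, solved by root finding;
  center sd equals the scale, radius sd half of it. Voxelized masks on the
  planning grid recover the requested mean within about ±0.03.
- **Determinism.** All randomness flows from one master seed through a
  deterministic integer fan-out (kept below 2³¹) to per-patient and
  per-observer seeds; the global RNG state is never left modified
  (`withr::with_seed`). Identical seeds give byte-identical NIfTI and CSV
  output.

**What the phantoms do not emulate** — scanner point-spread, scatter and
reconstruction artifacts, realistic anatomy and heterogeneous uptake,
respiratory motion and deformation, and observers who consult additional
imaging. Passing tests therefore demonstrate the *correctness of the
computations and the internal consistency of the design*, not clinical
performance; the printed clinical ranges of any particular patient study
are not reproducible from synthetic data.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run, as the package's own
validation design: 1000 random 16³ mask pairs against brute-force oracles
(metrics exact, DTA within 1e-9 cm); the analytic phantom at 1 mm voxels
(volumes within 5% of closed form); 10⁴ null ANOVA simulations (type-I
0.05 ± 0.01); 200 simulated observer pairs per calibration target; 20
replicate 7×6 cohorts for the outlier-power check (one observer at 3×
boundary error; power > 0.8). Rigid-transform validity uses 1e-9 on
orthonormality and determinant; inversion round-trips to 1e-9 (rotation)
and 1e-6 mm (translation).

# Known limitations

- Only axis-aligned grids; oblique data must be resampled upstream.
- Voxel-center surface distances (no sub-voxel surface model) and
  center-inclusion voxelization of spheres.
- The pooled one-way ANOVA ignores within-patient correlation; a
  mixed-effects analysis is out of scope by design.
- Binary masks only: no probabilistic contours, no consensus (STAPLE-type)
  truth estimation, no DICOM-RT I/O.
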