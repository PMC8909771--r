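---
title: "Methods: fiducial registration, needle guidance and ablation-margin assessment"
author: "arguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fiducial registration, needle guidance and ablation-margin assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arguide)
```

## The problem

Augmented-reality guidance for percutaneous liver tumor ablation rests on a
chain of geometric computations: a CT volume of the patient, acquired with
radiopaque skin fiducials in place, is segmented; the fiducials seen by a
tracking camera are matched against the fiducials segmented on CT to
estimate the rigid image-to-patient transform; a skin-to-target trajectory
is planned and the tracked needle (carrying a five-marker clip) is steered
along it with color-coded alignment feedback; and after ablation the pre-
and post-procedure volumes are co-registered to quantify how much of the
tumor and of a 5-mm periablational margin was actually destroyed, with
technical success defined as complete tumor ablation together with more
than 90 % of the margin ablated.

`arguide` implements this chain as a desk-scale toolkit. Real patient data
are replaced throughout by a seeded synthetic phantom generator, so every
stage is testable against known ground truth.

## Coordinate conventions

All world coordinates are millimetres in a single right-handed (LPS-style)
frame. Voxel indices are 0-based and refer to voxel *centers*:
`worldFromVoxel(grid, c(0,0,0))` is exactly the grid origin, and
`voxelFromWorld` is its algebraic inverse (round-trip identity to
1e-9 mm). Masks are stored boolean and resampled between grids by nearest
neighbour only, which avoids partial-volume ambiguity in coverage counts.

## The synthetic phantom

`makePhantom()` renders a CT-like scene from constant tissue HU values
(air -1000, soft tissue 45, spleen 50, liver 60, tumor 30, enhanced
vessels 150, bone 700, markers 2000; optional Gaussian image noise). The
default grid is 128 x 128 x 60 voxels at 0.7 x 0.7 x 2.0 mm - the 2-mm
slices and sub-millimetre in-plane pixels of the emulated abdominal CECT
acquisition, at a reduced in-plane matrix so a scene builds in about two
seconds; the clinical 512 x 512 matrix is available through the
configuration. Tumors are hypodense spheres (diameters restricted to
0.5-4 cm) placed inside the liver envelope, clear of the vessels.

Twenty fiducials are placed on the anterior body surface by rejection
sampling under two constraints: a minimum separation (default 15 mm) and a
*non-repetitive pattern* - no two pairwise distances of the constellation
closer than a distinctness tolerance. For the 5-marker needle clip (10
pairwise distances) the default tolerance is 2 mm. For 20 markers the
multiset has 190 distances spanning at most ~135 mm on a body-sized
surface, so gaps above 2 mm are impossible by pigeonhole; the default skin
tolerance is 0.1 mm. This is not a weakness of the matcher: correspondence
never relies on a single distance gap but on voting over the full
19-distance signature of each marker followed by a rigid-fit verification,
and the correspondence study below shows 100 % recovery at 0.5-mm tracker
noise.

The tracker itself is abstracted as an `ObservationModel`: a rigid
world-to-tracker frame, i.i.d. per-axis Gaussian noise (sigma, mm) and
per-marker dropout. Stereo triangulation error is folded into sigma, which
keeps the geometric contract testable without camera-calibration
machinery. Breathing is modelled as a rigid translation of the internal
structures, with skin fiducials following at an attenuation factor
(default 0.3) - the simplest model that reproduces the documented failure
mode (target shift relative to a skin-registered frame) while remaining
fully auditable. Deformable motion, textured CT noise and ablation heat
physics are deliberately out of scope: passing tests demonstrate the
geometric pipeline, not robustness to real tissue appearance.

## Segmentation

`segmentAuto()` is a threshold / connected-component / morphology pipeline
tuned to the phantom palette (largest liver-band component, closed at 3 mm
and hole-filled so hypodense tumors and enhanced vessels inside the liver
are retained; markers are components above 1200 HU). It is a declared
stand-in for the proprietary segmenters used clinically, which are not
published; the pipeline contract needs masks and marker centroids, not a
clinical-grade segmenter, and it is validated on phantoms only. Marker
centroids are intensity-weighted and labelled by a deterministic spatial
sort - correspondence is established downstream by geometry, so labels
need only be stable.

`segmentTumorSeeded()` grows a region from a seed point, constrained by an
HU band around the seed intensity and a maximum radius, then closes the
result. With `band = 0` on an exactly uniform background every voxel
qualifies, so the no-growth degenerate case only manifests on noisy
(all-distinct) data; the function flags degenerate growths (single-voxel
or ball-filling) rather than guessing.

## Fiducial registration

`fitRigid()` is the closed-form least-squares rigid fit: demean both point
sets, factorize the cross-covariance by SVD, and guard against reflections
by flipping the smallest singular direction when the orthogonal factor has
determinant -1. The fiducial registration error (FRE) is the RMS residual;
under i.i.d. per-axis noise sigma with N fiducials its expectation follows

  E[FRE^2] = (1 - 2/N) * 3 sigma^2,

which the test suite and acceptance script verify by Monte Carlo
(N = 20, sigma = 0.5 mm, expectation 0.675 mm^2, 2000 trials, 5 %).
Target registration error (TRE) against a known truth transform is
available for simulation studies and reproduces the classical lever-arm
behaviour (error grows with distance from the fiducial centroid).

`matchConstellation()` establishes correspondence without labels: each
observed marker's sorted distance signature is scored against each
reference signature within a tolerance (default 2 mm, chosen above the
~0.7 mm distance noise implied by 0.5-mm per-axis tracker noise); a
mutually distance-consistent seed assignment is grown greedily, verified
by a rigid fit, and refined by one nearest-neighbour reassignment pass.
Hypotheses are accepted only below an FRE ceiling (default 5 mm, matching
the accuracy regime of the guidance system), and among acceptable
hypotheses the one explaining the most markers wins, FRE breaking ties -
this prevents a small, accidentally well-fitting subset from beating the
full correct correspondence. Exhaustive permutation search over 20 markers
is infeasible (20! hypotheses), but `matchExhaustive()` provides the
brute-force oracle for up to ~8 markers and the test suite checks
agreement on noisy 7-marker problems. At least 4 observed markers are
required - the matcher tolerates up to n - 4 occlusions.

## Guidance

`planTrajectory()` scores candidate skin entries (body-surface voxel
centers, deterministically subsampled to at most 5000) lexicographically:
feasibility first (the entry-to-target segment must keep a minimum
clearance, default 2 mm, from every forbidden mask, checked by sampling
the segment at half the finest voxel pitch against the obstacle distance
transform), then minimal path length, with a spatial sort as the final
tie-break. The clinical notion of the "most suitable" path is not
published; this scoring is a declared stand-in and every threshold is
logged in the outputs.

`needlePose()` fits the five-marker clip model to its observations
(reusing the rigid fit; signature matching when the observations are
unlabelled) and maps the calibrated tip offset and shaft axis into the
world frame; a clip-fit FRE above the ceiling raises a tracking-lost
error. Needle bending is not modelled - the pose is rigid, consistent
with a rigid coaxial introducer. `alignmentStatus()` encodes the
blue/green display rule: green iff angular deviation <= 1.0 degree and
lateral target offset <= 2.0 mm, boundaries inclusive; the thresholds are
configurable and sit deliberately below the ~3-mm accuracy regime, since
no display tolerance is published. The recommended tip overshoot beyond
the deep tumor margin defaults to 6 mm, the midpoint of the recommended
5-7 mm window.

`simulateSession()` chains everything: segmentation, skin-constellation
registration, planning, and a tracked insertion in which the operator is
modelled as converging the *estimated* needle tip (averaged over 3 tracker
frames) onto the *displayed* target, so the true tip inherits the stacked
registration and clip-tracking errors. Sessions are deterministic under a
fixed seed. Noiseless sessions end within half a voxel diagonal of the
target; the mean tip-to-target error grows monotonically with tracker
noise (0.25 / 0.5 / 1.0 mm arms, 100 sessions each in the acceptance
script). These are simulation properties of the error model - the
clinical 3.2-mm accuracy is a patient measurement and is not claimed to be
reproduced by simulation.

## Confirmation

`marginShell()` builds the periablational margin as the metric dilation of
the tumor minus the tumor, using an exact anisotropic Euclidean distance
transform (Felzenszwalb-Huttenlocher separable algorithm, implemented in
C++); chamfer approximations were rejected because margin percentages at
5 mm are sensitive to metric error at 2-mm slice spacing. The shell is
clipped to the liver by default when a liver mask is supplied - tissue
outside the organ cannot be ablated - and the flag is logged in every
report. One rasterization property is worth stating: distances are
measured between voxel centers, so the digital shell undershoots the
continuous spherical shell by up to half a voxel at its outer boundary
(about 2.5 % in volume at 0.5-mm voxels, converging as voxels shrink).
Margin *residual percentages* are unaffected to first order because
numerator and denominator share the boundary bias; the concentric-sphere
oracle (tumor r = 10 mm, necrosis R = 13 mm, margin 5 mm) reproduces the
analytic residual 100 (15^3 - 13^3)/(15^3 - 10^3) ~ 49.6 % within 1.5
percentage points at 0.5-mm voxels.

`registerPrePost()` aligns the pre- and post-ablation organ masks rigidly:
centroid plus principal-axes initialization (all four proper sign
combinations tried) followed by a deterministic coordinate-descent
refinement of the six pose parameters (steps 2, 1, 0.5, 0.25 mm/degree)
that maximizes Dice overlap under nearest-neighbour resampling. The
clinical confirmation software uses an unspecified non-rigid tool; rigid
registration is a declared divergence that suffices for phantom validation
and keeps an auditable oracle. Registration below Dice 0.5 fails loudly.

`assessAblation()` maps tumor and shell into the post frame and reports
residuals as 100 |X \\ necrosis| / |X|. The flags follow the strict rule:
complete ablation iff the tumor residual is exactly 0; margin success iff
the margin residual is strictly below 10 % (a residual of exactly 10.0
fails, because the endpoint demands *more than* 90 % ablated); technical
success is their conjunction. Applied to the packaged per-lesion residual
table this yields 12 of 15 margin successes - the three residuals at
10.1, 12.1 and 14.1 % fail - and the toolkit reports the flags as
computed rather than reconciling them with any published per-study
aggregate. An empty necrosis mask is assessed (100 % residuals) with an
explicit warning flag rather than an error.

## Reporting

Records mirror the per-target clinical tables: patient, target, size (cm),
tip-to-target distance (mm), time to target (min), verification modality
(US/CT), residual 5-mm margin (%) and the success flags. The loader
normalizes decimal-comma cells (the packaged table ships one, verbatim)
with a warning. Summaries use exact arithmetic with the sample standard
deviation (n - 1) - the convention consistent with the published
dispersions - and round only at presentation (one decimal). The packaged
table's size column averages 1.553 cm while its printed overall row says
1.56 +/- 0.55; the fixture ships the table verbatim and the discrepancy is
documented, not corrected. Rendered reports are byte-deterministic and
embed every configurable threshold, so each run is self-describing.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run on: one 128 x 128 x 60
phantom scene (shared across session arms), 81^3 voxel sphere fixtures at
0.5 mm for the margin oracle, 2000-trial FRE calibration, 200-trial
correspondence study, and 100 sessions per noise arm. Every random draw is
seeded; the acceptance script derives independent sub-seeds from its
`--seed` argument. All generation is reproducible bit-for-bit under a
fixed seed.

## Known limitations

- Segmentation is palette-based and will not transfer to real CT.
- Breathing is rigid; deformation and hysteresis are not modelled.
- Pre/post registration is rigid where clinical tools are non-rigid;
  phantom necrosis volumes are spheres.
- The operator model is a one-step fixed-point correction; human factors
  (tremor, partial corrections, repositioning) are not simulated.
- Margin quantification counts voxels; sub-voxel surface effects appear
  only through the convergence behaviour described above.
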