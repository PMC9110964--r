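---
title: "Dual-phase CT segmentation for PCNL planning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-phase CT segmentation for PCNL planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalseg)
```

## The problem and the model

Percutaneous nephrolithotomy punctures the kidney through a calyx to reach
a stone, and the planning question is geometric: where are the calculi,
what is the shape of the urine-filled pelvicalyceal system they sit in, and
how do both relate to the bony landmarks? A dual-phase CT study answers it
with contrast physiology: in the non-contrast (native) phase calcified
stones are the densest renal structures, while some minutes after contrast
injection (the excretory/delayed phase) the collecting system fills with
iodinated urine and becomes radio-dense itself. Bone is dense in *both*
phases. That phase-dependence is the entire segmentation model used here:

* **calculus** — very high intensity in the native phase;
* **skeleton (bone)** — a band of intensities constant across both phases;
* **collecting system** — in the delayed band but *not* bone.

No statistical model is fitted; the classifier is fixed intensity bands
plus binary morphology, which is why the method is transparent,
deterministic, and sensitive to the acquisition protocol in a way the
parameters below make explicit.

## Pipeline stages and their parameters

### Intensity band shift

All thresholds are defined on an 8-bit display scale obtained by the
linear transfer function mapping the Hounsfield band [−548, 800] onto
[0, 255] (`band_shift()`), clamping outside the band. The band edges are
protocol constants, not tunables: moving them re-scales every threshold
below. Values are kept *continuous* after the shift — no 8-bit rounding —
so thresholds compare against exact positions and no unstated rounding
rule can flip boundary voxels. Clamping (rather than discarding) keeps the
grid complete; everything below −548 HU (air, lung) lands exactly at 0 and
everything above 800 HU (dense bone cortex, stone, concentrated contrast)
at 255, which is precisely why the calculus band starts at 250: stones
saturate the top of the scale.

### Median denoising

A single median filter pass, cubic neighbourhood of radius 1 (3×3×3),
borders by nearest-value replication (`median_denoise()`). The kernel
radius is deliberately the smallest useful one: infundibula are thin
tubular structures and a wider median eats them. The radius is
configurable; the tests pin the filter to a brute-force per-voxel median
oracle up to 10³ grids.

### Rigid co-registration

The two phases are acquired minutes apart with the patient supine, so the
transform family is rigid (3 rotations about the volume centre + 3
translations). The native phase is the fixed image — every stone threshold
applies on the native grid, making it the natural common frame — and the
delayed phase is moving. The similarity is Mattes-style mutual
information: a 32×32 joint histogram over a fixed random subset of
fixed-image samples with linear partial-volume weighting on both intensity
axes, moving values by trilinear interpolation. The optimiser is
regular-step gradient descent on scaled parameters (rotations scaled by
50 mm/radian so a unit step means roughly a millimetre of peripheral
motion), step halved on direction reversal or failed step, re-grown 1.5×
on success, two resolution levels, at most 100 iterations per level per
restart.

Four implementation details matter and were each forced by a measurable
failure mode on the phantom; they are the package's own design choices:

1. **Off-grid (jittered) sampling.** Metric samples are drawn at voxel
   centres plus a uniform sub-voxel jitter, with fixed values read by
   interpolation. Sampling exactly on the lattice makes mutual information
   artificially sharp at whole-voxel offsets (the classic interpolation
   artifact) and can trap the optimiser one voxel from the truth.
2. **Gaussian pyramid.** Each resolution level smooths with sigma equal to
   its decimation factor before striding. Without smoothing, voxel noise
   builds sharp spurious optima; with it the metric landscape around the
   optimum is smooth and unimodal.
3. **Border sample margin.** Samples within 8 mm of a volume face are
   excluded. Samples that slide off the moving volume as the transform
   changes shrink the effective overlap, and mutual information famously
   *increases* as uninformative overlap is lost — enough to displace the
   optimum by a millimetre along a weakly-informative axis.
4. **Moments initialisation.** The translation starts at the offset of the
   two intensity centroids. A cold identity start can sit exactly on a
   noise-induced metric ridge.

Determinism: the sample set is drawn once per level from a recorded seed,
so the objective is a fixed, reproducible function of the six parameters;
`coregister()` also restores the caller's RNG state.

### Segmentation

`segment_skeleton()` runs the six-step dual-phase chain (native band
[117, 180] → particle removal, cube 3 → dilation, cube 3; delayed band
[130, 255] → particle removal, cube 3; intersect). The published
description of the method numbers these steps inconsistently (its step 5
references the output of step 3 where step 4's output is clearly meant);
the implementation follows the only reading under which the skeleton is
the cross-phase-constant tissue and the collecting system, obtained by
subtracting the skeleton from the cleaned delayed-band mask, is the
delayed-only contrast-filled space. The subtraction direction (step 5
minus step 6) is likewise the only anatomically meaningful one.

Threshold bounds are inclusive on both ends — "lower/upper" naming leaves
no other sensible contract, and the boundary behaviour is codified in a
test (`[116, 117, 180, 181]` → `[0, 1, 1, 0]` at 117/180).

Morphology conventions: "particle removal" is opening *then* closing, in
the listed order; all elements are solid cubes in voxel space (anisotropic
spacing is ignored — element sizes are specified in voxels); out-of-grid
voxels are background for erosion and dilation alike; and with even-sized
elements (the calculus path uses edge 2) the second operation uses the
*reflected* element, which keeps opening and closing translation-neutral.
The dilation between the native and delayed paths is one iteration of a
cube of edge 3 (unspecified in the source description; chosen to match the
particle-removal element scale, configurable). Where diagnostics need
connectivity (e.g. counting stones), 26-connectivity is used, the 3D
foreground standard.

The stone may legitimately appear inside the collecting-system mask: the
delayed band [130, 255] contains stone intensities, and no carve-out is
applied because the stated steps perform none. The consequence is pushed
into volumetrics, where it belongs.

### Volumetrics

`mask_volume_mm3()` is the voxel count times the voxel volume. Because the
segmented collecting-system mask can contain the stone, `compute_metrics()`
exposes a `psv_convention`:

* **union** (default): PSV is the mask as segmented — the whole urine-space
  cavity, stone included. Faithful to the stated subtraction steps.
* **exclusive**: PSV excludes calculus voxels — contrast-filled space only.

The convention changes the SV/PSV ratio (0.0910 vs 0.1001 on the default
phantom), so it is recorded in every metrics report. Volumes are reported
in mm³ with cm³ alongside; the source description states no unit.

### Surface extraction

`extract_surface()` extracts the 0.5-isosurface of the 0/1 mask field and
returns physical-coordinate meshes for STL export. Two deliberate
deviations from the naive approach:

1. **Tetrahedral decomposition instead of the classic cube table.** Each
   lattice cell is split into six Kuhn tetrahedra (the Freudenthal
   triangulation, which tiles space consistently), and each tetrahedron is
   contoured independently. The classic 256-case marching-cubes table has
   ambiguous face configurations that can leave holes; the tetrahedral
   variant of the algorithm is watertight by construction, and
   watertightness is a hard contract here (`mesh_measures()` volumes are
   only valid on closed surfaces).
2. **Sub-voxel band-limiting before extraction.** On a raw binary field
   every vertex lies at an edge midpoint and the surface is a 45°
   staircase whose area *systematically* overestimates a smooth object's —
   measured at +9% for the classic table and +28% for the tetrahedral
   variant on a radius-10 voxel sphere, far outside the 5% accuracy bound
   the package tests demand. A Gaussian of sigma 0.7 voxel applied to the
   mask field restores sub-voxel vertex placement: sphere volume error
   −2.3%, area error +0.7%. Sigma is configurable and 0 disables the
   smoothing (the default was originally "no smoothing", and was changed
   because the measurement above proves that default cannot meet the
   package's own accuracy contract). The cost is a controlled bias: volume
   shrinks by roughly sigma-over-curvature-radius effects (−2 to −4% for
   stone-sized objects), which is why *volumetrics use voxel counts, never
   mesh volumes*.

The field is zero-padded by one voxel before extraction so structures
touching the grid boundary close. Interactive rendering is out of scope by
design; the STLs load in any viewer.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds a stated world, not a tuning knob:

* 96³ voxels at 1 mm isotropic (a down-scaled but geometry-faithful stand-in
  for 512×512 × 0.625 mm clinical reconstructions);
* tissue means: background −80 HU, soft tissue 40 HU, bone 300 HU, excreted
  contrast 450 HU (delayed phase only), stone 900 HU; Gaussian noise,
  SD 10 HU. Under the default shift these land at 88.5, 111.2, 160.4,
  188.8 and 255 (clamped) — each exactly where the fixed bands need it:
  bone inside [117, 180] *and* [130, 255]; contrast inside [130, 255] but
  above the native bone band; stone inside [250, 255]; soft tissue below
  117. `verify_bands()` audits this placement, including the probability
  mass the noise puts across each threshold, and `generate_phantom()`
  refuses specs whose means miss their intended bands (e.g. a 500 HU
  stone: f(500) ≈ 198.2 < 250);
* geometry: an elliptic-cylinder soft-tissue body; two vertical bone
  columns (spine/rib surrogates) embedded in it — embedded, because bone
  bordered by air rather than soft tissue would lose its boundary voxels
  to partial-volume mixing below the 130 threshold, which is an artifact
  of a wrong world, not of the method; a renal-pelvis ellipsoid
  (16, 12, 10) mm semi-axes with three radius-4 calyx cylinders growing
  from its surface; one stone ellipsoid (8, 6, 5) mm semi-axes inside the
  pelvis (analytic volume 4/3·π·abc = 1005.3 mm³);
* the delayed phase shares the anatomy with the collecting-system region
  raised to the contrast mean, carries its own noise draw (made *before*
  the misalignment resampling, so interpolation smoothing is realistic),
  and is resampled through a known rigid misalignment (default 2° about
  the slice axis + (3, −2, 1) mm). Out-of-field voxels are filled with
  background mean *plus noise*: a real reconstruction is noisy everywhere,
  and a constant fill was measured to put a sharp column into the joint
  histogram that displaced the registration optimum by a full voxel.

What it does **not** emulate: real anatomy (no atlas kidneys), partial
volume beyond trilinear interpolation, beam hardening, streak artifacts,
excretion-timing variability, obstruction grades. A green phantom test
therefore establishes the *pipeline's* correctness — thresholds applied as
stated, morphology exact, registration recovering a known transform,
volumes counted right — not clinical segmentation accuracy on patient
data, whose intensity distributions are set by scanner and contrast
protocol, not by this package.

## Numerical choices and degenerate inputs

* Thresholds compare continuous values; no rounding anywhere in the chain.
* Registration metric: 32 histogram bins, 20 000 samples, minimum step
  0.005 scaled units (~5 µm); insufficient overlap (<10% of samples valid)
  returns the worst metric value instead of an error mid-descent, while a
  geometrically disjoint pair fails fast with a registration error.
* Isosurface interpolation parameters are clamped to [10⁻⁶, 1−10⁻⁶] along
  each edge, so vertices never coincide exactly and no zero-area triangle
  is emitted even when field values equal the iso level exactly.
* Empty masks: volume 0 and PSV 0 are values, not errors; the SV/PSV ratio
  on PSV = 0 is flagged undefined (NA), not thrown. Surface extraction of
  an empty mask *is* an error (there is no surface to speak of).
* `run_full_pipeline()` re-raises any stage failure with the stage name
  attached, and logs per-stage voxel counts.

## Known limitations

* Fixed bands mean fixed protocol: data acquired with a different
  reconstruction kernel or contrast timing will need re-derived thresholds
  (the config exposes all of them; the histogram audit helps).
* Vessel segmentation is explicitly out of scope, as in the source method.
* The registration is rigid; gross patient repositioning between phases
  (e.g. supine → prone) is outside the model.
* DICOM support covers uncompressed single-frame CT (explicit/implicit VR
  little endian); encapsulated syntaxes and enhanced multi-frame objects
  are rejected with a clear error. MetaImage is the interchange contract.
* On the phantom, skeleton recall is bounded by partial-volume losses at
  bone boundaries after two interpolating resamples (generation +
  alignment); the measured ~0.95 recall is a property of the stated world
  as much as of the method.
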