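---
title: "Multimodal 4D ray-casting and contour assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal 4D ray-casting and contour assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(voxray)
```

voxray is a desk-scale software implementation of the visualization and
quality-assurance toolchain used in radiotherapy planning for moving (lung)
targets: fused direct volume rendering of mixed-resolution 3D/4D PET/CT
data together with delineation surfaces and iso-dose surfaces, plus the
quantitative layer used to judge internal target volume (ITV) delineations
— rasterization of structure sets, majority-vote consensus, Dice and
Hausdorff surface distances, conformity of rater judgments, dose-volume
histograms, and central/peripheral tumour location classification. A
synthetic 4D breathing phantom provides seeded, fully characterized input
data so every stage can be exercised and checked without patient data.

This vignette records the models, the conventions, the tunable parameters,
and the design decisions taken where more than one reasonable choice
existed. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## The data model: one world, many grids

Every source — image volume, delineation, dose — lives on its own regular
grid (`grid3d`): origin of the first voxel centre (mm), per-axis spacing
(mm), voxel counts, and an orthonormal direction matrix. Clinical 4D
PET/CT planning layouts mix very different resolutions (CT-class ~1 mm
in-plane grids against 4 mm PET grids and ~5 mm dose grids); the central
contract of the renderer is that **no volume is ever resampled onto
another volume's grid**. Each source is evaluated in its own geometry at
shared world-space sample points.

Conventions, fixed once:

* voxel indexing is 0-based and voxel-centred in the geometry API
  (`world_to_voxel`), with voxel `i` owning the half-open slab
  `[i - 1/2, i + 1/2)` in voxel units; time bins are 1-based in the R
  interface, as R users expect;
* interpolation of image and dose values is trilinear for all modalities
  (the interpolation order per modality is not fixed by common practice;
  trilinear everywhere is the declared choice), with support on the hull
  of voxel centres; points outside a source's hull contribute the outside
  value 0 and zero opacity;
* binary masks are categorical and therefore membership-tested by nearest
  neighbour, never interpolated, whenever a mask must be read at another
  grid's points;
* sheared (non-orthonormal) grids are rejected; oblique ones are fine.

## Transfer functions and windowing

Each image layer maps voxel values to RGBA through a piecewise-linear
transfer function. For functional (PET) sources the transfer function is
coupled to the display window: opacity 0 at and below the lower window
value, a constant cap at and above the upper value, and a linear ramp in
between, at constant colour. The cap defaults to 0.7, the conventional
ceiling that keeps even the hottest uptake translucent enough to see
anatomy through it; the ramp shape between the window bounds is a design
choice (only the endpoints are pinned down by the windowing convention)
and linear is the simplest monotone option.

## The ray-caster

`render()` marches each pixel's ray through the region of interest (ROI)
at a fixed world-space step and composites front to back:

* **Clipping.** The ROI is a per-axis fractional sub-box of the reference
  volume's bounding box (in the reference grid's own axes). All content —
  image samples and surface crossings alike — is clipped to it; rays that
  miss it show the background.
* **Fusion.** At each sample point every enabled image layer is sampled
  in its own grid and mapped through its transfer function; the fused
  sample is the weighted linear combination of the per-layer colours and
  opacities with weights normalized to sum to one (accumulation-level
  intermixing). Layers whose sample point falls outside their grid, or
  which are masked out there, are excluded from the normalization: an
  excluded layer contributes nothing, rather than diluting the others.
  This choice is forced by the masking semantics — masking a layer with an
  empty mask must equal disabling it.
* **Masking.** A layer may be gated by one or more delineations; it is
  visible where at least one of its masks contains the point (union
  semantics, nearest-neighbour membership). Different layers can be gated
  by different structures, e.g. CT-only inside the trachea while PET+CT
  show inside the ITV.
* **Surfaces.** Delineations are rendered as the 0.5 iso-surface of their
  trilinearly interpolated indicator — sub-voxel smooth without any mesh
  extraction; iso-dose surfaces are iso-levels of the dose field in Gy.
  Between consecutive samples, a sign change of (field − iso) localizes
  the crossing by inverse linear interpolation; the crossing is inserted
  as an extra sample at its exact depth in compositing order ("exclusive
  opacity"): it replaces no volume sample, and an opaque surface
  naturally absorbs everything behind it. Normals are central differences
  of the field in the source's own grid, negated and normalized; shading
  is Blinn-Phong (ambient + diffuse applied to the base colour, an
  achromatic specular lobe, channels clamped), with a headlight default.
* **Step size and opacity correction.** The step defaults to half the
  smallest voxel spacing among enabled sources; opacities are corrected
  for step length relative to a 1 mm reference step via
  `1 - (1 - a)^len`, where `len` is the actual segment length covered by
  the sample (the final partial segment of a ray is weighted by its true
  length, so shrinking the ROI to (near) zero extent fades to background
  rather than leaving a one-step artifact). An explicit `step_mm`
  override exists so that two scenes can be forced onto coincident sample
  points — this is how the no-resampling contract is verified
  behaviourally: rendering a 4 mm source in its native grid equals
  rendering a trilinearly pre-upsampled 1 mm copy, because trilinear
  interpolation restricted to an aligned sub-cell is reproduced exactly
  from that sub-cell's corners.
* **Termination.** Compositing may stop early once the remaining
  transmittance drops below 1e-6; any skipped sample could have changed
  the result by at most that transmittance, so images are independent of
  termination to 1e-6 per channel. Rendering is fully deterministic — no
  stochastic sampling — so repeated renders are bit-identical.
* **Depth and picking.** The depth buffer records the first surface hit
  per pixel. `pick_surface_point()` casts a single pixel's ray and
  returns the nearest delineation crossing with its world position and
  reference-grid voxel index, the hook for 3D-to-2D slice navigation.

The camera is a standard pinhole (vertical field of view, pixel-centre
rays), with an orthographic flag for parallel projection.

## Contours and rasterization

Structure sets are stacks of closed planar polygons with world-mm
vertices. The package defines a plain JSON dialect for interchange (see
`write_structure_set()` for the schema) so that contour fixtures are
readable text; masks export as NIfTI. Rasterization assigns each contour
to the nearest slice centre in z (tolerance: half a slice spacing;
anything farther is an error, since silently moving a contour would
falsify geometry), then marks voxels whose centre lies inside the polygon
under the even-odd rule, with boundary-touching centres counted inside as
a deterministic tie-break. Multiple contours on a slice combine by
parity, so nested contours cut holes. The output stays on the full
reference grid by default because the overlap metrics require identical
grids; `crop = TRUE` trims the axial extent to the covered slab range,
and `crop_to_content()` gives the tight 3D bounding box while preserving
every world position.

Majority voting over observer delineations is voxelwise `>= k` of `n`
(3-of-4 being the conventional consensus); `k = 1` is the union — which
is exactly how an ITV aggregates per-bin target positions — and `k = n`
the intersection.

## Overlap and surface-distance metrics

For a test delineation against a reference on a shared grid:

* Dice: `2|A ∩ B| / (|A| + |B|)`.
* Surface voxels: foreground voxels with a background 6-neighbour (the
  grid border counts as background). Distances are Euclidean mm between
  voxel centres, computed exactly with a separable squared distance
  transform (anisotropic spacing respected); sub-voxel or mesh-based
  distances are out of scope.
* Hausdorff statistics: the maximum over both directed nearest-surface
  distance lists; the average and the 95th percentile (linear
  interpolation) are computed on the pooled, symmetrized list. Pooling is
  a declared choice — directed 95% variants exist — and the brute-force
  oracle in the test suite uses the same definition, so the choice is
  pinned by tests.

Rater agreement uses the conformity index = mean absolute rating
difference between the two raters (absolute, not signed: a signed mean
would let disagreements cancel), on the 1 (excellent) to 5 (poor) scale,
with acceptance at rating <= 3.

## Dose-volume histograms

`cumulative_dvh()` evaluates mask membership at the dose grid's voxel
centres (nearest neighbour — consistent with the rasterization convention;
no partial-volume weighting, a known bias for structures small relative
to the dose grid) and reports the fraction of the structure receiving at
least each dose, at bin edges `0, w, 2w, ...` with `w = 0.1` Gy by
default. `fraction(0) = 1` by construction and the curve is
non-increasing; `Dmean` is the arithmetic mean of in-mask voxel doses,
so it is conserved exactly regardless of binning. The same dose levels
used for iso-dose surfaces (e.g. 37.5 Gy) are the natural `V_x` report
levels.

## The breathing phantom

`make_phantom()` builds one virtual patient with the multi-source layout
of a clinical 4D-PET/CT planning case, scaled down so the full pipeline
runs in seconds while preserving the resolution ratios:

| source | spacing (mm) | dims | bins |
|---|---|---|---|
| full-body CT | 1.4 × 1.4 × 4 | 64 × 64 × 40 | – |
| 4D-CT | 1.2 × 1.2 × 2 | 56 × 56 × 48 | 10 |
| 4D-PET | 4 × 4 × 4 | 20 × 20 × 24 | 10 |
| planning CT | 1 × 1 × 3 | 64 × 64 × 32 | – |
| dose | 5 × 5 × 3 | 16 × 12 × 32 | – |

A spherical lesion (default radius 10 mm, soft-tissue HU over lung
background) moves cranio-caudally with `d_z(t) = A sin(2π t / B)`
(default amplitude 10 mm, 10 bins — a realistic lower-lobe motion range).
The PET shows a smooth uptake blob (logistic edge, ~2 mm) at the same
per-bin positions on its own coarse grid, contrast 5:1 over background.
Noise is additive Gaussian on CT (15 HU) and Gaussian-approximated
Poisson on PET, all driven by one seed; geometry is seed-independent, so
different seeds differ only in noise. An airway tube and a mediastinum
slab provide organs at risk positioned so that the default lesion is
disjoint from both at zero margin but overlaps the 20 mm airway margin —
the two regimes of location classification. The ITV is the voxelwise
union of the per-bin lesion masks on the planning grid, and the structure
set carries matching planar contours (the union of z-shifted spheres has,
per slice, the circle of maximal radius over bins, so exact ITV contours
exist in closed form).

The dose model is a logistic falloff of the signed Euclidean distance to
the target surface, `D(p) = prescription · σ(−s(p)/falloff)` (prescription
50 Gy, falloff 3 mm — an SBRT-like gradient), which saturates at the
prescription deep inside the target and decays monotonically outward;
37.5 Gy (75%) is the default reported iso-dose level. Dose is an *input*
in the workflow this package supports; this generator exists to provide
controlled test data, not to model treatment planning physics.

What the phantom deliberately does not emulate: anthropomorphic anatomy,
hysteresis or deformation in the breathing cycle (rigid z-translation
only), PET partial-volume physics, or scanner-specific noise spectra.
Tests passing on the phantom therefore demonstrate geometric and
numerical correctness of the pipeline, not clinical performance on real
data.

## Margin volumes and location classification

Tumour location (central vs peripheral) is decided by overlap with margin
expansions of the proximal bronchial tree and the mediastinum. Dilation
is true Euclidean (voxel centres within the margin distance, anisotropic
spacing respected, via the exact distance transform), and the decision
rule is *any positive overlap* with any margin volume. The clinical rule
set is distance-based and applied by humans with measuring tools; an
automated positive-overlap rule over Euclidean dilations is the declared
equivalent, and margins default to 20 mm (bronchial tree) and 5 mm
(mediastinum), both exposed as parameters since published margin
definitions vary. Cross-grid overlaps are reported on the target's grid
in mm³. Classification is monotone in the margin by construction:
growing a margin can only flip peripheral to central.

## Numerical choices and degenerate inputs

* Ray/box intersection uses the slab method with closed bounds; points
  exactly on a clipping plane are inside.
* Surface crossing detection uses a strict sign-change test on
  (field − iso); a sample exactly at the iso value belongs to the
  "below" side via `<`, a deterministic tie-break.
* Zero-length gradients (flat fields) shade as the unshaded base colour.
* The distance transform seeds unreached cells with a large finite
  sentinel (1e15 mm²) rather than infinity to keep the parabola-envelope
  arithmetic well defined; anything at that scale reads back as `Inf`.
* Degenerate requests error loudly rather than guessing: empty masks in
  Dice/HD/DVH/classification, all-zero weights in fusion, contours
  farther than half a slice from every slice centre, lesions leaving the
  grid at some breathing phase.

## Problem sizes used in tests

The test suite builds everything programmatically: random masks up to
~16³ voxels for brute-force oracle comparisons (all-pairs surface
distances are O(n²)), 64² pixel renders for the integrator-oracle and
mixed-resolution contracts, and the default phantom (plus a few smaller
variants) for end-to-end runs. These sizes were chosen so the whole
suite completes in well under a minute of compute per file while leaving
the oracles dense enough to catch sub-voxel errors; they are scaled-down
analogues, and nothing in the implementation depends on them.

## Known limitations

* DICOM I/O is not implemented (no DICOM toolkit is available to R
  here); interchange uses NIfTI and the JSON contour dialect. The same
  applies to NRRD.
* 4D dose accumulation across breathing phases is explicitly out of
  scope: dose volumes are static 3D inputs.
* Surface distances are voxel-centre distances between surface voxels;
  they upper-bound the continuous surface distance by about half a voxel
  diagonal.
* The renderer is a correctness-first software implementation: a 64²
  fused multi-source frame takes on the order of a second. It is meant
  for reproducible figures and tests, not interactive navigation.
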