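---
title: "Quantifying 3D capillary architecture: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D capillary architecture: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capimorph)
```

## The measurement problem

Cleared-heart two-photon imaging produces three-channel 3D stacks of
ventricular tissue: a gel-perfused capillary lumen channel, a cell-membrane
channel, and a label-free second-harmonic collagen channel.  From each stack
the package computes five scalar morphometries:

* **mean lumen diameter** of the capillary network (µm),
* **capillary density** as total vessel surface area per stack volume
  (µm⁻¹),
* **angular dispersion** of the capillaries (dimensionless, 0–1),
* **myocardial disarray** of the cells (same statistic, cell channel),
* **collagen percentage** of the stack volume.

These per-stack records are then compared across experimental groups (two
rat strains by four ages, both ventricles) with a two-way ANOVA, Fisher LSD
post hoc tests, and Pearson correlations between the vascular and tissue
metrics.

Because no raw image volumes are publicly deposited for this kind of study,
the package ships a first-class synthetic phantom generator
(`generate_phantom()`) whose ground truth is exact by construction.  All
estimator validation in the test suite runs against phantoms or closed
forms.

## Conventions

One set of conventions is used package-wide and is worth stating once:

* arrays are indexed `(z, y, x)`; coordinate and pitch triples are ordered
  the same way; the centre of voxel `[1, 1, 1]` is physical `(0, 0, 0)` µm;
* direction versors are unit `(z, y, x)` vectors, *axial* (headless): `v`
  and `-v` denote the same axis.  Stored versors are reported in the +z
  hemisphere (`z > 0`, ties broken on `y`, then `x`);
* binarization is strictly greater-than: a voxel is foreground iff its
  intensity exceeds the threshold.

## Isotropic resampling

Stacks are acquired with a coarse axial step (2 µm in the emulated
acquisition) and a fine lateral pixel (0.439 µm).  `rescale_isotropic()`
interpolates linearly along z so that the axial pitch equals the lateral
pitch; the output plane count is `round(nz * factor)` with the factor the
axial/lateral pitch ratio (4.5558… for the pitches above, quoted as 4.55
when truncated to two decimals — `isotropic_factor()` keeps full precision
internally and exposes the truncation only for reporting).  Linear
interpolation is used because it cannot overshoot: the downstream
distance-transform radius estimator is sensitive to threshold-crossing
artifacts that spline interpolants can introduce.  Resampling a constant
volume is exact, and an already-isotropic stack passes through unchanged —
both are tested.

## Vessel segmentation and skeletonization

Segmentation is a global Otsu threshold on a 256-bin histogram of the whole
volume (`otsu_threshold()`), the classic maximum-between-class-variance
rule; ties resolve to the smallest qualifying threshold.  Components
smaller than 10 voxels (configurable) are removed before skeletonization as
noise.

`skeletonize()` reduces the mask to a one-voxel-wide, topology-preserving
centerline by homotopic thinning: only *simple* voxels — deletable without
changing the topology, characterized by exactly one 26-connected foreground
component in the punctured 3×3×3 neighbourhood and exactly one 6-connected
background component in the 18-neighbourhood touching a face neighbour —
are deleted, and curve endpoints (fewer than two foreground neighbours) are
preserved.  Deletion proceeds in layers of increasing Euclidean distance
transform so the skeleton settles on the medial ridge, and within a layer
the border is eroded one face direction at a time over eight parity
subfields.  The subfield decomposition matters: a naive sequential scan can
eat an even-width tube longitudinally from one end (no voxel ever becomes
an endpoint), whereas candidates inside one subfield pass are pairwise
non-adjacent, so erosion is symmetric and an axis-offset cylinder keeps its
full length (tested; end erosion is bounded by about the tube radius at the
final layer).

The skeleton is decomposed at junction voxels (three or more neighbours)
into maximal branch-free segments; junction voxels belong to the node, not
to any segment, so lengths are not double-counted.  Terminal twigs shorter
than 5 µm (about one capillary radius; configurable) that hang off a
junction are pruned as thinning artifacts and the graph is rebuilt, merging
the interrupted branch.  Whole free-floating segments are never pruned.

Per-segment measurements (`measure_segments()`) follow the standard
skeleton conventions: local radius is the Euclidean distance transform of
the mask at the centerline voxel; segment volume is `sum(pi * r_i^2 *
step_i)` along the polyline.  Because the thinned skeleton is quantized to
the voxel grid, the point-sampled distance is biased low by up to half a
voxel; the radius used for the diameter statistic therefore takes the
maximum of the distance transform over the voxel's 26-neighbourhood (the
largest inscribed sphere touching the centerline voxel's surroundings).  On
digitized 6 µm cylinders this estimator is accurate to a few percent; the
per-segment *volume*, which squares the radius, is unbiased over sub-voxel
axis placements but can deviate by about ±12% for a single grid-aligned
placement — the tests assert the placement-averaged value.

## Mean lumen diameter: length-binned mean of modes

Segments are grouped by centerline length into half-open bins
`[0,5), [5,10), …, [25,30)` µm; segments of 30 µm or longer are excluded.
In each non-empty bin the Mode of the segment diameters (twice the mean
radius) is taken after discretizing to 0.1 µm — a Mode on continuous values
needs a declared discretization to be deterministic, and ties resolve to
the smaller diameter.  The stack's mean diameter is the arithmetic mean of
the per-bin modes over non-empty bins; empty bins are skipped rather than
zero-filled, which would bias the mean with no physical justification.

## Capillary density: vessel surface per stack volume

The numerator is the area of the triangulated isosurface of the mask at
level 0.5.  The triangulation is marching tetrahedra on the Kuhn 6-tet cube
decomposition — inside a tetrahedron the interpolated level surface is
planar, so there are no ambiguous cases to table.  Triangulating the raw
binary field overestimates smooth-surface area by ~25% (the staircase
effect; voxel-face counting is worse still at ~50%), so the indicator is
first smoothed with a small Gaussian.  The smoothing scale trades staircase
suppression against curvature-driven inward drift of the 0.5 level; σ =
0.7 voxels puts both a digitized sphere (radius 8 voxels) and an
axis-aligned cylinder (radius 4 voxels) within ~1% of their closed-form
areas, and that value is the package default (`surface_density()`,
validated in the tests).  The denominator is the full physical stack
volume.  A skeleton-length-per-volume alternative (µm⁻²) is reported
alongside under an explicit name (`length_density()`); the surface measure
is the primary density.

## Orientation, angular dispersion and disarray

`block_orientations()` tiles the volume into cubic blocks (default 60 µm)
and computes per block the structure tensor — the sum of outer products of
Gaussian-derivative gradients (σ = 2 µm default).  The block's direction is
the eigenvector of the *smallest* eigenvalue: along the axis of an
elongated bright structure the intensity varies least.  Blocks are marked
invalid when they contain almost no signal (foreground fraction below 1%
against a global Otsu threshold), when the tensor is degenerate, or when
its anisotropy `1 − λ_small/λ_mid` falls below 0.1 — an isotropic-noise
block has no meaningful axis.  Edge blocks covering less than half a block
volume are dropped as unstable.  None of these thresholds is physically
critical; all are explicit parameters with the stated defaults.

`local_disarray()` groups blocks into super-blocks (default 120 µm, i.e.
2×2×2 blocks; partial edge groups average over the members they have) and
computes `Disarray = 1 − Alignment` per super-block, where Alignment is the
norm of the mean of the member versors; the global disarray is the mean of
the local values.  Because versors are axial, a sign convention is needed
before averaging.  Sign-fixing against a fixed hemisphere pole looks
natural but is *not rotation invariant*: a cluster of axes lying near the
equator of the chosen hemisphere is split into two antipodal half-clusters
and its alignment collapses, so the same tissue rotated by 90° can change
its disarray from 0.02 to 0.5.  The package therefore sign-aligns each
group's versors to the group's principal orientation-tensor eigenvector
(which co-rotates with the data and ignores signs) before the vector mean.
The numeric anchor cases are unchanged by this choice: identical versors
give disarray 0, an orthogonal pair gives `1 − 1/√2 ≈ 0.2929`, and
hemisphere-uniform axes give 0.5.  A dyadic (orientation-tensor order
parameter) variant is available behind `method = "dyadic"` for comparison.

Applied to the vessel channel the statistic is the capillary **angular
dispersion**; applied to the cell channel it is the **myocardial
disarray**.  Membrane stains outline rather than fill cells, so real cell
channels should be analysed with `invert = TRUE`; the phantom generator
already emits the negative-style image (bright rod interiors), so the
pipeline default is no inversion.

Block averaging makes the measured dispersion a *shrunk* version of the
per-tube orientation spread (each 60 µm block already averages several
tubes); the statistic is therefore comparative, not an absolute cone-angle
estimate — which is also how it is used in the group analyses.

## Collagen percentage

The second-harmonic channel is binarized with the isodata
(iterative-intermeans) threshold — the fixed point of `t = (mean below +
mean above)/2` on a 256-bin histogram, the long-standing default automatic
threshold of general image-analysis suites (Otsu is available behind a
flag).  The percentage is foreground voxels over all voxels of the stack,
with no tissue masking; a per-plane variant exists for stacks with strong
depth attenuation.  Phantom speckle fields at 5/10/25% true fraction are
recovered within one percentage point.

## Group statistics

`two_way_anova()` fits `metric ~ strain * age` with `lm()` and reports
partial (Type II) sums of squares via `car::Anova` — for balanced designs
these equal the textbook closed forms (asserted to 1e-10 in the tests), and
Type II is the declared choice for unbalanced complete designs.  Designs
with empty cells are rejected naming the cell.  `fisher_lsd()` is the
unadjusted pairwise comparison using the pooled ANOVA error on the residual
degrees of freedom; it deliberately applies no family-wise correction (that
is the procedure's defining property, and its inflation of family-wise
error under the null is demonstrated in the test suite).  `pearson_cor()`
and `student_t()` wrap the standard product-moment and pooled-variance
tests; a zero-variance pair with equal means returns p = 1 by convention.
`minmax_normalize()` maps metric columns to [0, 1] for the summary heat
map and is idempotent.

The unit of replication in `run_study()` is the stack (ventricular region),
as in the emulated study design; regions within an animal are not
independent in real data, so per-region replication is a statistical caveat
of the design, not of the implementation.

## The phantom generator

`phantom_spec()` fixes the synthetic study conditions:

* **volume**: 128 µm cube at 1 µm isotropic pitch by default.  The emulated
  acquisitions are 450 × 450 × 300 µm at 0.439 µm lateral pitch; the
  package works at a reduced size so that a full multi-stack study runs in
  minutes on one CPU, and all estimator properties asserted on phantoms are
  size-local (tube diameter, block size and PSF are far smaller than either
  volume).  The full-size geometry is reachable through the parameters.
* **vessels**: 50 capillaries of diameter 6 ± 0.5 µm (capillary scale), a
  ~10% volume fraction matching myocardial capillary content.  Directions
  are von Mises–Fisher about a mean axis (default the +z pole; κ = 20 gives
  the mild alignment of healthy myocardium); centerlines are anchored at a
  uniform interior point, clipped to the volume faces, and perturbed by a
  3 µm transverse sinusoid (wavelength 100 µm) for tortuosity.  A voxel is
  vessel iff its centre is within diameter/2 of a centerline — exactly the
  geometry the distance-transform estimator measures.
* **cells**: rods 80 × 15 µm (myocyte scale) at 50% fill, orientations from
  the same vMF family (κ_cell separately controllable).
* **collagen**: Gaussian-smoothed white noise thresholded at the quantile
  that yields the target volume fraction exactly (before blur/noise).
* **optics**: Gaussian PSF of 1 µm, additive Gaussian noise of 0.08 on a
  0.05→0.85 background/signal scale (SNR ≈ 10), optional Poisson stage;
  intensities are clamped to [0, 1] so stacks are storable as TIFF.
* **truth**: per-vessel centerlines, diameters and analytic
  cylinder surface/volume, canonicalized orientation versors with their
  exact dispersion, the exact collagen voxel fraction, and the pre-blur
  binary masks.

vMF sampling uses the exact inverse-CDF of the cosine on the 2-sphere;
κ = 0 is uniform on the sphere, and the sample mean cosine at κ = 2
matches the closed form `coth(2) − 1/2` in the tests.  Identical spec and
seed reproduce the stack bit-for-bit in memory (generation runs in a
private RNG stream and restores the session RNG); TIFF storage quantizes
intensities to 32-bit steps of 2⁻³².

What the phantom does *not* emulate: capillary anastomosis topology (tubes
cross but do not branch, except through user-supplied centerlines),
depth-dependent attenuation and scattering, spatially varying PSF, and
stitching artifacts of mosaicked acquisitions.  Passing the phantom suite
therefore validates the estimator chain on controlled geometry — it does
not certify performance on real stacks with those additional effects.

## A synthetic two-strain study

`phantom_study_design()` builds the default end-to-end experiment: two
strains × four ages × three regions, the hypertensive strain with twice the
capillary count of the control at every age and an orientation
concentration that falls with age (κ = 30, 12, 5, 2.5) while the control
stays at κ = 30.  `run_study()` then reproduces the qualitative structure
the estimators should reveal: a ~2× density ratio, a significant strain
effect on density at every age, and a positive correlation between
capillary angular dispersion and myocardial disarray.  The numbers printed
by the tests and `scripts/acceptance.R` are computed from this synthetic
study at run time; no group values from any real dataset are asserted
anywhere.

## Known limitations

* Thinning erodes up to about one tube radius from the free ends of
  vessels, and 26-connected polylines overestimate oblique centerline
  lengths by up to ~8%; both effects are far smaller than the between-group
  contrasts the statistics target.
* The per-segment volume formula inherits the ±½-voxel radius quantization
  squared; use the placement-averaged value or finer pitch when absolute
  volumes matter.
* Otsu thresholding assumes a genuinely bimodal histogram; on nearly empty
  stacks (well below 1% foreground) it splits the background noise
  instead.  The phantom conditions and any realistic capillary stack are
  far from this regime.
* All disarray-type statistics are block-size dependent; compare only
  values computed with the same block and super-block sizes.
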