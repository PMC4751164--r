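---
title: "Automatic aortic-root landmark detection: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic aortic-root landmark detection: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aorticroot)
```

## The problem

Sizing a prosthesis for transcatheter aortic valve implantation (TAVI)
requires a handful of measurements of the aortic root taken from a
contrast CT angiography (CTA) scan: the radius of the virtual annulus ring,
the orientation of the annulus plane, and the distances from that plane to
the two coronary ostia (a short distance raises the risk of coronary
obstruction after deployment). These measurements are anchored on six
anatomical landmarks: the sinotubular junction (STJ), the right and left
coronary ostia, and the three basal attachment points of the valve leaflets
— the right-coronary (RC), left-coronary (LC) and non-coronary (NC)
hinge points. Manual landmarking is slow and observer-dependent; this
package detects all six landmarks automatically from three inputs:

* the CTA volume (intensities on a Hounsfield-like scale),
* a segmented aortic-root surface mesh, open at the LVOT and
  ascending-aorta ends (segmentation itself is out of scope — the mesh is
  an input), and
* a centerline running from the LVOT into the ascending aorta.

All coordinates are patient millimeters; the axis convention is documented
as left(+x) / posterior(+y) / superior(+z). The anterior/posterior
labeling rules below are stated in this convention.

## The unwrapped-surface representation

Every detector works on 2D maps obtained by unwrapping the root surface
around the centerline. The centerline is resampled at a uniform arc-length
step (0.5 mm by default) and equipped with multiplanar-reconstruction (MPR)
frames perpendicular to it. Frames are propagated by the double-reflection
rotation-minimizing method, so the in-plane axes carry no spurious twist
and maps have no angular seam; the angular origin is fixed by projecting
patient +x onto the first normal plane (falling back to +y when the
tangent is nearly parallel to +x). Any internally consistent convention
would do; this one is reproducible and makes anterior/posterior reasoning
direct. The pipeline trims the resampled centerline to the slices whose
8-ray probe hits the mesh all around, so slices beyond the open ends never
enter the maps.

`surface_radial_map()` casts, for every MPR slice and angular bin (96 bins
by default), an in-plane ray from the centerline and records the distance
to its first mesh intersection. Cells whose ray misses are inpainted by
angular interpolation; a slice with more than 25 % misses stops the
pipeline, because the surface is then not star-shaped around the given
centerline and the unwrapping is not meaningful.

## Root extents and the STJ

The elliptical LVOT cross-section expresses itself as a strong second
Fourier harmonic of the per-slice radius function r(θ); the three sinuses
of Valsalva as a strong third harmonic. The per-slice ratio
h3 / (h2 + ε) therefore rises sharply over the sinus region while staying
near zero in the LVOT and the tubular aorta. Magnitudes are normalized so
a pure A·cos(kθ) profile gives h_k = A, and ε (default 0.01 mm) keeps the
ratio finite on circular slices, where it is otherwise 0/0.

The ratio profile is smoothed with a 1D Gaussian (SD 2 slices ≈ 1 mm;
second differences amplify noise, and the published description names no
filter) and differentiated twice with the discrete [1, −2, 1] Laplacian.
Among the local maxima of the Laplacian magnitude flanking the global
ratio maximum (the sinus belly), the strongest below is the proximal
extent and the strongest above the distal extent; the STJ is defined as
the distal extent. Peak positions are refined to sub-slice precision by
3-point quadratic interpolation — with integer slice indices the STJ
would jump a whole slice under an arbitrarily small rigid motion of the
inputs. Searching the signed Laplacian instead of its magnitude is
available as a configuration switch (`laplacian_mode`); the magnitude is
the default because both shoulders of a bump are curvature extrema of
opposite sign.

A genuine sinus signature is also required: the peak smoothed ratio must
exceed `min_ratio` (default 2, i.e. the third harmonic must exceed the
floored second). A sinus-free tube otherwise yields arbitrary
noise-driven "extents"; with the floor it fails loudly at the
extent-detection stage, which is the correct behavior for, say, a purely
tubular segmentation.

## Coronary ostia

Contrast-filled coronary arteries are bright. `outward_projection_map()`
averages the volume inside a small probe (length 2.5 mm, radius 0.75 mm)
directed outward from every surface cell — the image of the shell between
the segmented surface and its dilated offset. The probe is implemented as
a bundle of parallel sub-rays, each anchored on the wall along its own
ray via the radial map; a single rigid cylinder would let off-axis sample
points cross a sloping wall into the lumen of a neighboring slice and
create false bright responses at the sinus shoulders.

Two further steps make the search robust:

* `subtract_row_background()` removes each slice's angular median.
  Partial-volume averaging at the lumen boundary produces a bright,
  angularly almost constant baseline ring (strongest where the wall is
  steep, near the STJ). The ostia are angularly localized, so the
  subtraction cancels the ring without touching them. Without it, an
  ostium sitting 8–10 mm below the STJ — which the phantom suite
  legitimately produces — is down-weighted below the ring and lost.
* `weight_by_distal_gaussian()` multiplies the map by a Gaussian in the
  slice position centered at the distal extent (SD 4 mm), encoding the
  prior that the ostia sit near the STJ.

The angular profile (per-column maximum) yields the two strongest local
maxima at least 45° apart (`min_peak_separation`; anatomically the ostia
sit in different sinuses, more than 90° apart — the floor only guards
against one wide bright region producing both detections). For each
ostium angle the axial position is the argmax over slices within a ±2-bin
angular window. Two refinements matter here. First, the axial profile is
divided by the known Gaussian weight before the argmax: the weight decides
*which* bright structure wins, but applied to the flat-topped response of
a tube it tilts the argmax to the tube's distal edge and biases the
ostium height by over a millimeter. (Setting `global_axial = TRUE`
restores the literal single shared axial maximum of the published
description.) Second, both peaks are refined to sub-bin precision by
3-point quadratic interpolation; without this, the ~3.75° angular
quantization (≈ 0.8 mm at a 12 mm radius) dominates the error budget.
Detections are snapped to the nearest mesh vertex, and labeled by the
anterior rule: the more anterior point (smaller +y) is the right ostium.

## Hinge points

Three surface maps are combined:

* a Gaussian-curvature map: per-vertex angle-deficit estimates normalized
  by the mixed Voronoi area (the standard convergent discrete estimator;
  boundary vertices inherit their nearest interior value), resampled to
  the cylindrical grid by nearest-surface-point lookup;
* the minimum-intensity-inward map (MIIAM): the minimum intensity along a
  1.5 mm × 0.75 mm probe directed inward, dark where a leaflet meets the
  wall;
* the maximum-intensity-inward map (MXIAM): the corresponding maximum,
  bright over lumen and calcification.

The three maps have incompatible units, and the published description
multiplies them without stating any scaling. The convention implemented
here rescales each factor to [0, 1] first: curvature is clamped at zero
and divided by its maximum (only convex attachment geometry counts as
hinge evidence — saddles and flat wall score zero), the MIIAM is
inverted so dark leaflet contact scores high, the MXIAM is min-max
rescaled. The product is then a co-occurrence score in [0, 1], invariant
to affine rescaling of the input intensities. This is the largest
interpretive decision in the package; it is configurable in the sense
that the three maps are exported individually and `combine_maps()` is a
pure function of them. A constant factor (e.g. MXIAM in a
calcification-free scan of uniform lumen) is replaced by all-ones with a
warning rather than amplifying noise.

The combined map is lightly smoothed (separable Gaussian, SD 1 cell,
circular in angle) before the search: its intensity factors carry voxel
noise, and the location of an unsmoothed argmax wanders with how the
angular bins happen to sample that noise, which breaks the
rigid-equivariance of the detections at the half-millimeter scale.

The map is then split into three sinus tiles: the sinus peak angles are
the three maxima of the mean radius profile between the extents, tile
boundaries are the angular midpoints between adjacent peaks, and rows run
from 5 mm below the proximal extent (the hinge nadir sits at or below it)
up to the distal extent. If no three genuine radial maxima exist
(angular radius variation below 0.1 mm), tiling falls back to uniform
120° sectors anchored at the third-harmonic phase, with a warning.

Within each tile, the above-half-maximum pixels are reduced by PCA (in
mm-scaled coordinates: slice position versus arc length at the mean sinus
radius) to a principal search direction, with the sign pointing
proximally — the hinge is the proximal end of the leaflet attachment.
A 1D profile is resampled (bilinear, 0.25 mm steps) along that direction
through an anchor cell, and the profile maximum, refined quadratically,
is the hinge; the result is mapped back to 3D and snapped to the nearest
mesh vertex. Two open details were resolved by experiment on the
phantoms:

* the anchor is the tile's maximum cell (with sub-bin refinement), not
  the thresholded centroid: the leaflet attachment crown is V-shaped, and
  when both commissure arms clear the half-max threshold the centroid
  falls between them, pulling the search line onto an arm rather than
  the hinge nadir;
* the anchor is restricted to slices at most 3 mm above the proximal
  extent. The hinge is the basal end of the attachment; without the
  bound, bright distal structures (the commissural crown, the convex
  sinus belly) can capture the anchor.

Labels follow the published rule: RC is the most anterior hinge; of the
remaining two, LC is the more posterior-and-left (largest y + x); NC is
the rest. When two hinges have nearly equal anterior coordinates the rule
is intrinsically ambiguous and a label swap between geometrically correct
detections can occur; positions and all sizing quantities are unaffected.

## Sizing

The annulus plane, center and radius are the circumscribed circle of the
three hinge points, computed exactly from the 2×2 linear system in the
triangle's plane; the plane normal is oriented distally (toward the STJ)
so that signed annulus-to-ostium distances are positive for plausible
anatomy. Reported ostium distances are absolute values (the clinical
convention), with signed values retained for diagnostics. The automated
STJ plane is the MPR plane at the distal extent — the only orientation
the automated detection provides, whereas a manual protocol fits a plane
to three picked STJ points. `compare_reports()` implements the
plane-accuracy measures (center shift, planar angle) and paired
differences used to compare automated with reference measurements, and
the evaluation module provides paired landmark distances (mean, n−1 SD,
median, per landmark and pooled), Bland–Altman limits of agreement, and
the intraclass correlation coefficient in its two-way random-effects,
absolute-agreement, single-measure form ICC(2,1) (the consistency form is
available via an argument). The ICC sample estimate is not bounded below
by −1 at very small n; it is reported unclamped.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds a fully synthetic test case with known ground
truth. The surface radius field r(s, θ) blends an elliptical LVOT
(13 × 10 mm semi-axes) through a three-sinus band (tube radius 12 mm,
sinus depth 2.5 mm over s ∈ [15, 35] mm) into a circular tube, and adds
two basal features: a 1 mm annular waist centered at the hinge level
(the annulus is the narrowest part of the root) and a small convex
attachment nub at each hinge angle whose crest radius equals the
requested annulus radius exactly — so the ground-truth hinge circumradius
is the spec'd annulus radius by construction. The nubs give the hinge
points locally positive Gaussian curvature; with the curvature factor
clamped at zero, a basal attachment modeled as a pure saddle would be
invisible to the combined map, and thin-sheet leaflets alone cannot
create convex wall geometry in a surface that must stay star-shaped.

The volume rasterizes lumen (350), a 1.5 mm wall shell outside the
surface (80), background (−50), 0.9 mm-thick leaflet sheets (100)
descending from a commissural attachment crown (9 mm rise) to a
coaptation level, two contrast-bright coronary tubes (350) leaving the
surface at 60° and 200°, 16 and 14 mm above the annulus, optional
calcification spheres (1200), and additive Gaussian noise (SD 20),
seeded and bit-reproducible. The sinus phase default (100°) places the
right ostium inside the RC sinus and the left inside the LC sinus, so
the anatomical and anterior/posterior labeling rules agree. The
centerline is straight by default; a circular-arc option
(`centerline_curvature`) exercises the curved-centerline code paths.
The mesh is triangulated from the analytic radius field at 0.35 mm ×
1.4° resolution — finer than half a millimeter in both directions
because detections snap to mesh vertices, so the mesh resolution bounds
the detection quantization.

`phantom_suite()` jitters the radius (±15 %, scaling tube, annulus and
LVOT together), sinus depth (±40 %), ostium angles (±20°), ostium
heights (±3 mm) and sinus phase (uniform over its 120° period), with
fixed noise, deterministically from a seed.

What the phantom does not emulate — and what passing tests therefore do
not show about clinical data: realistic CT physics (beam hardening,
streaks, anisotropic noise), irregular calcific leaflets, segmentation
error in the input mesh (the phantom mesh is exact to ≲0.02 mm RMS),
non-trefoil sinus anatomy (bicuspid valves), and motion. Phantom
recovery errors (well under 1 mm) are accordingly much smaller than the
2–3 mm accuracies reported for patient data by comparable methods; the
phantom validates the algorithmic chain, not clinical accuracy.

## Numerical choices and degenerate inputs

* Problem sizes: the default pipeline uses 96 angular bins and 0.5 mm
  slices; the test suite and the acceptance script run a 20-phantom
  jittered suite at these settings (about 3 s per phantom end to end).
* Probes sample 6 axial stations × 5 sub-rays (30 points, trilinear);
  probe sub-rays anchored per-ray on the surface (see above).
* Ray–mesh intersection is Möller–Trumbore over axially bucketed
  triangles; first hit wins (the wall is a thin open surface).
* Degenerate inputs fail as classed conditions carrying the stage name:
  collinear hinge points (degenerate annulus), fewer than two separated
  angular maxima (ostia), flat combined tiles (hinges), non-star-shaped
  slices (unwrapping), fewer than 2 distinct centerline points.
  `run_detect()` converts these into a nonzero exit naming the stage.
* Ties: an isotropic tile PCA falls back to the proximal axis; equal-y
  ostium labels break toward the more leftward point being left.
* The detection chain contains no random number draws; identical inputs
  and configuration give byte-identical outputs, and all phantom
  randomness is derived from explicit seeds.
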