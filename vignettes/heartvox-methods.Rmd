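---
title: "From line-scan strips to vascular curvature: the heartvox processing model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From line-scan strips to vascular curvature: the heartvox processing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartvox)
```

heartvox re-implements, as a desk-scale and fully testable toolkit, the data
processing chain used for whole-heart dual-channel block-face fluorescence
microscopy: line-scan strips are stitched into section images, sections are
stacked into multilevel chunked volume pyramids, display products
(thickness-limited maximum-intensity projections, fuchsia/green channel
merges, depth-coded capillary projections) are rendered, the vascular channel
is segmented, traced and meshed with per-vertex wall curvature, and cellular
features are measured under an explicit scale calibration. Because no public
acquisition of this kind is available at workstation scale, every stage is
exercised against a built-in synthetic heart phantom whose ground truth is
known by construction.

All volumes are integer arrays in `(z, y, x)` order; voxel `(i, j, k)`
(1-based) sits at physical position `((i,j,k) - 1) * voxel_size_um`. The
default sampling is 0.32 x 0.32 um in plane with 1-um sections, the geometry
of high-definition dual-color line-scan block-face acquisition, and
intensities are 16-bit unsigned.

## The synthetic heart phantom

`generate_phantom()` renders two channels from a `phantom_spec()`:

* **Myocardium channel** (counterstain-like). Cylindrical myocytes of radius
  `myocyte_radius_um` (default 6 um) are packed on a square grid with a 1-um
  interstitial gap, in three wall-depth layers whose fiber directions follow
  the layered architecture of the ventricular wall: longitudinal
  (subepicardial), circumferential (mid-wall), longitudinal again
  (subendocardial). Each myocyte carries one ellipsoidal nucleus per
  along-fiber segment (default full axes 15.5 x 3.5 x 3.5 um, major axis
  along the fiber, 1.5x brighter than the cytoplasm) and 1-voxel-thick dark
  transverse gaps every `disc_spacing_um` (default 30 um) standing in for
  intercalated discs, which image dark because the counterstain binds nucleic
  acids. The disc planes are phase-shifted by half a spacing so the volume
  does not begin on an all-dark section.
* **Vascular channel** (endothelial-reporter-like). A user-supplied or
  default branching tree of capsule segments is rendered as bright walls:
  hollow shells for radii above three in-plane voxels, filled tubes below
  (capillary scale). The wall is 1.2x the coarsest voxel pitch thick —
  endothelium-scale at the default sampling, and the minimum at which the
  rasterized shell is free of pinholes (a shell thinner than the voxel
  diagonal lets the lumen leak during hole filling). Capillary-scale
  branches carry elongated bright streaks on their walls, mimicking
  endothelial nuclei. Ground truth records the filled tube mask
  (voxel-exactly the rasterization of the centerline graph), the centerline
  graph itself with per-edge radii, and per-nucleus axes and voxel-counted
  volumes.

Intensities are flat (background 1000, foreground 20000) with additive
Gaussian noise, by default 2% of the dynamic range; the acquisition this
emulates has no published noise or point-spread characterization, so the
flat-plus-Gaussian model is an explicit assumption, chosen as the simplest
model sufficient to exercise threshold-based downstream processing. No
optics (PSF, bleaching, vignetting) and no anatomical chamber geometry are
simulated; consequently the test suite demonstrates correctness of the
*processing*, not robustness to every artifact of real acquisitions.

Identical spec and seed give bit-identical volumes; the RNG state of the
caller is left untouched.

### Strip emission

`emit_strips()` cuts each section into vertical strips of fixed width with a
nominal column overlap, mimicking back-and-forth line scanning; alternate
strips carry a reversed-scan flag (metadata only — pixel order is already
normalized, and no scan-direction distortion is modeled because none is
characterized for this instrument class). Optional jitter perturbs the true
cut positions: column jitter is drawn per strip, while vertical jitter
accumulates strip-to-strip as stage *drift*, which keeps consecutive-pair row
offsets inside the registration search window — the physically sensible
model, since each strip is acquired immediately after its neighbor. True
offsets are returned for ground-truth tests.

## Stitching

`estimate_offset()` maximizes the normalized cross-correlation (NCC) between
the trailing band of the left strip and the leading band of the right strip
over integer translations, within +/-10 columns of the nominal offset and
+/-3 rows (block-face imaging has no large inter-strip drift). The method is
deliberately integer-pixel: the acquisition geometry gives no evidence of
sub-pixel registration, and integer translation keeps the cut-policy
round trip bit-exact. Flat bands (zero variance) and bands whose best
correlation falls below 0.2 — the magnitude expected from independent noise
at band sizes of 64 x 20 and larger — fall back to the nominal offset with a
warning and a `flagged` row.

`stitch_section()` places strips at cumulative offsets. Policy `"cut"` splits
every overlap zone at its midpoint and copies pixels unmodified, so
restitching noise-free strips at true offsets reproduces the section
bit-exactly; `"feather"` ramps linearly across the zone (weights summing to
one, so constant inputs are preserved). Output height is the intersection of
vertically aligned rows, and `row_origin` records where that intersection
sits relative to the first strip's frame so that independently stitched
sections can be re-aligned into a shear-free stack (sections are natively
aligned in block-face imaging; only the stitching crop varies).

## Volume pyramids

`build_pyramid()` stacks sections into level 0 and derives coarser levels by
per-axis block reduction (default factor 2 per axis, stopping when the
coarsest level fits 256^3 voxels). Mean reduction averages the actual
members of partial edge blocks and rounds half-to-even back to 16-bit
integers (so the mean of 0..7 reduces to 4); max reduction propagates the
global maximum unchanged through all levels. The on-disk store is a plain
chunked directory layout — raw little-endian uint16 chunk files plus JSON
metadata per level — functionally a minimal zarr-like store; `read_region()`
fetches only the chunks a region touches, and results are independent of the
chunk shape.

`resample_to_voxel()` serves the display convention of down-sampling to a
10-um grid: it picks the coarsest level not coarser than the target on any
axis and interpolates trilinearly, because the ratio of display to native
sampling (10 / 0.32 = 31.25) is not an integer and nearest-neighbor
decimation would alias. Output voxel `i` samples physical position
`i * target`; the output shape is `ceiling(extent / target)`. Upsampling
below the native voxel is refused.

## Rendering

`max_projection()` is the per-pixel maximum over a slab: one slice for
myocardial detail (the 1-um display convention), hundreds of slices for
vascular connectivity. `merge_channels()` windows each channel to [0, 1],
multiplies by its display color — fuchsia for myocardium, green for
vasculature — and clips the sum to 8 bits, so doubly saturated pixels whiten.

`depth_code()` implements sequential depth coding of a binarized stack: the
color bar is linearized over the number of images, each image gets the
corresponding single color, and the colored images are stacked in order.
Where a pixel is foreground in several slices the later slice wins by
default (`last_hit`, the literal result of sequential stacking), with
`first_hit` as the alternative; both are options because the procedure's
overwrite semantics are genuinely underdetermined. The default color bar is
an HSV hue sweep from blue (240 degrees, shallow) to red (0 degrees, deep),
also configurable. The binarization threshold defaults to a global Otsu
threshold over the slab histogram. `slice_of_origin` stores the winning
1-based slice index with `NA` for background (the R convention for
missingness, in place of a -1 sentinel).

## Vascular chain

`segment_threshold()` marks voxels at or above the threshold (Otsu when
`"auto"`), fills enclosed background cavities — large vessels image as hollow
endothelial walls, and the filled lumen is what tracing and Dice-style
comparisons need — and removes components below a minimum size. Lumen
filling is connectivity-based (background components not touching the volume
border), so a vessel whose open end is clipped by the volume face keeps an
open lumen; slice-wise `apply_manual_edits()` exists for exactly such
corrections, mirroring the manual clean-up step of interactive segmentation,
and its log can be replayed to reproduce any edited mask.

`trace_from_seed()` flood-fills the seeded component (26-connectivity by
default, preserving thin diagonal capillaries), then skeletonizes it by
homotopic thinning: simple points (Bertrand-Malandain characterization:
one 26-connected foreground component in the 26-neighborhood and one
6-connected background component in the 18-neighborhood touching a face
neighbor) are deleted in increasing distance-transform order, with curve
endpoints preserved. Two refinements matter in practice and are part of this
implementation's design:

* deletion runs in six *directional subiterations* per pass (only voxels
  whose face neighbor in the current direction is background), which peels
  one layer per direction per pass — without this, a thin side branch can
  unravel end-to-end within a single pass and vanish before it ever becomes
  a protected endpoint;
* with anisotropic voxels, each direction fires at a rate inversely
  proportional to its physical spacing, so erosion advances isotropically in
  micrometres and arms along the coarse (z) axis are not consumed first.

Spurs — endpoint arms shorter than `prune_factor` (default 3) times their own
mean local radius (from the anisotropic distance transform, half-voxel
corrected) — are pruned iteratively. The trunk is identified first as the
skeleton path maximizing length weighted by local radius (the thickest long
path, the aorta-to-apex trunk of a coronary tree) and is protected from
pruning: a plain longest path can be outranked by a tip-to-tip path through
two long thin branches, and an unprotected trunk overhang shorter than the
pruning threshold would be eaten as a spur. The branch count is the number
of remaining degree-1 endpoints minus the two trunk ends — zero for an
unbranched tube, and the number of side branches for a trunk-and-branches
tree. This count is well defined when the trunk overhangs its terminal
junctions by more than roughly its own radius; stubbier overhangs leave no
skeletal arm (a property of skeletons, not a defect of the estimator), which
is why the phantom's default tree keeps its junctions in the middle half of
the trunk.

### Surfaces and curvature

`extract_surface()` extracts the 0.5 iso-surface of the binary mask with
marching tetrahedra on the conforming Kuhn 6-tetrahedron cube decomposition,
so closed components yield watertight meshes by construction (every edge
shared by exactly two triangles; `is_watertight()` checks this). Two
smoothing stages control staircase artifacts:

* a Gaussian presmooth of the binary field (default sigma 1.5 voxels)
  before iso-surfacing, which removes sub-voxel terracing of the surface —
  without it, discrete curvature on the raw iso-surface is bimodal (flat
  terraces and sharp risers). Presmoothing shifts the level set inward by
  about sigma^2 x curvature / 2, negligible for vessels much thicker than a
  voxel but a real shrinkage for capillary-scale structures: for
  measurement-grade meshes of thin tubes, keep sigma below about a third of
  the thinnest radius (the enclosed-volume tests do exactly that), and
  components too thin to survive presmoothing at all are automatically
  extracted from the raw field;
* Taubin two-step smoothing of the mesh (default 30 iterations of a +0.5 /
  -0.53 Laplacian pair), which relaxes the remaining voxel texture without
  the systematic shrinkage of plain Laplacian smoothing. Thirty iterations
  (rather than a conventional ten) are needed to bring the median discrete
  curvature of voxelized spheres and cylinders within a few percent of the
  analytic value; because Taubin smoothing is non-shrinking, the extra
  iterations cost accuracy nothing.

`vertex_curvature()` computes mean curvature from the cotangent-Laplacian
mean-curvature normal with barycentric vertex areas, signed by the outward
vertex normal (convex outward positive: 1/r on a sphere of radius r,
1/(2r) at mid-cylinder, 0 on a plane); Gaussian curvature from the angle
deficit; and the maximum principal curvature as `H + sqrt(max(H^2 - K, 0))`.
Marching-tetrahedra meshes contain sliver triangles whose pointwise
estimates are outliers, so accuracy statements are about the *median* over
vertices; the mean is not robust on such meshes. One further rasterization
subtlety, stated here because the tests rely on it: geometry exactly aligned
with the voxel lattice (an axis-aligned cylinder through lattice points, a
grid-aligned ellipse) is a degenerate, measure-zero configuration whose
discretization errors are correlated and systematically larger than any
generic sub-voxel placement; oracle fixtures therefore use generic
placements.

`colorize_curvature()` maps the robust [2nd, 98th] percentile range of the
(by default signed) curvature linearly onto a blue-to-red map — minimum
curvature blue, maximum red, matching the usual wall-curvature rendering
convention — with out-of-range values clamped; an absolute-value mode is
available because published renderings do not always state which was used.

## Morphometry

All measurements are explicit about scale (`scale_calibration()`): distances
multiply pixel displacements element-wise by anisotropic pixel sizes;
volumes are voxel counts times the voxel volume, with cohort summaries as
unweighted means and sample (n-1) standard deviations. The nucleus ellipse
fit uses normalized second central moments with the 1/12 pixel-integration
term — the Fit Ellipse convention of ImageJ, the tool this emulates — and
returns the axes of the ellipse with matching second moments; recovery on
rasterized ellipses of 3-20 um axes at 0.32-um pixels has a median axis
error well under 1%. A note on units: the source material reports the
five-nuclei volume statistic as "87.2 +/- 6.1 um", dimensionally a volume;
heartvox treats nucleus volumes as cubic micrometres throughout and flags
rather than silently corrects that reading. The 2D fit follows the
measurement procedure described for single sections; whether a 3D fit was
used for the published axes is not stated.

Vessel diameters are twice the anisotropic Euclidean distance transform at
the skeleton voxel nearest the query point, minus one in-plane voxel
(half a voxel on the radius) to correct for the distance between the last
foreground voxel center and the wall. The correction makes a 1-voxel line
measure one voxel across and a 50-voxel tube measure within 2%, while a
2-um capillary (radius ~3 in-plane voxels) measures ~1.7 um — at that scale
the estimate resolves to the in-plane voxel, consistent with ~2 um being the
resolvability limit of the emulated acquisition.

## Numerical choices and degenerate inputs

* Integer intensity rounding is half-to-even everywhere (base R `round()`).
* NCC candidates with zero-variance bands are skipped; wholly flat or
  sub-threshold overlaps return the nominal offset, flagged.
* Zero-size pyramid regions return empty arrays; out-of-bounds reads error
  with the nearest valid origin.
* `depth_code()` with a threshold outside the data range warns and returns
  an all-background image; a one-slice stack uses the first colormap color.
* Degenerate (zero-area) triangles are excluded from curvature stencils with
  a count in the warning; constant curvature fields colorize mid-map with a
  warning.
* Isolated single voxels yield small closed polyhedra from the raw binary
  field (they cannot survive presmoothing).
* Empty masks error on surface extraction; empty segmentations are returned
  with a warning (they are legitimate for high thresholds).

## Problem sizes

The bundled test and verification runs use phantoms between 48 x 96 x 96 and
96 x 160 x 160 voxels, acquisition-scale strip widths (660 px with 20 px
overlap) on 4-section stacks, a 128^3-scale isotropic tree phantom for the
vascular chain, and 50-ellipse recovery studies; the end-to-end pipeline
configuration is 96 x 128 x 128 at the native anisotropic sampling. These
sizes keep a full verification run in the minutes range on one CPU while
every stage still operates in its intended regime (multi-strip sections,
multi-level pyramids, hollow-wall vessels, capillary-scale branches).

## Known limitations

* The phantom's flat-intensity emission does not model PSF blur, depth-
  dependent attenuation, stitching seams from illumination fall-off, or
  autofluorescence; threshold-based segmentation is therefore easier here
  than on real data.
* Offset estimation is integer-pixel by design; data with genuine sub-pixel
  drift would need a sub-pixel upgrade.
* Branch counting assumes a trunk-with-side-branches topology (a tree); on
  masks with loops the trunk is still the radius-weighted diameter, but the
  endpoint count no longer has the side-branch interpretation.
* Inter-section (z) registration is deliberately absent: block-face
  acquisition yields natively aligned sections, and none is simulated.
* Curvature at capillary scale (radius of a few voxels) is resolution-
  limited; curvature maps are quantitative for vessels at least ~10 voxels
  in radius at the chosen sampling.
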