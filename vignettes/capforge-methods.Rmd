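---
title: "Designing perfusable microcapillary scaffolds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing perfusable microcapillary scaffolds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capforge)
```

`capforge` generates porous capillary membranes for two-photon
lithography (TPL) along arbitrary 3D centerlines, synthesises support
structures, assembles printable chips, and implements the quantitative
QC used to validate prints. This vignette documents the underlying
models, the tunable parameters, the numerical choices, and what the
synthetic test fixtures do and do not demonstrate. All geometry is in
micrometres.

## Centerlines and moving frames

A capillary axis is an ordered point list interpolated per coordinate by
a natural (or periodic, for closed loops) cubic spline against the
cumulative chord-length parameter; degree 1 keeps the exact polyline.
Arc length is accumulated over a dense sampling (20 sub-samples per
segment), and all downstream placement is arc-length parameterised, so
station spacing is uniform regardless of how unevenly the input points
are spaced. Imported CSV paths and the built-in Hilbert generator
default to the exact polyline: the space-filling property (non-adjacent
segments exactly one grid step apart) is then exact, and smoothing is an
explicit choice. For swept tubes the polyline corners are first filleted
(corner cutting at a configurable radius, default the lumen radius) and
fitted with the cubic — a sharp corner would otherwise force the bend
radius below the tube radius and self-intersect the swept surface.

Sweep frames are rotation-minimizing frames propagated by the
double-reflection method, not Frenet frames: the Frenet normal is
undefined on the straight segments that dominate Hilbert-style routings,
while the rotation-minimizing frame is defined everywhere and introduces
no spurious twist (on a planar curve the accumulated twist is zero to
numerical precision). The initial normal is the in-plane direction
`z x t`, so planar build-plane paths get in-plane normals and the
circumferential seam (angle zero) faces a consistent direction; for
near-vertical tangents the projected x axis is used instead. Transport
always runs on a fine grid (400 stations) merged with the requested
stations, so frame accuracy does not depend on the caller's spacing.

## The pore layout

For lumen diameter $l_d$, pore diameter $p_d$ and edge-to-edge pore
spacing $p_s$, the cylinder surface is subdivided into

$$u = \left\lfloor \frac{P_l}{p_d + p_s} \right\rfloor, \qquad
  v = \left\lfloor \frac{\pi l_d}{p_d + p_s} \right\rfloor, \qquad
  s_l = \frac{P_l}{u}, \qquad s_r = \frac{\pi l_d}{v},$$

with $P_l$ the path length. The subdivision counts are real-valued
relations made integer by *flooring* (configurable to round or ceiling):
flooring guarantees the realised pitch never falls below the requested
one. $u$ is clamped to at least 1 and $v$ to at least 3 (fewer than
three circumferential cells does not form a tube), and
$u\,s_l = P_l$, $v\,s_r = \pi l_d$ hold to machine precision by
construction.

Each cell becomes a *picture frame*: a rectangular opening inset by
$p_s/2$ per side, so the opening is $p_d$ across exactly when the cell
pitch divides the surface evenly. The pored surface is generated
directly in parameter space — per cell a 4x4 vertex patch (cell
boundary, frame inset) with the centre sub-cell omitted — and vertices
on shared cell boundaries are deduplicated by their parameter key, which
makes the surface manifold by construction and pore count exactly
$u \cdot v$.

### Side-pore elongation

The TPL writing voxel is strongly elongated along the optical axis
(about 0.6 um lateral vs 3.3 um vertical), so pores that face sideways
tend to print closed. Openings whose outward normal lies within a cone
of 30 degrees (configurable) of the horizontal plane are therefore
stretched circumferentially by a factor of 1.5 (configurable). The
stretch is applied to the pore's own inset rows only; the cell-boundary
rows shared with axially adjacent cells keep the default inset, so
neighbouring cells with different classifications still share identical
edge partitions and the surface stays manifold. Elongation at factor 1
is bitwise the identity.

A note on measuring the factor: the circumferential/axial extent ratio
of an opening equals the elongation factor only when the unelongated
opening is square, i.e. when $s_l = s_r$. The straight reference tube
used in tests and in the acceptance script therefore picks
$l_d = 120/\pi$ um with $p_d = p_s = 5$ um and $P_l = 1000$ um, making
both cell sides exactly 10 um. Measured on the mesh, the expected ratio
is slightly below 1.5 (about 1.49) because the circumferential extent is
a chord of the cylinder while the opening is specified along the arc.

## Thickening and topology checks

The membrane solid offsets every vertex along its stored radial
direction — outward by default, so $l_d$ remains the perfusable inner
diameter — and bridges every boundary loop between the inner and outer
copies. This turns each pore into a through-channel and the tube ends
into annular caps, and it is index-based, so watertightness is exact,
not tolerance-based. The topology is then checkable: a capped tube with
$P$ through-pores is a genus-$(P{+}1)$ surface, so its Euler
characteristic must be $\chi = V - E + F = -2P$. The test suite and the
acceptance script verify this identity exactly, which catches essentially
any pore-cutting or bridging defect.

Thickening refuses configurations whose outer radius reaches the
minimum bend radius of the path (the offset surface would
self-intersect), and the sweep warns when the bend radius falls below
the lumen radius.

## Smoothing

Smoothing is Catmull-Clark subdivision (the variant used in mesh-based
CAD workflows), applied after thickening: face points, edge points and
vertex points follow the classic masks, with the cubic B-spline curve
rules on boundaries. One iteration (the default; the count is
configurable) rounds the frame edges without visibly shrinking pores.
Subdivision preserves watertightness and Euler characteristic, which the
tests assert, and the classic operation count (a cube subdivides to 26
vertices and 24 quads) pins the implementation. The implementation is
vectorised over half-edges; faces are fixed-arity matrices (triangles
in, quads afterwards).

Pore diagnostics (`pore_size_profile()`) are taken on the pored or
thickened mesh, where pore metadata still references mesh vertices; the
effective diameter is the largest inscribed circle of the rectangular
opening, i.e. the smaller of the two extents. On curved paths this
reproduces the characteristic constriction of pores on the inside of
bends and widening on the outside.

## Supports

**Polygonal rings** (planar designs): at each anchor a collar
(watertight annular cylinder, inner radius = capillary outer radius +
clearance) wraps the tube; a polygon of struts in the cross-section
plane surrounds it, with diagonals to the collar and slanted legs from
the below-axis vertices to the base plane. The polygon radius is the
collar outer radius plus two beam diameters so legs clear the capillary
underside. Anchors are either equidistant or placed at predicted
field-of-view (FOV) stitching seams: the printer tiles its FOV, and the
seam lines form two line families at the stitch angle with period
`fov_width - overlap` (defaults 15 degrees and 5 um overlap; the FOV
width itself is objective-dependent, defaulting to 400 um as an explicit
assumption). Seam crossings are found by intersecting the projected path
with both families; the prediction is invariant under one-period origin
shifts.

**Truncated-octahedron lattice** (full 3D designs): the truncated
octahedron is the space-filling cell with 36 edges used for its high
porosity and connectivity; cells tile on a body-centred-cubic
arrangement (vertices are the permutations of $(0, \pm a/4, \pm a/2)$
for cell size $a$). Shared edges are deduplicated and edges are clipped
to the bounding box. The cell size is a required design input — there is
no universal value; it trades support density against open volume.
Struts are culled against the capillary solid by *sampled* distances
along the whole segment (step = half the strut radius), not endpoint
tests, which would miss grazing struts; a strut is removed when any
sample comes within `radius + clearance` (default clearance 2 um, half
the smallest printed beam radius) of the surface or falls inside the
solid. The point-to-mesh query is grid-accelerated compiled code; the
tests verify it against a pure-R point-triangle-distance oracle.
Surviving floating islands (e.g. a short strut trapped in the lumen,
which distance tests alone cannot see) are caught by the endpoint
connectivity graph (merge tolerance 0.1 um) and dropped. Struts become
capsules — cylinders with hemispherical caps — at 24 circumferential
segments by default, keeping the meshed volume within about 1% of the
analytic capsule volume (the pipeline uses 12 segments for fabrication
output, where file size matters more than quadrature).

**Cone supports** (soft materials): frusta rising from the base to the
capillary underside, with wall taper at least 15 degrees from vertical —
shallower cones shadow the laser path and fail to print, so the
constructor rejects them. Because the planar facets of a triangulated
frustum sit slightly steeper than the analytic wall, the builder boosts
the build angle until the realised minimum facet taper meets the
specification (measured as the angle between each facet plane and the
vertical). The capillary envelope (outer surface plus clearance) is
subtracted by projecting any intruding vertex down onto the envelope
underside — a deformation that preserves the mesh's watertight
connectivity, conforms the cone top to the membrane with zero gap, and
guarantees no cone material enters the perfusable volume. Anchors not
under the capillary are flagged in the contact report.

## Chip assembly and export

The base is a watertight slab under the scaffold's convex-hull footprint
plus a margin, top face at z = 0 (the scaffold datum). Nozzle ports are
vertical annular cylinders whose bore continues the lumen and whose
outer diameter (508 um = 0.020 inch) mates heat-shrink tubing, each with
a retaining wall that keeps sealing resin out of the scaffold. Assembly
concatenates closed components rather than computing exact booleans:
fabrication slicers handle overlapping closed shells natively, every
component remains individually watertight, and volume/void queries treat
the assembly as the CSG union of components (the voxel-oracle tests work
this way). Decimation is iterative shortest-edge collapse with the link
condition (manifoldness) and a normal-flip guard, collapsing to
midpoints; boundary edges are never collapsed. The default target
removes 95% of faces — the mesh-budget reduction applied before slicing
— and the implementation reports the achieved fraction and a sampled
Hausdorff distance. STL is binary, deterministic (fixed header, no
timestamps), and round-trips exactly at float32 precision; since binary
STL has no units field, an optional JSON sidecar records the micrometre
convention.

## QC computations

**Registration.** The design render (orthographic top-down silhouette of
the mesh, rasterised at pixel centres; support-tagged faces excludable,
mirroring the digital subtraction of cone supports) goes to the green
channel and the binarised print image to the red channel: yellow =
correct overlap, green = missing material, red = excess material, black
= correct void. The four fractions sum to 1 over the frame. Because the
normalisation of a single "overlap" number is a genuine choice, all
three are reported — relative to the union of structures
(`overlap_percent`, the headline number, which excludes void pixels),
relative to the target area, and relative to the frame. Alignment is the
caller's responsibility (prints are cropped on reference features); an
optional exhaustive integer-shift refinement is provided but off by
default. Contrast enhancement before thresholding is a linear gain about
mid-gray (a "30%" enhancement multiplies contrast by 1.3), followed by
Otsu's threshold.

**Bead velocimetry.** Detection is per-frame thresholding at a fraction
of the frame maximum followed by connected components and
intensity-weighted centroids; linking is nearest-neighbour within a
maximum-displacement gate, closest pairs first. Per-track speed is the
mean per-frame displacement magnitude times `pixel_size /
frame_interval`; the estimate over tracks is mean ± sample SD in mm/s.
The time base is treated as the frame interval (for a camera exposing
back-to-back, exposure time and frame interval coincide; the package
names the parameter `frame_interval` to remove the ambiguity). A manual
mode accepts per-frame click positions, the scripted equivalent of
GUI-based trajectory extraction.

**Live/dead counting.** Each channel is Otsu-binarised and segmented;
components below 20 px (the default, suited to 4x images) are noise.
Red components mark dead cells; a green component overlapping a red one
counts as dead only, since the dead stain marks nuclei of dying cells
that may retain green signal — the paper-silent tie-break is resolved
conservatively toward dead. Components much larger than the median area
count as multiple cells (area / median, for blobs above 1.5x the
median), which tracks a watershed segmentation within a few percent on
moderately touching fields. Manual corrections replay a deterministic
edit list (add live, add dead, remove nearest within 5 px) and keep an
audit log.

## Synthetic fixtures: what they show and what they do not

All three QC paths are exercised end-to-end on generated data with known
ground truth: mask pairs constructed by eroding/shifting a scaffold-like
pattern (known pixel fractions), bead movies rendered with a Gaussian
PSF at subpixel positions (known speeds; defaults emulate bright 1 um
fluorescent beads: PSF sigma 1.5 px, amplitude 0.85, Gaussian noise SD
0.002, 15 frames at 1 um/px and 0.5 ms — at these settings per-frame
displacements span 0.05-4.7 px across the cerebral microvascular band of
0.1-9.4 mm/s, and recovery has mean absolute relative error well under
3%), and live/dead disk images with rejection-sampled non-touching
centres (exact counts recoverable). These fixtures validate the
*computations*, not the imaging: real SEM masks carry segmentation
ambiguity, real bead videos carry motion blur, focus drift and clogging,
and real viability images carry debris and uneven illumination — none of
which the generators emulate. Passing tests therefore demonstrate
correctness of the analysis pipeline, not robustness to acquisition
artefacts.

## Problem sizes and reproducibility

The reference design used by the acceptance script is the layered
Hilbert chip — two stacked second-order Hilbert curves at 150 um step
and 120 um layer gap (about 4.4 mm of path), 40 um lumen, 5 um pores at
8 um spacing, 10 um wall, 100 um lattice cells with 10 um beams — sized
so the full pipeline (3069 pores, ~1M assembled faces before
decimation) completes in about two minutes on one core; larger chips
scale linearly in pore count. The whole pipeline is deterministic under
a fixed seed: geometry generation uses no randomness, manifests record
MD5 checksums, and repeated runs produce byte-identical STL files.

## Known limitations

* Boolean operations are representational (component union), not exact
  CSG; intersecting components are not re-meshed.
* Closed-loop capillaries get seam-matched sweeps, but the
  rotation-minimizing frame holonomy around a loop is not corrected, so
  the pore grid of a closed path can be rotated at the seam.
* Membrane deformation of soft materials (swelling, drying collapse) is
  observed experimentally but not modelled; supports address it
  structurally.
* The design-mask renderer is binary and orthographic; it does not model
  SEM perspective or charging artefacts.
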