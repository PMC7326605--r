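---
title: "Label-driven mesh manipulation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-driven mesh manipulation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshops)
```

`meshops` manipulates labeled tetrahedral/triangle meshes the way
image-based anatomical modeling pipelines need: every operation is
expressible in terms of per-element region tags and geometric features, so
a whole model-building chain can run unattended.  This vignette explains
the underlying procedures, the tunable parameters and the design decisions
taken where the design was genuinely open.

## The data model

A `mesh` is a point matrix, a mixed tet/triangle connectivity, an integer
tag per element and an optional per-element fiber vector.  Internally all
indices are **1-based** — the natural convention for R containers — and the
readers/writers translate to the 0-based on-disk dialects at the boundary.
Tetrahedra are always stored with positive signed volume; readers and
constructors reorient violators and report the count, which turns inverted
element detection everywhere else into a sign test.  Fibers are opaque
payload: splits copy the parent's vector, collapses keep the surviving
element's, no fiber arithmetic is attempted.

Coordinates carry the units of the source data (often micrometres in
image-derived meshes); the package treats units as opaque and never
rescales.

## Manifold decomposition

Smoothing a multi-region volumetric mesh must not let region interfaces
bleed: a vertex may only be averaged with neighbours of its own manifold.
Vertices are classified as

* **VOLUME** — all incident faces interior to one tag region; averages over
  all edge neighbours;
* **SURFACE** — on the outer boundary or on a two-region interface.  Each
  interface patch is identified by its unordered tag pair; the outer
  boundary uses a reserved pseudo-tag.  Averages stay within the patch;
* **LINE** — on edges where patches meet, or on surface edges whose
  adjacent face normals deviate by more than the *feature angle*; averages
  stay on the line;
* **POINT** — where three or more line branches meet (or a line ends);
  pinned.

The default feature angle is **40°**: right-angle creases of segmented
geometry (90°) are detected with a wide margin, while smooth curved
boundaries at the refinements used here produce per-edge normal deviations
far below it and develop no spurious lines.  Lowering the angle only ever
adds line vertices (a property the tests assert).  For a *noisy* closed
surface the caller should disable feature detection (angle 180°): with
vertex noise comparable to the edge length, dihedral deviations of tens of
degrees are noise, not features, and a 40° threshold would freeze most of
the mesh.

## Shrinkage-free smoothing

One smoothing iteration applies two synchronous (Jacobi-style) passes over
the manifold-restricted neighbour averages: a forward step `λ` towards the
average and a backward step `μ < −λ` away from it.  In the eigenbasis of
the averaging operator the pair has per-iteration gain
`f(k) = (1 − λk)(1 − μk)` on frequency `k ∈ [0, 2]`: a low-pass filter
whose pass band ends where `f(k) = 1`, i.e. at `k_pb = 1/λ + 1/μ`.
Synchronous updates make results independent of vertex ordering, hence
deterministic and testable.

Defaults are `λ = 0.5`, `μ = −0.505`, a pass band of about 0.02.  The
classical wider setting (`μ` chosen for `k_pb ≈ 0.1`) has `f > 1` just
below the pass band; a discrete closed surface's own coordinate modes can
sit exactly there, and over hundreds of iterations the compounded gain
inflates the geometry measurably (we measured ≈ 5% volume growth on a
clean 2562-vertex icosphere after 200 iterations).  With the narrow band
the maximal gain is ≈ 1.000025 per iteration — volume stays put to a
fraction of a percent — while the attenuation at high frequencies
(`f(1) ≈ 0.75`, `f(2) = 0`) still removes noise quickly.  `μ = 0` gives
plain Laplacian smoothing, retained as the shrinkage control.

With a **quality threshold** set (tetrahedral meshes only, metric
volume-edge ratio or minimal dihedral sine), each pass is followed by a
revert loop: any tetrahedron whose quality would fall below the threshold
while currently above it, or decrease further while already below it, has
all its vertices reset to their pass-start positions; the check is repeated
until stable.  The reverted set only grows, so the loop terminates, and by
induction the minimum quality after smoothing is never below
`min(threshold, initial minimum)` — the threshold is never crossed
downwards.  Reverting (rather than clamping the step) was chosen because
it composes with the synchronous update without order dependence; the
granularity is per-vertex, so one bad neighbourhood degrades gracefully
instead of aborting the pass.

Node data fields (scalar or 3-vector) are smoothed with the same λ/μ
scheme over plain edge adjacency, componentwise.  Element data smoothing is
out of scope.

## Quality metrics

Volume-edge ratio `q = 6√2·|V| / l_rms³` (`l_rms` the root mean square of
the six edge lengths) and minimal dihedral sine
`min_e sin θ_e / sin 70.5288°`, computed via the identity
`sin θ_e = 3 V l_e / (2 A₁ A₂)`.  Both are scale-invariant, 1 exactly for
the regular tetrahedron and 0 for degenerate elements; values are clipped
to `[0, 1]` against round-off.

## Re-sampling

Resolution change runs in two strict phases (split, then collapse) —
interleaving is not attempted, keeping each phase's invariant simple.

**Split.**  Edges longer than `max_edge` are bisected at their midpoints,
longest first (ties broken by vertex index, so the order is
deterministic); every incident element is subdivided (tet → 2 tets,
triangle → 2 triangles), which maintains conformity even across a
tag-restriction boundary.  Children inherit tag and fiber; node data
fields are midpoint-interpolated.  Each split halves an edge, so the phase
terminates with no eligible edge above the cap, volume conserved to
round-off and orientation preserved by construction.

**Collapse.**  Edges shorter than `min_edge` are processed shortest first.
The collapse direction follows the manifold classes: the lower class moves
into the higher one (volume → surface → line → point), equal classes on
the same patch meet at the midpoint, two corner points never collapse.  An
attempt is dismissed when any surviving tetrahedron would have
non-positive volume or quality below `quality_floor` (default **0.05** —
low enough to permit aggressive coarsening, high enough to reject slivers
visibly), when any boundary/interface face normal would rotate by more
than `normal_change_max_deg` (default **25°**, the shape-preservation
control), when the merge would create an edge above `max_edge`, or when
the edge crosses the tag-restriction boundary.  Short edges that survive
all rounds are *reported* — near constrained corners and interfaces the
minimum length is genuinely not enforceable — never an error.

A user-supplied *average* target `a` maps to `min = 0.7a`, `max = 1.4a`:
the bracket is wide enough that a structured mesh engages both phases and
narrow enough that the resulting mean lands near `a` (the tests assert
within 20% per region on a three-region box).

Tag restriction is conservative for collapses (every element incident to
either endpoint must lie in the restriction) and permissive for splits
(an edge on the restriction boundary may split; out-of-restriction
incident elements are subdivided to stay conforming).  Elements entirely
outside the restriction and away from its boundary are bit-identical in
the output.

## Surfaces, traversal, submeshes, merging

Canonical face identity is the sorted vertex triple; boundary extraction
keeps faces of multiplicity one among the selected tetrahedra, oriented
outward from the selection, so enclosed volumes are positive and interface
normals well defined.  Set operations work on face keys, take orientation
from their first operand and sort output deterministically.

Seeded traversal snaps each seed coordinate to the nearest surface vertex
(warning beyond a snap radius, default 5% of the bounding-box diagonal —
never silently), measures geodesic distance *along edges* (metric, not hop
count), and blocks edges whose adjacent face normals deviate beyond the
critical angle.  Faces are kept when **all three** vertices are reached —
the conservative reading — and face-to-face growth only crosses passable
edges, so a blocked crease genuinely stops the region even though its
vertices are shared.  Reach is monotone in both the distance limit and the
block angle.

Overlap extraction selects elements of one mesh whose centroid lies within
a given distance of any vertex of another, via a uniform-grid spatial
hash; the complement is returned alongside and the two sides partition the
input exactly.  Merging unifies vertices within a tolerance (default
`1e-6 ×` the combined bounding-box diagonal — scale-free; nearest wins,
ties to the lowest index) and fails loudly if unification would degenerate
an element.

## What the synthetic fixtures do and do not show

The generators emulate the *structure* of image-derived inputs: multi-label
boxes (axis-aligned label slabs), a two-label shell with cavity standing in
for ventricular tissue around a blood pool, a closed rod surface standing
in for a CAD device, an icosphere as the canonical smooth closed surface,
and seeded Gaussian jitter for rough pre-smoothing interfaces.  They are
deterministic given a seed, and small: the test suite works at thousands
to tens of thousands of elements (e.g. a 17³-cube box, ≈ 29k tets, for the
quality-guard check; a level-4 icosphere, 2562 vertices, for the
shrinkage check; an 8×8×9 three-region box for re-sampling), which keeps
the whole suite under a minute.  What passing tests show is that the
*contracts* hold — partition laws, conformity, orientation, threshold
guards, metric targets; what they cannot show is behaviour on anatomical
geometry: highly anisotropic elements, topologically complex interfaces,
segmentation noise far from Gaussian, and meshes several orders of
magnitude larger with the attendant performance questions.

## Known limitations

* Volumetric re-meshing from surfaces (the classical Tetgen-backed step)
  is out of scope; pipelines substitute a pre-generated labeled volume.
* Only tetrahedra and triangles are representable; readers reject other
  element types with a clear message.
* Quality tracking during smoothing covers tetrahedral meshes only.
* Edge flips/face swaps and Delaunay-style improvement are not part of
  re-sampling; binary and XML VTK dialects are not read or written.
* The `.surf/.vtx` grammar implemented here is a committed decision
  (header + `Tr` rows; `.vtx` with a count line and an `intra` keyword);
  anyone interoperating with other tools should verify their dialect.
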