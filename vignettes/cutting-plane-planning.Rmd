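---
title: "Planning bone-tumor resections with extruded cutting surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning bone-tumor resections with extruded cutting surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The planning problem

Patient-specific cutting guides let a surgeon execute a pre-planned set of
saw cuts to remove a bone tumor. Because the operation is performed through
a single incision, all cutting planes are parallel to one surgical-access
direction. After canonicalization (tumor volume centroid at the origin,
access direction mapped to +z), a plan is fully described by an open
polygonal chain of $n+1$ points in the $xy$ plane: its vertical extrusion
is the cutting surface, each of the $n$ extruded segments is one planar
saw cut, and the solid on the tumor side of the surface is the resected
part. The planner must remove the tumor *completely* -- including a safety
margin that absorbs execution error -- while sacrificing as little healthy
bone as possible.

`osteoplan` searches over the $2(n+1)$ point coordinates with a global-best
particle swarm, minimizing

$$ f \;=\; \frac{vol_{B\,cut}}{vol_{B\,tot}} \;+\; K\,\frac{vol_{T\,left}}{vol_{T\,tot}}, $$

where $vol_{B\,cut}$ is the resected healthy-bone volume, $vol_{T\,left}$
the unresected volume of the margin-expanded tumor, and both are
normalized by the corresponding totals. Invalid configurations receive a
flat penalty value instead of $f$.

### Parameters that matter

* **n (plane count)** -- chosen by the surgeon from tumor shape and access;
  more planes follow the tumor more closely but saw width limits small cuts.
* **margin (mm)** -- tumor offset distance; default 0 for the analytic
  phantom, 2 mm for the curved phantoms, matching typical clinical margins
  of a few millimetres.
* **K** -- tumor-term weight, default 100. It must make any appreciable
  tumor residue dominate every achievable bone saving ($f \le 1$ for the
  bone term alone), but stay finite: as $K \to \infty$ the feasible
  minimum sits arbitrarily close to penalized points and the swarm cannot
  navigate the cliff. With $K = 100$, leaving 1% of the tumor costs 1.0 --
  the price of resecting the *entire* bone.
* **penalty value** -- default $10 + K$: strictly above the feasible range
  $[0, 1+K]$, small enough not to blow up swarm velocities.
* **swarm** -- reference scale 150 particles x 100 iterations; constant
  coefficient grids hold $\omega = 0.8$, $c_1 + c_2 = 4$; the variable
  schedule interpolates $\omega: 0.9 \to 0.4$, $c_1: 2.5 \to 0.5$,
  $c_2: 0.5 \to 2.5$ linearly over the iterations (endpoints are this
  package's choice; only "exploration to exploitation" is prescribed).

## Geometry implementation

### Splitting a mesh with the extruded chain

All geometry happens in the canonical frame, where the cutting surface is
a vertical extrusion; splitting therefore reduces to classifying mesh
vertices by a scalar field $F(x, y)$ and cutting triangles along
$F = 0$. We define $F$ as the unsigned distance to the chain *extended
collinearly at both ends*, with its sign decided by even-odd ray-crossing
parity relative to the parity of the tumor centroid: negative = tumor
side = resected.

Two design points deserve emphasis:

* **Why parity, not nearest-facet normals.** Signing the distance by the
  nearest facet's normal (the behaviour of implicit-distance clipping in
  common mesh libraries) is discontinuous across ridges equidistant from
  two facets that disagree about "side". During swarm exploration those
  ridges routinely cross the bone, and a marching clip then fabricates
  cut surfaces where no saw cut exists; we observed the optimizer
  *exploiting* the resulting mis-measured volumes (reporting $f$ below
  the provable optimum). The parity sign is globally consistent, makes
  $F$ continuous with zero set exactly on the extended curve, and
  eliminates the exploit class. The facet-normal orientation rules (all
  normals away from the centroid; the reflex-gap cases for an ending or
  intermediate facet) are still computed and exposed -- they are part of
  the surface's contract, drive the exported facet equations, and are
  covered by dedicated tests -- but the split's side decision no longer
  depends on them.
* **Exact volume conservation.** Crossed triangles are subdivided at
  their edge crossings (computed once per mesh edge and shared between
  neighbours), and the cut outline is capped by triangulating each
  boundary loop in the unrolled (arc-length, z) plane of the extrusion.
  Cap triangles are refined along the dihedral crease lines (exact in
  unrolled coordinates) so caps follow the actual surface, and both the
  resected part and the remainder share the same cap triangles with
  opposite orientation. Resected + remainder therefore tile the input
  exactly and conservation holds to floating-point precision, not merely
  to a tolerance.

Degenerate cut loops (the cut grazing mesh lattice planes) are handled by
retiring zero-area polygon corners during ear clipping; a fan fallback
guarantees closure for numerically hostile loops. A 1-Lipschitz check on
edge crossings ($|F_i| + |F_j|$ cannot exceed the edge's $xy$ length for a
genuine crossing) is kept as a safety invariant and signals a penalized
null split if it ever fires.

### Ordering the path points

Raw swarm coordinates are unordered; every evaluation re-sorts them by
polar angle about the tumor centroid. The circular order must be cut open
somewhere to form an open chain, and the cut is placed in the *largest
angular gap*. A fixed `atan2` branch cut would scramble every chain whose
angular span crosses 180 degrees -- including the convex-hull warm start
whenever the tumor protrudes toward $-x$ -- whereas the largest-gap rule
is rotation-equivariant and puts the chain's open side in the sector where
nothing is being cut. A consequence is that a reflex gap larger than $\pi$
can no longer arise *inside* a re-sorted chain (it would have been chosen
as the opening); the reflex orientation cases remain reachable through
direct surface construction and are tested that way.

### Validity and penalties

Before any split, a configuration is checked for the two invalid classes,
each mapping to the flat penalty with a reason code:

* **facet-miss** -- every plane must actually cut the bone. Each facet's
  infinite vertical plane is intersected with the bone; the section
  contour is projected on the facet's own segment axis and the facet
  misses when the contour range is disjoint from the facet's range (or
  there is no contour at all). Note a path enclosing the whole bone
  footprint is *invalid* under this rule even though the split itself
  would happily return the entire bone.
* **self-intersection-hit** -- chain self-intersections are acceptable
  unless the vertical line through a crossing point pierces the bone or
  the expanded tumor, in which case the split is geometrically
  meaningless. The full line (both z directions) is tested, since the
  extrusion spans the z-extent. All crossings are tested, and touching
  contacts count as crossings (conservative toward penalization).

Null or folded splits (empty resected part, non-positive signed volume)
are reported as `null-split`; collinear-overlap chains as
`degenerate-chain`; duplicate consecutive points merely collapse to
coincident redundant planes and are allowed.

### Margin expansion

The safety margin is applied by offsetting each tumor vertex by the
least-squares solution of its adjacent-face constraints
$\langle d, \hat n_f \rangle = m$ -- a plain normal offset on smooth
regions and the sharp plane-offset corner on creases (capped at $3m$).
The contract is the distance postcondition (every input surface point at
least $m - \varepsilon$ inside the output), not the particular offset
construction; an exact Euclidean offset would satisfy it equally.

## The convex-hull warm start

The 2D convex hull of the expanded tumor's $xy$ projection is polar-ordered
about the centroid; hull points whose vertical line meets the bone are
"true". The single contiguous true run plus its two flanking false points
forms an open polyline (only these points generate facets that cut bone),
which Ramer-Douglas-Peucker simplification reduces to exactly $n+1$ points:
the smallest tolerance whose RDP output has at most $n+1$ points is found
by bisection at $10^{-4}$ mm resolution, and midpoint densification pads
any undershoot. Finally the points are pushed radially outward on a
0.1 mm grid (up to 10 mm) until the path clears the expanded tumor
completely without penalty. The hull is taken on the *expanded* tumor
because the final path must clear the margin (the raw tumor is
selectable). Multiple true runs, all-true or all-false masks are reported
infeasible rather than guessed, and the planner then falls back to a
plain random-initialization run.

The warm start replaces one of the swarm's random particles. Since a
personal best is never discarded, a warm-started run can never end worse
than the warm start itself.

## Synthetic phantoms: the stated world

No clinical meshes are distributable, so the package generates phantoms
emulating epiphyseal long-bone tumors whose footprint protrudes beyond the
bone (guaranteeing the warm start applies):

* **corner_column** -- 40 mm cubic bone, box tumor overlapping one edge
  column; at $n = 2$, margin 0 the optimal cut removes a
  $10 \times 10 \times 40$ mm column, so $f^* = 4000/64000 = 0.0625$
  analytically. Used for optimum-recovery and complete-removal targets.
* **eccentric_ellipsoid** -- capsule bone (r = 15 mm), ellipsoid tumor
  12 mm off-axis, margin 2 mm, $n = 3$.
* **concave_bean** -- same bone, tumor formed as the radial-max union of
  two offset ellipsoids: a genuinely concave footprint (hull area exceeds
  footprint area), which is the case where multi-plane paths beat a single
  chord.

Default mesh resolution is ~1 mm edge length (volumes accurate to well
under 1%). What the phantoms do *not* emulate: real cortical/trabecular
geometry, segmentation noise, registration error between CT and MRI
frames, and anatomy-driven constraints on the access direction. A green
test therefore establishes the geometry and optimization machinery, not
clinical performance.

## Numerical choices

* Extrusion z-range: the scene's z-extent inflated 5% per side (any value
  strictly covering the meshes is equivalent).
* Degenerate segments (< 1e-6 mm) collapse; polar ties break by radius,
  then x, then y.
* Velocity clamp 20% of the box diagonal per component; boundary handling
  clamps the position and zeroes the offending velocity component.
* Experiment confidence intervals are $1.96\,\mathrm{sd}/\sqrt{repeats}$
  (the reference reports "CI" without a definition).
* One RNG stream per run, seeded from the config; identical seeds give
  bit-identical runs.
* STL is written in float32; reading welds vertices exactly and drops
  faces collapsed by quantization, preserving closedness.

## Test-scale reductions

The acceptance suite runs the full pipeline but at reduced scale, chosen
for time budget, not for outcome: 2-3 mm phantom meshes where the default
is 1 mm, and swarms of 30 x 50 (optimum recovery) or 12 x 25 (schedule and
warm-start comparisons) where the clinical reference is 150 x 100. The
schedule comparison uses the eccentric ellipsoid ($n = 3$), where the
advantage of the variable schedule over fully individualistic
($c_1 = 4, c_2 = 0$) and fully social ($c_1 = 0, c_2 = 4$) swarms is
expressed; plane counts of two make the landscape easy enough that even
degenerate schedules often find the minimum.

## Known limitations

* Planes are all parallel to the access direction; tilting them is out of
  scope, as are saw-width minimum-segment constraints and penalties for
  nearly coincident redundant planes.
* The facet-miss rule follows the strict reading (every plane must cut
  bone), which also forbids plans that resect the entire bone.
* Tumor footprints whose bone-overlap splits into multiple runs are
  reported infeasible for the warm start rather than solved.
* The mesh offset can self-intersect for margins comparable to
  concave feature sizes; the expansion errors out (volume check) rather
  than repairing such cases.
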