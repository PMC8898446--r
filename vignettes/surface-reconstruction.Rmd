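---
title: "Minimal-area surface reconstruction from serial contours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal-area surface reconstruction from serial contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicemesh)
```

## The problem

Segmentation of CT or MR volumes — of long bones such as the femur and tibia
in particular — commonly produces closed 2D contours on evenly spaced
parallel slices, with spacings on the order of 1–5 mm. Surgical planning and
navigation need a single watertight triangle mesh instead. `slicemesh`
interpolates an ordered contour stack into such a mesh, keeping the original
contour points (no resampling, no new vertices, with the single exception of
*removing* points during keyhole cleaning).

The pipeline runs per pair of consecutive slices: branching resolution, then
tiling by area minimisation, and finally one global sealing step for the
first and last contours. Keyhole removal is applied once per input contour
before any pair is processed (see *Ordering of the stages* below).

## The tiling model

Let the lower contour have points $L_0,\dots,L_{n-1}$ and the upper
$U_0,\dots,U_{m-1}$, both rings implicitly closed. An elementary **tile** is
a triangle made of one contour segment plus one point of the opposite ring.
A **span** $(i, j)$ is the edge $L_i U_j$; spans are the nodes of a graph in
which a move $(i,j) \to (i{+}1,j)$ lays down the tile
$(L_i, L_{i+1}, U_j)$ and a move $(i,j) \to (i,j{+}1)$ the tile
$(U_{j+1}, U_j, L_i)$. A complete band between the two contours is a
monotone path of exactly $n + m$ moves; because both rings are cyclic the
graph is toroidal, and it is cut open at the **closest span** — the pair of
points at minimal 3D distance between the two rings.

Each move is weighted by its triangle's area,
$\mathrm{Area} = \tfrac12\,\lVert (A - B) \times (C - B) \rVert$,
and the band chosen is the minimum-total-area monotone path from $P(0,0)$ to
$P(n,m)$. Since moves only ever advance $i$ or $j$, a label-correcting
search is unnecessary: the row-by-row dynamic program

$$\mathrm{cost}(i,j) = \min\bigl(\mathrm{cost}(i{-}1,j) + W_\text{lower},\;
\mathrm{cost}(i,j{-}1) + W_\text{upper}\bigr)$$

is exact in $O(nm)$, and keeping only the cheaper path into each shared node
is precisely the pruning the search formulation describes. Ties prefer the
lower-contour advance, for determinism.

**Start-span strategy.** The default is the single sweep from the closest
span. The true optimum over the toroidal graph may start elsewhere, so
`tile_pair(start = "exhaustive")` re-runs the sweep from every upper-ring
offset and keeps the global best; it costs a factor $m$ and is rarely
needed. The default was chosen as the cheaper strategy whose result the
exhaustive mode never improved on our synthetic geometries — the test suite
asserts only that exhaustive is never worse.

## Normalisation

Minimising raw area fails on a classic configuration: two identical circular
cross-sections whose centres are offset by one diameter. The cheapest raw
band degenerates toward a double cone pinched at a line rather than the
obvious skewed cylinder. The fix is to evaluate the *cost* on normalised
copies of the contours: each ring is translated so its vertex-mean centroid
is at $(0,0)$ and scaled by the width and height of its axis-aligned
bounding window, $x' = (x - c_x)/w$, $y' = (y - c_y)/h$, which maps the
window to the unit square. $z$ is untouched, so inter-slice distance still
enters the metric. Geometry is always *emitted* in original coordinates;
normalisation is a cost transform only. It defaults to on.

Two choices here were genuinely open and are this package's:

* the window maps to the **unit square** (rather than, say, unit half-width);
  any fixed target square gives the same optimal path ordering, so only the
  printed cost scale depends on it;
* the "midpoint of the contour" is the **vertex mean**, which is simpler and
  order-robust for the roughly uniformly sampled contours segmentation
  produces; an area centroid would also have been defensible.

With normalisation on, the offset-circles case reproduces, span for span,
the correspondence of perfectly aligned circles — the suite asserts this
identity directly.

## Branching

When one slice cuts a structure into $m$ contours and the next into $n \ne
m$ (both positive), the side with more contours is reduced: the two contours
whose rings come closest are bridged into one composite ring through their
globally nearest point pair $(p, q)$ — traverse ring 1 to $p$, bridge to
$q$, traverse all of ring 2 back to $q$, bridge back to $p$, finish ring 1.
The composite has $n_1 + n_2 + 2$ points; $p$ and $q$ appear twice, and the
two bridge edges are geometrically coincident, traversed in opposite
directions, so the assembled mesh still closes over them. Merging repeats,
closest pair of contours first, until the counts match. All ties break
toward the lowest index pair.

This handles simple bifurcations (a femoral shaft splitting into condyles in
near-axial cuts). It is explicitly **not** a solution for complex branching
— saddle topologies, holes forming between slices, the tangled unconnected
regions coronal cuts can produce — nor for the correspondence problem:
contours are assumed already ordered and grouped, and across equal-count
slices they are matched greedily by centroid proximity.

## Keyholes

A keyhole is a narrow channel in a single contour: non-adjacent ring points
closer than a threshold. Tiling can reach into the channel, so keyholes are
removed first. Every point is compared with every other point of its
contour; a pair is in conflict when its distance is below the threshold and
its ring-index distance exceeds 2 (wrapping). "Index distance > 2" is this
package's reading of "not adjacent": with ≤ 1 the immediate neighbours of
every short edge would conflict on densely sampled contours, and ≤ 2 also
exempts next-nearest neighbours, which are routinely close on fine
segmentations.

Conflicts are resolved lowest-index pair first: the points on the *shorter*
arc (by count) strictly between the pair are deleted — those are the points
"inside" the channel — and the pair is joined directly; the scan then
repeats until clean, which makes the operation idempotent and guarantees the
post-condition (no non-adjacent pair closer than the threshold) by
construction. Under this shorter-arc rule a conflict can only exist for
$n \ge 6$ and removal always leaves at least $\lceil (n+2)/2 \rceil \ge 4$
points, so the "contour too small for this threshold" error is a defensive
guard rather than a reachable state.

The default threshold is **1.5 × the median segment length** of the
contour. No absolute value suits both a 12-point square and a 200-point
femoral outline; a relative default adapts to sampling density, and a
uniformly sampled convex ring can never conflict with it (its closest
non-adjacent pair, three indices apart, is ~3 median edges away). For
engineered geometries with known channel widths — like the `keyhole_c`
fixture, whose 0.2 mm slot is documented to be tested at 0.5 mm — pass an
explicit `keyhole_threshold`.

**Ordering of the stages.** The pipeline scans each *original* contour once,
before branching is resolved, and never re-scans composite rings: their
deliberately coincident bridge vertices (distance 0, non-adjacent) would
otherwise be flagged as a keyhole and the bridge destroyed. Scanning
originals first is substantively equivalent — every input point is checked
against exactly the points of its own contour either way.

## Sealing and mesh assembly

The first and last contours are capped with a planar triangulation that uses
only the contour's own vertices. An unconstrained Delaunay triangulation of
the vertex set would place triangles outside a concave polygon (bone
cross-sections are routinely concave), so the caps are built by **ear
clipping**, which honours the ring edges by construction and yields exactly
$n - 2$ triangles whose areas sum to the polygon's shoelace area. The ear
test uses *closed* triangle containment so that a reflex vertex lying
exactly on a candidate ear's closing edge blocks the ear — the standard
failure case on axis-aligned concave outlines. Caps with interior holes
(annular sections) are out of scope. When a boundary slice has several
contours, each is capped independently.

Orientation: contours are normalised to counter-clockwise (viewed from +z)
on load, tiles are wound so band normals point outward, the bottom cap faces
−z and the top cap +z, and every shared edge is traversed in opposite
directions by its two faces. Assembly welds vertices by **exact** coordinate
equality — contour points are shared by construction and never recomputed,
so epsilon-welding and its pitfalls are unnecessary. For a sealed,
unbranched, single-contour-per-slice stack the result is a closed genus-0
surface: 0 boundary edges, 0 non-manifold edges, $V - E + F = 2$, verified
by `watertight_report()`. Branched stacks carry duplicated bridge vertices
and are exempt from that guarantee by design; the report still runs and
reports honestly.

## Numerical and convention choices

* **Closure**: the first point is not repeated; $n$ points = $n$ segments,
  which keeps tiling index arithmetic free of double counting.
* **Winding**: counter-clockwise from +z, enforced on load. The convention
  is declared, not inherited — serial-section formats are silent on it.
* **Indexing**: all public indices are 1-based, the R convention; the PLY
  writer emits 0-based and the OBJ writer 1-based indices as those formats
  require.
* **Units**: millimetres throughout, matching CT slice spacing.
* **File format**: the JSON contour-stack schema is written with 17
  significant digits, so write→read round-trips are bit-exact.
* **Degenerate tiles** (three collinear points) are legal with cost 0.
* **Ties** (closest span, nearest bridge pair, DP moves, contour matching)
  always resolve to the lowest index, so every run of the pipeline on the
  same input produces bitwise-identical mesh files.

## What the fixtures emulate — and what they do not

`make_fixture()` generates deterministic stacks standing in for segmented
long-bone sections: `cylinder` and `cone` for shaft-like runs of similar
cross-sections, `skewed_cylinder` for lateral drift between slices (the
normalisation stress case, centres one diameter apart at `offset = 2r`),
`y_branch` for a simple bifurcation, `keyhole_c` for a narrow-channel
cross-section, and `random_convex` for irregular but simple rings. Circle
fixtures sample uniform angles starting at angle 0 and index 0, so expected
correspondences are predictable in tests.

Real segmentations differ in ways the fixtures deliberately do not model:
non-uniform point spacing, highly concave and locally noisy outlines, rapid
shape change between slices (where area-minimal bands are known to pinch
triangle fans toward one point of the smaller contour), several interacting
problems — a keyhole at a branch point, say — in the same place, and
annular cross-sections. Passing tests therefore demonstrate correctness of
the optimisation, the preprocessing contracts and the mesh topology, not
reconstruction fidelity on clinical data.

Test problem sizes are the package's own choice: DP-versus-enumeration
checks use rings of 3–7 points (enumeration is $\binom{n+m}{n}$ paths),
watertightness sweeps use 20-point rings over 3 and 10 slices at 1–5 mm
spacing, and closed-form area checks go up to 128-gons. All are exact or
at 1e−9 relative tolerance; nothing is tuned.

## Known limitations

* Complex branching and coronal-cut topologies are out of scope; the
  branch bridge handles one simple merge per slice pair.
* Contour correspondence across slices is assumed given (stack order and
  centroid proximity), never inferred.
* Caps cannot represent interior holes.
* The closest-pair start is a heuristic cut of the toroidal cycle; the
  exhaustive mode bounds, but does not prove, its optimality gap on a given
  input.
* Normalisation uses the axis-aligned bounding window, so it is not
  rotation-invariant; contours rotated between slices are better served by
  the exhaustive start mode.
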