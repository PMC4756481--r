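---
title: "Marker-guided 3-D watershed segmentation: models, parameters and design notes"
author: "markerseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-guided 3-D watershed segmentation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(markerseg)
```

This vignette is the package's own account of the science it implements:
the segmentation model and its assumptions, the parameters that matter,
what the synthetic phantoms do and do not emulate, and the numerical and
design choices made where more than one reasonable option existed.

## The segmentation model

The input is a single-channel 3-D volume in which membranes (animal
tissue) or cell walls (plants) are bright and cell interiors dark. The
core assumption is therefore *intensity-as-altitude*: a seeded watershed
flood, rising through the raw intensity relief from one marker per
segment plus a background marker, stops where floods meet — ideally the
crest of a wall. No gradient-magnitude preprocessing is applied, because
membrane channels are already ridge-like; an optional Gaussian
pre-smoothing (`smooth_sigma`, default 0 voxels) is available for noisy
data.

Segmentation state lives in the *marker graph*, a forest over seed points
maintained as a union-find partition: one disjoint subset per segment.
All corrections are edits of this graph (add a seed, merge two subsets,
delete a subset), and each iteration deterministically re-derives the
label map from the graph. This is what makes sessions replayable: a
recorded list of graph edits (the session-script format of
`parse_session_script()`) reproduces a user's session exactly.

Seeds of one subset must flood as a single marker, or the watershed would
fragment the segment. Multi-seed subsets are therefore connected into
strokes along geodesic paths: the subset's central seed (the member
closest to the subset's mean position, physical coordinates, lexicographic
tie-break) is the source of a Fast Marching solution of
`|grad D| = 1/P`, and a discrete steepest-descent path over the
26-neighbourhood of `D` is traced from every other seed. First-order
upwind Fast Marching is accurate enough here — paths, not sub-voxel
distances, are consumed — and the discrete descent is guaranteed to
terminate (arrival time strictly decreases along every step).

### The geodesic speed map

The arrival-time construction only avoids walls if the speed map makes
them slow. The package uses

```
P(x) = 1 / (1 + beta * I_rel(x)),   I_rel = max(0, (I - I50) / (I99 - I50))
```

on the `[0, 1]`-normalized intensity, with `beta = 20`. Two choices need
justification:

* **Background subtraction (`I50`).** With speed tied to raw intensity,
  a moderately bright interior travels at slowness 3–4 per voxel, so
  hopping straight across a thin wall (one voxel at slowness ~20) can be
  *cheaper* than an honest detour around it — we observed exactly this
  failure on a two-chamber fixture. Subtracting the volume median keeps
  interiors at speed ≈ 1 and preserves the wall-to-interior cost ratio.
* **`beta = 20`.** One wall voxel then costs about 20 interior voxels of
  detour — larger than any within-cell detour at the cell sizes this tool
  targets (radius 5–20 voxels), while still finite so that a genuinely
  enclosed seed (no gap at all) is dropped with a warning rather than
  silently bridged.

A constant-speed mode (`speed_mode = "constant"`) is available; then the
arrival time is simply the Euclidean distance from the central seed.

### Flooding determinism and plateaus

The flood queue is ordered by `(intensity, insertion order)` — FIFO
within a flood level. The alternative, breaking ties by marker id, is
equally deterministic but hands *entire* equal-intensity plateaus (a
noiseless wall, a saturated region) to the lowest id; FIFO splits a
plateau at its geometric middle, which is both fairer and what the
established watershed implementations do. Priority is the neighbour
voxel's own intensity (classical ordered-queue flooding), not the running
maximum along the path, so the two floods climbing a wall from either
side meet at its crest. Markers are dilated by one voxel (6-connected
ball) before flooding so one-voxel strokes are not swallowed; the
dilation writes only into unclaimed voxels, so markers of different
segments never merge.

If no background marker is supplied, voxels of the volume's outer
one-voxel shell at or below the shell's 5th intensity percentile become
the background marker — the standing assumption is that the specimen does
not touch the image border.

## The cellness confidence model

A correct segment is expected to have (1) a boundary brighter than its
interior, (2) bright walls towards each neighbour, (3) a mostly convex
shape, and (4) a shape similar to its neighbours. The sub-scores:

* `s1 = B̄ / (B̄ + S̄)` where `B̄`, `S̄` are mean boundary / interior
  intensity. The raw ratio `B̄/S̄` is unbounded; this map is monotone in
  it, equals 0.5 at parity, and lives in `[0, 1]` as the blending in
  `cellness()` requires.
* `s2`: mean over neighbouring cells of the common-wall mean intensity,
  normalized by the volume's 99th-percentile intensity (robust to hot
  pixels) and clipped to 1.
* `s3`: convexity (segment volume over convex-hull volume).
* `s4 = 1 − mean_j c · ||f_k − f_j||` over neighbours `j`, with `f` the
  z-scored (volume, sphericity, flatness, elongation) vector and
  `c = 1/max` pairwise distance in the volume. Segments without cell
  neighbours get the uninformative 0.5 for `s2` and `s4`.
* `s5`: credit dissemination. Path probability is the product of pairwise
  similarities `d_ij = 1 − c·||f_i − f_j||` (clipped to `[1e-6, 1]`), so
  the optimal path from any confirmed segment is a Dijkstra shortest path
  under `w_ij = −log d_ij` and `s5 = exp(−cost)`. Confirmed segments
  score 1; segments unreachable from every confirmed segment — and all
  segments when nothing is confirmed — keep the uninformative 0.5.
  (Note a subtlety: because of that default, confirming a segment can
  *lower* a previously unreachable segment below 0.5 if its best path
  product is small; on connected adjacency graphs, the usual case for
  compact tissue, adding sources is exactly monotone.)
* `s6`: semi-supervised classification in `(s1..s4)` space by graph label
  propagation — Gaussian kernel on a k-nearest-neighbour graph (k = 7,
  sigma = median pairwise distance), labelled segments clamped, harmonic
  solution for the rest. Chosen because it behaves well with the
  2–20 labels a user realistically provides; any probabilistic
  semi-supervised classifier could stand in its place.

The blend weight `nu = balance * n/(n + 20)` (balance =
`2·min(n_pos,n_neg)/n`) is this package's own formula, constructed to
satisfy the qualitative requirements — zero without both classes, growing
with the number of labels, maximal when balanced — with half-saturation
at 20 labels, the scale at which the classifier's decision boundary
becomes trustworthy in our phantom experiments. It is exposed as a
parameter (`half_saturation`).

Merge recommendations score every neighbouring pair by
`mean(B_kj) · |B_kj|/|B_k|` on the normalized volume and report each
unordered pair once with the smaller directional score, ascending: a dim
or tiny shared wall ranks early. Note the score *by design* also ranks
tiny-but-bright contact faces low — they too are plausible
over-segmentations. Validation of "the injected dim wall ranks first"
therefore uses brick-tissue phantoms, where every true wall is a
substantial cell face and the only low-score pair is the planted one;
on Voronoi tissues, sliver contacts at cell corners legitimately compete.

## Features: numerical choices

* **Boundary** `B_k` is the *inner* boundary (segment voxels with a face
  neighbour outside), so boundary intensities stay within the segment's
  own wall signal; image-border faces count as boundary.
* **Surface area** is estimated as exposed-voxel-face area times 0.678, a
  correction toward the true area of smooth surfaces (face counting
  overestimates a sphere's area by ~3/2). The correction is calibrated
  for curved surfaces; for a perfect cube it overcorrects, so sphericity
  (and the other `(0, 1]` ratios) are clipped at 1.
* **PCA eigenvalues** come from the covariance of physically-scaled voxel
  coordinates. Bounding box and enclosing cylinders are PCA-aligned, with
  extents widened by the voxel footprint projected onto each axis (a
  20×10×5-voxel cuboid then scores squareness exactly 1).
  `cylindricity_mode` defaults to `"lowest"` (the worst-fitting of the
  three principal-axis cylinders), with `"highest"` available — the
  definition is ambiguous between the two readings and the default is the
  literal one.
* **Convex hull** volume uses the hull of boundary-voxel centres
  (incremental 3-D hull in C++); convexity is clipped at 1. Degenerate
  (coplanar) segments get hull volume 0 and convexity 1, and report
  `Inf` sentinels for elongation/flatness when eigenvalues vanish.
* **Histograms** (intensity and border-distance) use 32 bins; the 1-D
  Earth Mover's Distance is the L1 distance of the cumulative histograms
  times the bin width, in intensity units.
* **AP axis**: cubic spline through the user's anterior-to-posterior
  marker points, arc-length resampled at ~1-voxel steps; position along
  the axis is the arc-length fraction of the nearest axis point, the
  angle is against the segment's robust best-fit line (IRLS with Tukey
  bisquare weights, 10 iterations). AP features are `NA` — absent, never
  zero — when no axis is supplied.

F-measure evaluation matches each truth cell to the candidate label of
maximal overlap (not a global assignment); at the cell densities of the
phantoms, greedy matching and optimal assignment coincide, and the scores
are invariant to candidate relabelling.

## The phantom generator

`generate_phantom()` emulates the *structure* the algorithms consume: an
ellipsoidal specimen (major axis along x, giving a natural AP axis)
tiled by a Poisson-disk Voronoi tessellation; walls on Voronoi faces and
on the specimen surface; additive Gaussian noise; optional wall dropout
in random patches (weak staining); drift, cell division, corrupted seed
sets (missed + spurious nuclei), and corrupted label maps (merges +
splits). The reference conditions, used by the whole test suite, are a
64^3 grid, 30 cells, membrane level 0.8, interior 0.2, background 0.05,
noise sd 0.05, wall thickness 2 voxels, seed 0.

Two generator choices deserve a note:

* **Wall profile.** Walls carry a Gaussian cross-section (sigma =
  thickness/2) peaking exactly on the Voronoi face / specimen surface,
  as a stained membrane does under the microscope PSF, rather than a
  flat-topped slab. A flat slab has no intensity crest, so where the
  flood meets within it is a discretization accident; the peaked profile
  makes the watershed's behaviour — floods meeting at the crest — the
  geometrically meaningful one.
* **Surface wall placement.** The specimen's outer wall straddles the
  ellipsoid surface (half inside, half outside the foreground), mirroring
  how an annotator would place the cell boundary mid-wall.

What the phantoms do *not* emulate: optics (PSF anisotropy, light-sheet
stripes, attenuation with depth), intensity inhomogeneity across the
specimen, nuclei channels, touching specimens, or irregular cell shapes
beyond convex Voronoi polyhedra and their brick-tissue variant. Passing
tests on phantoms therefore demonstrates algorithmic correctness — the
watershed, graph, confidence and propagation machinery do what they
claim on membrane-like geometry — not segmentation accuracy on any real
microscope's data.

## Validation experiments and problem sizes

The package's validation (tests and `scripts/acceptance.R`) re-creates
each headline experiment at desk scale; sizes were chosen so the whole
suite runs in about a minute:

* Watershed fidelity: the 64^3/30-cell reference phantom, noisy and
  noiseless, per-cell F against ground truth.
* Credit dissemination: 200 random graphs (≤ 8 nodes) against exhaustive
  simple-path enumeration.
* Geodesic wall avoidance: a two-chamber box with an off-centre gap; the
  undilated stroke must use the gap (the one-voxel marker dilation may
  graze the gap's rim by construction, so the geometric check is on the
  path itself).
* Propagation ordering: a 5-frame series drifting (0, 1, 2) voxels/frame;
  "nuclei detector failure" is 20% dropped plus 20% spurious seeds —
  severities chosen to echo how badly blob detectors degrade on
  late-stage embryos. Compared: per-frame corrupted initialization,
  chain propagation from a corrected first frame, and per-frame
  propagation from a corrected previous frame.
* Iteration improvement: corrupted seeds (10% dropped, 20% spurious),
  corrections derived from ground truth and applied worst-first over
  three iterations.
* Cellness separation: 10% merges + 10% splits (20% of segments
  affected), 5 confirmed + 5 corrected labels, AUC of the cellness
  ranking.
* Recommendation precision: 20 brick-tissue phantoms (48^3, 2×3×3
  bricks), one division-like dim wall (20% of membrane intensity) each.
* Closed forms: digitized ball (r = 10), cuboid (20×10×5), cylinder
  (r = 5, h = 30), point-mass EMD.
* Division statistics: 20 cells dividing into 40, mean-volume ratio.

## Known limitations

* The watershed has no shape prior: a missing wall with no seed evidence
  merges two cells, recoverable only via seeds/corrections.
* Fast Marching is first-order; arrival times carry O(h) error near the
  source. Fine for stroke tracing; not a sub-voxel distance oracle.
* Label propagation (`s6`) assumes the corrupted and correct populations
  are separable in `(s1..s4)`; pathological tissues that violate the
  four expectations will defeat it, which is why `nu` keeps the blend
  conservative at low label counts.
* `batch_propagate` transfers seeds only — no shape prior or lineage
  model crosses frames, and cell division along a propagated chain
  appears as a merged segment until corrected.
* Greedy truth matching can over-credit a candidate that swallows two
  truth cells; at phantom densities this does not occur, but evaluation
  on dense real annotations should use an assignment-based matcher.
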