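---
title: "Measuring tree structure from leaf-off TLS point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tree structure from leaf-off TLS point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopymetrics)
```

## The measurement problem

A leaf-off terrestrial laser scan of an isolated tree is a dense cloud of
surface returns from trunk, branches and twigs, typically subsampled to
about one point per 2 cm.  From that cloud, urban-forestry datasets record
a standard structural profile per tree: its location, diameter at breast
height (DBH), total height, crown base height, directional crown radii,
maximum crown diameter, and crown projection area — plus, when a
quantitative structure model (QSM, the tree as a hierarchy of fitted
cylinders) exists, the woody volume and the cylinder topology graph.
`canopymetrics` implements that measurement chain, and a synthetic-tree
generator that makes every estimator testable by parameter recovery.

## The pipeline and its parameters

All defaults live in one record, `cm_defaults()`, shared by the library
and the CLI.

**Outlier removal.** For each point, the mean Euclidean distance to its
`knn = 20` nearest neighbours is computed on the raw cloud (exact kd-tree
search); points with a mean above `outlier_threshold = 0.30` m are
removed.  One pass only — iterating to a fixpoint would couple the
neighbourhoods to the filtering order and is not what the single-step rule
describes.  On clouds with `n <= k` points, `k` drops to `n - 1`.  Ties at
the k-th neighbour distance are broken arbitrarily; this can only matter
on exactly symmetric artificial inputs.

**Slice circle fits.** Location, DBH and the crown-start scan all reduce
to fitting a circle to a horizontal slice, minimizing the sum of squared
radial residuals.  We use the algebraic Kåsa least-squares solution
followed by Gauss–Newton refinement of the geometric objective: exact on
noise-free circles, a fraction of a millimetre from the global optimum on
noisy trunk slices (verified against a grid+polish minimizer in the test
suite).  Slices are half-open `[lo, hi)` so adjacent slices partition the
cloud.  Structure-level callers require `min_circle_points = 10` per
slice; the geometric primitive itself only needs 3 non-collinear points.

**Heights.** The tree base is the minimum z *after* outlier removal (a
single low stray return would otherwise shift every height-referenced
slice); tree height is max z − min z.  Because both ends are extreme
values, sensor noise inflates height by roughly the expected maximum of
the extreme points' noise (about 3 standard deviations per densely
sampled end); at 5 mm noise this stays within a couple of centimetres.

**Crown start.** From the DBH slice upward, 10 cm slices are fitted in
turn; slices with fewer than 10 usable points are skipped and do not
update the reference radius.  The crown starts at the bottom of the first
slice whose radius is at least `crown_jump = 1.2` times the previous
fitted radius, the reference being initialized to the DBH radius.  The
scan is capped at 60% of tree height: a crownless pole would otherwise be
scanned to its tip only to fail anyway.  "Not found" is reported as a
missing value, never as 0 — 0 would be a statement about geometry, NA is
a statement about knowledge.

**Directional crown radii.** For each azimuth θ (5° steps,
counterclockwise from +x of the project frame), the crown radius is the
longest horizontal distance from the tree location to the crown points
inside the vertical slab of total width `slab_width = 0.10` m centred on
the vertical plane through the location along θ, restricted to the
half-plane with positive projection on θ.  Empty directions give radius
0.  The flat 72-vector uses crown-only points (at or above the detected
crown start; whole cloud as a flagged fallback when no crown start was
found), while the 2 m height-banded variant always uses the whole cloud —
bands below the crown legitimately measure the trunk.  Whether the flat
radii should be crown-only is genuinely open; we chose crown-only because
the quantity is a *crown* radius, and record the choice in the output
(`params$crown_points`).

Because the directional radius is a maximum-distance statistic, it has a
positive bias under sensor noise — the expected maximum of the rim
points' radial noise, ~3σ for the hundreds of rim points a slab
contains.  At σ = 5 mm that is ≈ 1.5 cm regardless of crown size, i.e.
~1.5% on a 1 m crown radius.  The same logic applies to the convex-hull
projection area (hull vertices are extremes).  This is a property of the
definitions, not of the implementation; noise-free recovery is exact to
sampling resolution.

**Maximum crown diameter** is `max over θ of r(θ) + r(θ+180°)`, an exact
function of the 72-vector (asserted as an invariant on every output).

**QSM volume and audit.** Total volume is the closed-form cylinder sum in
litres.  The fit audit computes each point's minimum distance to any
cylinder, treating cylinders as *solids* (points inside count as fitted,
distance 0): the audit exists to find real structure the model missed —
twigs sticking far outside — not points swallowed by a cylinder.  The
threshold for "not fitted" defaults to `0.05` m and is exposed, since any
single value is a convention.

**Topology graph.** One node per cylinder with all its attributes; one
edge per cylinder whose `parentCylID` names an existing cylinder.  Parent
ids that match nothing (conventionally 0, the source tool being
1-indexed) mark roots.  The single `childCyID` field cannot encode
branching and is stored but never used for edges.  Serialization is a
node-link JSON text file — portable and diffable where a binary object
dump is neither — and round-trips all attributes at full precision.

## What the synthetic generator emulates

`generate_tree()` builds, from a seeded spec: a trunk with a linear radius
taper anchored so the radius at 1.3 m is exactly `dbh/2`; a crown
envelope (cylinder, ellipsoid or cone, with independent x/y semi-axes)
sampled on its surface — the shell of outer twigs that defines crown
extent in a leaf-off scan; straight horizontal branches contained inside
the envelope; isotropic Gaussian noise (iid per coordinate); and planted
far outliers.  The topmost 0.5 m is a bare tapering leader (tip radius
1.5 cm) above the crown envelope: in real leaf-off crowns the apex is a
thin twig, so the highest returns are sparse — this controls the
extreme-value inflation of tree height that a flat, densely sampled
"roof" would exaggerate.  The matching cylinder table is the exact
generating geometry (0.5 m trunk segments plus one cylinder per branch),
and the ground-truth record carries every metric in closed form (crown
radii from the envelope ellipse, projection area πab, banded radii from
the envelope profile, volume from the cylinder sum).

Defaults mirror the survey conditions: 2 cm point spacing, 5 mm noise.
All randomness flows from one stream seeded by `spec$seed`, drawing in a
fixed order (trunk phases, crown, branches, occlusion, intensity, noise,
outliers), so output is bit-identical across machines.

What the generator does *not* emulate: occlusion beyond an optional
azimuthal mask, beam divergence and multi-return effects, wind sway,
foliage, bark texture, co-registered multi-scan artefacts, and crowns
that are not single convex envelopes.  Passing recovery tests therefore
demonstrates correctness of the measurement chain on idealized leaf-off
geometry, not robustness to every field condition.

## The benchmark battery and observed recovery

`benchmark_specs()` fixes 25 trees with randomized dimensions (DBH
0.25–0.5 m, height 8–12 m, crown start 2–4 m, crown semi-axis 1–1.8 m,
axis ratio ≤ 1.3) under the survey conditions above; tree dimensions
derive deterministically from the tree index, so the battery is stable.
Crowns are near-circular here on purpose: the slab-maximum radius
definition is itself biased upward on strongly eccentric rims (the slab
picks up the locally widening rim, up to ~3% at mid angles for a 3:1
ellipse), and that definitional bias should not be conflated with
estimator error; the eccentric case is tested separately at its own
tolerance.  `run_recovery_benchmark()` measures each tree and tabulates
errors; the acceptance script reports them.  At these sizes (~150–250
thousand points per tree) the full battery runs in under a minute on one
CPU.  Typical results: mean absolute DBH error below 1 mm, mean height
error below 1 cm, crown start within one slice of truth, mean directional
radius error ≈ 1.5% (worst single direction ≈ 2.5–3%, the max-statistic
bias discussed above).

## Numerical conventions and degenerate inputs

* Collinearity (circle fit, hull) is tested by the second singular value
  of the centred coordinates against a 1e-9 relative tolerance.
* The Gauss–Newton refinement accepts only objective-decreasing steps and
  stops on relative improvement below 1e-15; on noise-free data the Kåsa
  start is already optimal.
* Cylinder axes are renormalized on input; deviations from unit norm
  beyond 1e-2 additionally warn and flag the row.
* Transform files must carry exactly 16 numbers with last row
  `(0, 0, 0, 1)` (1e-9 tolerance) and a non-singular 3×3 block; the
  inverse map is provided for round-trip work even though the survey
  direction is project→global only.
* Empty slices, empty directions and missing crown starts are legal
  states with defined answers (empty cloud, radius 0, NA); failed scalar
  stages in `measure_tree()` become NA fields plus a machine-readable log
  entry, and only an empty input cloud aborts.
* A crownless pole is expressible in the generator as
  `crown_shape = "none"`, used by the degenerate-case tests and fixtures.

## Known limitations

The crown-start rule assumes the crown widens abruptly relative to the
trunk; gradually flaring crowns (ellipsoid bottoms) trigger one or two
slices above the geometric envelope base.  The DBH fit assumes a roughly
circular stem at breast height — buttressed or strongly elliptical stems
violate it.  The banded radii measure whatever occupies a band, trunk
included, by design.  Volume is only as good as the upstream QSM; the
audit flags missing structure but cannot detect over-wide cylinders.
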