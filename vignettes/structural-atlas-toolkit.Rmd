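---
title: "Structural atlases of cortical folds: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural atlases of cortical folds: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structatlas)
```

## The structural approach

Two traditions exist for putting many subjects' brains into
correspondence. The *iconic* approach warps every image onto a common
template, so that a voxel address means the same thing in everyone; its
price is that each individual's folding geometry is deformed. The
*structural* approach keeps every subject in its own native coordinate
system and establishes correspondence through *named structures*: each
cortical fold is segmented as a discrete object, embedded in a graph, and
annotated with a sulcus name drawn from a shared nomenclature. "The left
central sulcus" then means the set of nodes carrying that label in each
subject — no warping involved. A *structural atlas* in this sense is not
an average map but a collection of annotated individual datasets under
one nomenclature.

This package implements the computational layer of that workflow:
data model, editing, measurement, coordinate handling, and cohort-level
queries. It deliberately contains no renderer and no segmentation
pipeline; graphs enter either from files or from the built-in synthetic
generator.

## The data model

An elementary **fold** is represented as the voxel set of its *negative
cast* — the thin sheet of (conceptually cerebrospinal-fluid-filled) space
that moulds the fold, one voxel thick across the sheet, extending from
the brain hull down to the fundus. A `voxel_surface_set` must be
non-empty, in-grid, and one single 26-connected component: a fold is one
connected piece, and 26-connectivity is the most permissive choice for
one-voxel-thick sheets, where face-connectivity (6- or 18-) would
spuriously fragment oblique surfaces.

A subject's **structural graph** holds fold nodes and two kinds of
topographic edge taken from the sulcal-graph tradition: *junction*
(the folds touch) and *proximity* (they lie close without touching).
Nodes carry a label (or the `"unknown"` sentinel — one canonical
spelling, so round-trips are unambiguous) and a map of named scalar
measurements. All voxel representations in one graph share a single
`volume_geometry`: 0-based indices, a 4×4 `voxel_to_world` matrix in the
qform/sform convention of NIfTI-1, world coordinates in mm.

A typical hemisphere yields on the order of 300 such folds, and a sulcus
is generally the union of several of them sharing one label; both facts
shape the scales used throughout the tests.

**Nomenclatures** are trees of named entries with optional 8-bit RGB
colours. Names are unique tree-wide — labels must resolve to exactly one
entry — and colour resolves upward to the nearest coloured ancestor, so a
lobe can colour all its sulci at once while individual entries may
override.

## Coordinate systems without a centre

Every dataset is bound to a named *referential*. Rather than forcing one
privileged space, a `transformation_graph` joins referentials pairwise:

* **affine edges** (4×4 matrices) are traversable in both directions —
  the inverse is taken on the fly;
* **deformation-field edges** are *directed*. A dense non-linear mapping
  need not be invertible at every point, so a field edge is never walked
  backwards; users holding both directions register both files.

`resolve_path()` finds the chain with the fewest edges; among equally
short chains the one whose traversed referential names are
lexicographically smallest is chosen. Fewest-edges-plus-lexicographic is
this package's own rule (nothing in the tradition prescribes trust
weighting), chosen purely so that resolution is deterministic and
testable. `map_point()` applies the chain: affine steps exactly, field
steps by trilinear interpolation of the field at the current position.

Two field conventions circulate in practice. Natively the package stores
*absolute target coordinates* — voxel `(i,j,k)` of the field holds the
target-space mm position that the voxel's own world position maps to —
which avoids any ambiguity about which space a displacement lives in.
Displacement-convention files are converted on load
(`read_deformation_field(..., convention = "displacement")`).

Numerical choices: trilinear interpolation is exact on affine-valued
fields, which gives a sharp correctness oracle (a field synthesized from
a known matrix must reproduce it to rounding); points outside the field
grid raise an `OutOfField` condition rather than extrapolate — silent
extrapolation of a deformation field is never what a user wants.

## Editing: labels and cuts

Annotation uses copy/paste semantics: `copy_label()` lifts a label (with
provenance) off a node, possibly in another subject's graph, and
`paste_label()`/`set_label()` stamps it onto a series of nodes after
validating it against the nomenclature.

`split_node()` repairs the classic segmentation failure where two sulci
merge into one fold. The user supplies one or more cut points; the
procedure, each sub-choice fixed so results are deterministic:

1. each seed snaps to the nearest fold voxel, at most 2 voxels away
   (farther seeds are off-structure errors);
2. consecutive snapped seeds are joined by shortest 26-connected paths
   *inside* the voxel set — the cut spine;
3. the spine is extended from both ends along the fold's dominant
   principal axis until it leaves the set. The extension walks the voxel
   set itself (greedy 26-neighbour steps with strictly increasing
   projection on the axis, staying near the straight line through the
   first seed) rather than marching a straight line: a straight march
   steps off a curved one-voxel-thick sheet after a voxel or two.
   Diagonal steps are thickened with their axis-aligned companions,
   because a 26-path containing diagonal moves does not by itself
   separate a 26-connected sheet — the complement leaks through the
   diagonal gaps;
4. removing the spine must leave exactly two 26-connected components
   (one is an ineffective cut, three or more an ambiguous one);
5. every spine voxel is handed to the nearest component (ties to the
   larger), so the children exactly partition the parent — no voxel is
   lost or duplicated;
6. the parent is deleted; each former edge reattaches to the child
   nearest its other endpoint (minimum voxel-pair distance); a junction
   edge joins the two children, which inherit the parent's label until
   relabelled;
7. parent meshes are dropped — children are voxel-list-only until
   remeshed.

`merge_nodes()` is the inverse gesture (undo): union of the voxel sets,
first node's label, edges re-homed with duplicates collapsed.

## Morphometry

`compute_node_measures()` derives per-fold scalars from the voxel cast:
size (voxel count × voxel volume, mm³), a thin-sheet surface area (count
× mean voxel-face area, mm²), and extent statistics over the principal
axes of the voxel cloud: length along the first axis; a depth profile —
depth extent per one-voxel bin of length — whose maximum and mean give
`max_depth` and `mean_depth`. Using the *second* principal axis as the
depth direction is an explicit approximation: the true depth direction
runs from the brain hull inward, and no hull is available here. Extents
include the projection of one voxel box onto the axis, so a straight run
of L one-millimetre voxels measures L mm (centre-to-centre extents would
systematically lose one voxel). Cortical `thickness` and sulcal
`opening` cannot be derived from the cast alone — they need the original
MRI — so existing values pass through untouched and are otherwise absent.

`aggregate_morphometry()` pools nodes per label (a sulcus being the union
of its folds): summed for size/area/length, size-weighted means for the
depth metrics; `cohort_morphometry()` concatenates subjects into the long
`(subject, label, metric, value)` table that population statistics start
from. Statistical testing itself is out of scope — the CSV goes to
whatever stats tooling the user prefers.

## Fusions

Of the large family of derived "fusion" objects a full visualization
environment offers, the two computational cores implemented here are:

* `sample_volume_on_mesh()` — a scalar volume textured onto mesh
  vertices through the transformation graph, trilinear (or nearest) at
  each vertex, a background value outside the grid, a frame selector for
  4D inputs (no temporal interpolation);
* `mesh_plane_intersection()` — the polyline contour of a mesh on a
  plane, segments chained at 1e-9 mm and loops closed explicitly.
  Vertices exactly on the plane count as positive side, which fixes the
  degenerate touching cases deterministically.

Both come with exactness oracles: trilinear sampling reproduces a linear
ramp to machine precision, and the unit cube sliced at z = 0.5 yields one
closed loop of length 4.

## Cohorts

A `cohort` binds subject graphs to one shared nomenclature, optionally
with per-subject affine transforms into a common display space —
affine-only by design, since the whole point of the structural approach
is to show each brain's own geometry, merely re-oriented, never warped.
`select_by_label()` selects the same named entity across every subject at
once, expanding interior nomenclature entries to their subtrees.
`consistency_report()` is the side-by-side sanity check that atlases
assembled subject-by-subject historically lacked: it counts, per label,
the subjects carrying it, and flags labels absent from more than a
threshold fraction of subjects (default 0.2) as well as labels in use
that the nomenclature does not know. `paginate()` exposes the
deterministic sorted ordering used to browse large cohorts page by page.

## The synthetic generator

Real sulcal graphs come from an MRI segmentation pipeline that is out of
scope here, so the package generates its own: folds are parametric
ribbons — a template curve swept along a depth direction — rasterized
into the grid densely enough (0.35-voxel steps) that the result is
always one 26-connected one-voxel-thick sheet. Per fold site, a
variability configuration is drawn emulating what fold extraction
produces on real data: a single long fold; an interruption into two
pieces, optionally with a parallel overlapping segment; short or long
side branches at shifted positions; a missing part; and, as an
annotation stressor beyond the geometric events, whole-label dropout
(default probability 0). Junction edges are derived where generated
folds touch (26-adjacent voxel sets), proximity edges under 3 mm
separation. Every generated node's true label and every injected event
is recorded in a ground-truth manifest, which is what selection and
consistency checks are tested against.

Default conditions: 300 fold sites per subject (the typical hemisphere
fold count), a 128³ grid at 1 mm, jitter 1 mm; site geometry (fold
lengths ≈ 10–15 mm, depths ≈ 7–12 mm) scales with the site grid so the
packing in the 128³ volume resembles a folded hemisphere's density. One
site is laid per nomenclature leaf, so with zero variability every label
has exactly one node; the many-folds-per-sulcus structure of real data
emerges through interruptions and branches. Each subject's RNG substream
derives from the cohort seed plus the subject index, so a subject is
reproducible independently of generation order and a fixed seed yields
byte-identical serialized cohorts.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: anatomical folding geometry (no gyral
patterns, no hull, no curvature statistics), segmentation noise at the
voxel level, partial-volume effects, and any correlation structure
between neighbouring sulci. It exercises the *machinery* — graph
integrity, editing, measurement, selection — not anatomical realism.

## Scales, budgets and limitations

The shipped test-suite sizes are the package's own choices: 100 random
transformation graphs for the path oracle, 1,000 interior points per
field check, 50 random cuts, 10 hemisphere-scale (300-site) graphs for
the morphometry oracle, a 100-subject × 20-site cohort for the binomial
event-frequency check, 20 seeds for round-trip checks, and one
60-subject hemisphere-scale cohort — the documented size of real
expert-built atlases — run end to end (generation, validation,
selection, consistency report).

Known limitations, beyond those already flagged: depth measures are
principal-axis approximations; `split_node()` assumes sheet-like folds
(a solid 3D blob cannot be severed by a one-voxel spine and correctly
reports an ineffective cut); GIFTI support covers ASCII-encoded
POINTSET/TRIANGLE/scalar arrays only; the legacy binary formats of the
original desktop software are intentionally not read, and no
compatibility with them is claimed.
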