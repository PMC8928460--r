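# structatlas

Toolkit for **structural atlases of cortical folds** — the approach to
inter-subject brain anatomy that keeps every subject in its own native
coordinate system and establishes correspondence through *named
structures* instead of warping everyone onto a template.

Who it is for: neuroanatomists and neuroimaging methodologists who work
with sulcal graphs — annotating them, repairing segmentations, measuring
sulci per subject and per population, and moving coordinates between
template spaces — without a graphical environment (scripts, pipelines,
servers).

## The model

Each subject is a **structural graph** `G = (V, E)`:

* a node `v ∈ V` is one elementary cortical fold, represented by the
  voxel set of its *negative cast* — the one-voxel-thick, 26-connected
  sheet moulding the fold — with optional triangle mesh and a map of
  scalar measurements (size mm³, length mm, depth mm, ...);
* an edge `e ∈ E` is a topographic relation between two folds:
  *junction* (they touch) or *proximity* (they lie close);
* nodes carry labels from a shared hierarchical **nomenclature**
  (tree of names with inheritable display colours). A sulcus is the set
  of nodes carrying its label; a typical hemisphere holds ~300 folds.

Coordinate systems form a decentralized **transformation graph**:
referentials joined by affine matrices (invertible, walked both ways)
and deformation fields (directed; a non-linear map need not be
invertible). Point mapping composes the shortest chain on the fly,
`y = (T_k ∘ … ∘ T_1)(x)`, with trilinear interpolation inside field
steps.

On top of that: structure-level editing (label copy/paste across
subjects, fold splitting along a cut line with graph-topology update),
per-sulcus morphometry tables, volume-on-mesh sampling and mesh–plane
contours (two classic "fusion" computations), cohort-level selection and
annotation-consistency reports, and a seeded generator of sulcal-like
cohorts with ground truth. File formats: a deterministic JSON graph
dialect (`.sgraph.json`), nomenclature JSON, NIfTI-1 volumes and 4D
deformation fields, Wavefront OBJ and GIFTI meshes, plain-text 4×4
affines, cohort manifests, morphometry CSV.

## Worked example

```r
library(structatlas)

cfg <- generator_config(seed = 42, n_subjects = 3, folds_per_subject = 30,
                        volume_shape = c(72L, 72L, 72L))
gen <- generate_cohort(cfg)
co  <- gen$cohort

co$subjects[["sub-001"]]
#> <structural_graph sub-001/left: 43 nodes, 17 edges, referential 'sub-001_native'>

validate_graph(co$subjects[["sub-001"]], cfg$nomenclature)
#> [1] entity  rule    message            # 0 rows: every invariant holds
```

30 nominal fold sites became 43 nodes: interruptions and branches split
some sulci into several folds, exactly as fold extraction does on real
hemispheres. Select one sulcus across all subjects and measure it:

```r
select_by_label(co, "S.Fr.1")
#> $`sub-001`: 1 2      # interrupted: two folds carry the label
#> $`sub-002`: 1
#> $`sub-003`: 1

subset(cohort_morphometry(co), label == "S.Fr.1" & subject == "sub-001")
#>  subject  label       metric      value
#>  sub-001 S.Fr.1         size 144.000000   # mm^3 (1 mm voxels)
#>  sub-001 S.Fr.1 surface_area 144.000000   # mm^2, thin-sheet estimate
#>  sub-001 S.Fr.1       length  19.651838   # mm, both folds pooled
#>  sub-001 S.Fr.1    max_depth   7.465563   # mm, size-weighted
#>  sub-001 S.Fr.1   mean_depth   7.465563
```

Repair a segmentation by splitting a fold at a cut point (children
partition the parent's voxels exactly and a junction edge joins them):

```r
g  <- co$subjects[["sub-001"]]
vr <- g$nodes[["1"]]$voxel_rep
res <- split_node(g, 1, colMeans(voxel_to_world(vr$geometry, vr$voxels)))
res$new_ids
#> [1] 44 45            # 96 voxels -> 60 + 36
```

Check annotation consistency across the cohort:

```r
consistency_report(co)
#> Consistency report: 3 subjects, 30 labels in use
#> Labels missing in > 20% of subjects: none
#> Labels absent from the nomenclature: none
```

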