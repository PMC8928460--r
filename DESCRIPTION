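Package: structatlas
Title: Structural Atlases of Cortical Folds: Graphs, Nomenclatures and
    Transformation Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Headless toolkit for the structural approach to brain atlasing:
    multi-subject graphs of cortical folds (voxel-cast nodes, junction and
    proximity edges), hierarchical structure nomenclatures with colour
    inheritance, a decentralized graph of coordinate systems joined by
    affine transforms and directed deformation fields, structure-level
    editing (label copy/paste, fold splitting along a cut line),
    per-sulcus morphometry tables, volume-on-mesh sampling and mesh-plane
    intersection, plus a seeded generator of sulcal-like cohorts with
    ground truth. Reads and writes JSON graph/nomenclature dialects,
    NIfTI-1 volumes and deformation fields, Wavefront OBJ and GIFTI
    meshes, and plain-text affine transforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
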