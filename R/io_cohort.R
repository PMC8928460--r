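#' Write a cohort to a directory
#'
#' Writes the shared nomenclature, one `.sgraph.json` per subject, the
#' optional native-to-common affines, and a cohort manifest tying them
#' together. Everything is deterministic byte-for-byte.
#'
#' @param cohort a [cohort()].
#' @param dir output directory (created if needed).
#' @return Path of the manifest JSON, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nom_file <- NULL
  if (!is.null(cohort$nomenclature)) {
    nom_file <- "nomenclature.nom.json"
    write_nomenclature(cohort$nomenclature, file.path(dir, nom_file))
  }
  recs <- list()
  for (sid in sort(names(cohort$subjects))) {
    gfile <- sprintf("%s.sgraph.json", sid)
    write_graph(cohort$subjects[[sid]], file.path(dir, gfile))
    rec <- list(subject_id = sid, graph = gfile)
    tc <- cohort$to_common[[sid]]
    if (!is.null(tc)) {
      tfile <- sprintf("%s_to_common.txt", sid)
      write_affine(tc$matrix, file.path(dir, tfile))
      rec$to_common <- tfile
      rec$common_referential <- tc$target
    }
    recs[[length(recs) + 1L]] <- jobj(rec)
  }
  doc <- jobj(list(format = "cohort_manifest.json", version = "1.0",
                   nomenclature = nom_file, subjects = jarr(recs)))
  invisible(write_canonical_json(doc, file.path(dir, "cohort.json")))
}

#' Read a cohort from its manifest
#'
#' @param path manifest JSON written by [write_cohort()]; referenced files
#'   are resolved relative to it.
#' @return A [cohort()].
#' @export
read_cohort <- function(path) {
  doc <- read_json_checked(path, "cohort_manifest.json")
  dir <- dirname(path)
  nom <- NULL
  if (!is.null(doc$nomenclature)) {
    nf <- file.path(dir, doc$nomenclature)
    if (!file.exists(nf))
      sa_abort("sa_missing_file",
               sprintf("manifest references missing nomenclature %s", nf))
    nom <- read_nomenclature(nf)
  }
  graphs <- list(); to_common <- list()
  for (rec in doc$subjects) {
    gf <- file.path(dir, jfield(rec, "graph", path))
    if (!file.exists(gf))
      sa_abort("sa_missing_file",
               sprintf("manifest references missing graph %s", gf))
    g <- read_graph(gf)
    graphs[[length(graphs) + 1L]] <- g
    if (!is.null(rec$to_common)) {
      tf <- file.path(dir, rec$to_common)
      if (!file.exists(tf))
        sa_abort("sa_missing_file",
                 sprintf("manifest references missing transform %s", tf))
      to_common[[g$subject_id]] <- list(
        source = g$referential_id,
        target = if (is.null(rec$common_referential)) "common"
        else as.character(rec$common_referential),
        matrix = read_affine(tf))
    }
  }
  cohort(graphs, nom, if (length(to_common)) to_common else NULL)
}
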