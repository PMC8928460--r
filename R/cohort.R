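#' Multi-subject cohort sharing one nomenclature
#'
#' A cohort binds several subjects' structural graphs to one shared
#' nomenclature — the structural-atlas setting: the same named entities
#' exist across subjects while every graph stays in its own native
#' coordinate system. Optional per-subject affine transforms into a common
#' space support displaying or comparing subjects in one orientation
#' without warping anybody's data.
#'
#' @param subjects list of [structural_graph()] objects; subject ids must
#'   be unique.
#' @param nomenclature the shared [nomenclature()].
#' @param to_common optional named list (by subject id) of
#'   native-to-common affine transforms, each a list with `source`,
#'   `target`, `matrix`; each `source` must equal the subject's
#'   referential.
#' @return An object of class `cohort`; `subjects` is re-keyed by subject
#'   id.
#' @export
cohort <- function(subjects = list(), nomenclature = NULL, to_common = NULL) {
  ids <- vapply(subjects, function(g) g$subject_id, character(1))
  if (anyDuplicated(ids))
    sa_abort("sa_id_collision",
             sprintf("duplicate subject ids: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  names(subjects) <- ids
  if (!is.null(to_common)) {
    for (sid in names(to_common)) {
      g <- subjects[[sid]]
      sa_check(!is.null(g), "sa_not_found",
               sprintf("to_common names unknown subject '%s'", sid))
      sa_check(identical(to_common[[sid]]$source, g$referential_id),
               "sa_invalid_transform",
               sprintf("to_common transform for '%s' does not start at its native referential", sid))
    }
  }
  structure(list(subjects = subjects, nomenclature = nomenclature,
                 to_common = to_common),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d subjects>\n", length(x$subjects)))
  invisible(x)
}

#' Select nodes by structure name across all subjects
#'
#' Selecting a name selects it in every subject at once. Non-leaf names
#' are expanded through the nomenclature: selecting a sulcus made of
#' several sub-entities selects all of them.
#'
#' @param cohort a [cohort()].
#' @param names character vector of structure names; each must occur in
#'   the cohort's nomenclature.
#' @return Named list mapping subject id to the (possibly empty) sorted
#'   integer vector of matching node ids.
#' @export
select_by_label <- function(cohort, names) {
  expanded <- character(0)
  for (nm in names) {
    if (!nom_contains(cohort$nomenclature, nm))
      sa_abort("sa_label_not_in_nomenclature",
               sprintf("name '%s' absent from nomenclature", nm))
    expanded <- c(expanded, subtree_labels(cohort$nomenclature, nm))
  }
  expanded <- unique(expanded)
  lapply(cohort$subjects, function(g) {
    hits <- vapply(g$nodes, function(n) n$label %in% expanded, logical(1))
    sort(unname(vapply(g$nodes[hits], function(n) n$node_id, integer(1))))
  })
}

#' Annotation-consistency report over a cohort
#'
#' Cross-subject sanity check of the annotations: an atlas assembled from
#' individually annotated subjects can accumulate contradictory
#' identifications that only show up when all subjects are examined side
#' by side. For every label in use the report counts the subjects carrying
#' it and the per-subject node counts, and flags (a) labels absent from
#' more than `absence_threshold` of the subjects and (b) labels used in
#' graphs but missing from the nomenclature.
#'
#' @param cohort a [cohort()].
#' @param absence_threshold flag labels missing in more than this fraction
#'   of subjects (default 0.2).
#' @return A `consistency_report`: list with `label_counts` (data frame
#'   `label`, `n_subjects`, `total_nodes`), `node_counts` (label x subject
#'   integer matrix), `flagged_absent` and `flagged_foreign` (character
#'   vectors), `n_subjects`, `absence_threshold`.
#' @export
consistency_report <- function(cohort, absence_threshold = 0.2) {
  sids <- sort(names(cohort$subjects))
  labels <- character(0)
  counts <- list()
  for (sid in sids) {
    labs <- vapply(cohort$subjects[[sid]]$nodes, function(n) n$label,
                   character(1))
    labs <- labs[labs != UNKNOWN_LABEL]
    counts[[sid]] <- table(labs)
    labels <- union(labels, names(counts[[sid]]))
  }
  labels <- sort(labels)
  mat <- matrix(0L, length(labels), length(sids),
                dimnames = list(labels, sids))
  for (sid in sids) {
    tb <- counts[[sid]]
    mat[names(tb), sid] <- as.integer(tb)
  }
  n_subj <- length(sids)
  n_with <- if (n_subj) rowSums(mat > 0L) else integer(0)
  flagged_absent <- labels[n_subj > 0 & (n_subj - n_with) / max(n_subj, 1) >
                             absence_threshold]
  flagged_foreign <- if (is.null(cohort$nomenclature)) character(0)
  else labels[!vapply(labels, function(l) nom_contains(cohort$nomenclature, l),
                      logical(1))]
  structure(list(
    label_counts = data.frame(label = labels,
                              n_subjects = as.integer(n_with),
                              total_nodes = as.integer(rowSums(mat)),
                              stringsAsFactors = FALSE),
    node_counts = mat,
    flagged_absent = flagged_absent,
    flagged_foreign = flagged_foreign,
    n_subjects = n_subj,
    absence_threshold = absence_threshold),
    class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.consistency_report <- function(x, ...) {
  lines <- c(sprintf("Consistency report: %d subjects, %d labels in use",
                     x$n_subjects, nrow(x$label_counts)),
             sprintf("Labels missing in > %.0f%% of subjects: %s",
                     100 * x$absence_threshold,
                     if (length(x$flagged_absent))
                       paste(x$flagged_absent, collapse = ", ") else "none"),
             sprintf("Labels absent from the nomenclature: %s",
                     if (length(x$flagged_foreign))
                       paste(x$flagged_foreign, collapse = ", ") else "none"))
  if (nrow(x$label_counts) > 0)
    lines <- c(lines, "", sprintf("  %-24s %10s %12s", "label", "subjects",
                                  "total nodes"),
               sprintf("  %-24s %10d %12d", x$label_counts$label,
                       x$label_counts$n_subjects, x$label_counts$total_nodes))
  lines
}

#' Paginate the subject list
#'
#' Browsing a large atlas goes page by page: this returns one page of the
#' deterministic (lexicographically sorted) subject ordering.
#'
#' @param cohort a [cohort()].
#' @param page_size subjects per page (>= 1).
#' @param page_index 0-based page number.
#' @return Character vector of subject ids on that page; the last page may
#'   be shorter.
#' @export
paginate <- function(cohort, page_size, page_index) {
  sa_check(page_size >= 1, "sa_not_found", "page_size must be >= 1")
  ids <- sort(names(cohort$subjects))
  n_pages <- ceiling(length(ids) / page_size)
  if (page_index < 0 || page_index >= max(n_pages, 1))
    sa_abort("sa_not_found",
             sprintf("page %d out of range (%d pages)", page_index, n_pages))
  lo <- page_index * page_size + 1
  hi <- min((page_index + 1) * page_size, length(ids))
  if (lo > length(ids)) character(0) else ids[lo:hi]
}
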