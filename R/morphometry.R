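#' Per-fold morphometric measurements
#'
#' Derives scalar measurements from a node's voxel representation:
#' \describe{
#'   \item{size}{voxel count times voxel volume, mm^3.}
#'   \item{surface_area}{voxel count times mean voxel-face area, mm^2 — a
#'     thin-sheet estimate appropriate for the one-voxel-thick negative
#'     cast of a fold.}
#'   \item{length}{extent of the voxel cloud along its first principal
#'     axis, mm.}
#'   \item{max_depth, mean_depth}{the depth axis is taken as the second
#'     principal axis of the voxel cloud (the true depth direction, from
#'     the brain hull inwards, would need the hull itself). Voxels are
#'     binned along the length axis at one-voxel resolution; the depth
#'     extent of each bin gives a depth profile whose maximum and mean are
#'     reported.}
#'   \item{thickness, opening}{never computed here — estimating cortical
#'     thickness or sulcal opening needs the original MRI. Existing values
#'     in `node$properties` are passed through untouched.}
#' }
#'
#' @param node a [structure_node()] with a voxel representation.
#' @param geometry optional [volume_geometry()] overriding the one stored
#'   in the node's voxel set.
#' @return Named numeric vector of measurements (the node's existing
#'   properties, updated).
#' @export
compute_node_measures <- function(node, geometry = NULL) {
  if (is.null(node$voxel_rep))
    sa_abort("sa_no_representation",
             sprintf("node %d has no voxel representation", node$node_id))
  geo <- if (is.null(geometry)) node$voxel_rep$geometry else geometry
  v <- node$voxel_rep$voxels
  n <- nrow(v)
  vs <- geo$voxel_size
  props <- node$properties

  props["size"] <- n * prod(vs)
  props["surface_area"] <-
    n * mean(c(vs[1] * vs[2], vs[2] * vs[3], vs[1] * vs[3]))

  w <- voxel_to_world(geo, v)
  if (n == 1L) {
    props["length"] <- 0
    props["max_depth"] <- 0
    props["mean_depth"] <- 0
    return(props)
  }
  pc <- stats::prcomp(w, center = TRUE, scale. = FALSE)
  along <- pc$x[, 1]
  depth <- if (ncol(pc$x) >= 2) pc$x[, 2] else rep(0, n)
  # extents are measured between voxel centres; add the projection of one
  # voxel box onto the axis so an L-voxel straight run measures L mm
  M <- geo$voxel_to_world[1:3, 1:3]
  w1 <- sum(abs(as.numeric(pc$rotation[, 1] %*% M)))
  w2 <- if (ncol(pc$x) >= 2) sum(abs(as.numeric(pc$rotation[, 2] %*% M)))
  else 0
  props["length"] <- max(along) - min(along) + w1
  # depth profile: depth extent per one-voxel-wide bin along the length axis
  binw <- min(vs)
  bins <- floor((along - min(along)) / binw)
  ext <- tapply(depth, bins, function(d) max(d) - min(d)) + w2
  props["max_depth"] <- max(ext)
  props["mean_depth"] <- mean(ext)
  props
}

#' Aggregate node measurements into a per-sulcus table
#'
#' A sulcus is the union of the fold nodes sharing one label, so
#' measurements are pooled per label: `size`, `surface_area` and `length`
#' are summed over the nodes; `max_depth`, `mean_depth`, `thickness` and
#' `opening` are size-weighted means of the node values. Unlabeled nodes
#' are pooled under [UNKNOWN_LABEL]; labels with no node are absent.
#' Node measurements missing from `properties` are computed on the fly
#' from the voxel representation.
#'
#' @param graph a [structural_graph()].
#' @param nomenclature optional [nomenclature()]; labels outside it (other
#'   than [UNKNOWN_LABEL]) raise an error, catching annotation typos
#'   before they silently become separate table rows.
#' @return A long-format data frame — the morphometry table — with columns
#'   `subject`, `label`, `metric`, `value`, one row per (label, metric).
#' @export
aggregate_morphometry <- function(graph, nomenclature = NULL) {
  summed <- c("size", "surface_area", "length")
  weighted <- c("max_depth", "mean_depth", "thickness", "opening")
  rows <- list()
  per_label <- list()
  for (node in graph$nodes) {
    props <- if (!is.null(node$voxel_rep)) compute_node_measures(node)
    else node$properties
    lab <- node$label
    if (!is.null(nomenclature) && lab != UNKNOWN_LABEL &&
        !nom_contains(nomenclature, lab))
      sa_abort("sa_label_not_in_nomenclature",
               sprintf("node %d label '%s' absent from nomenclature",
                       node$node_id, lab))
    per_label[[lab]] <- c(per_label[[lab]], list(props))
  }
  for (lab in sort(names(per_label))) {
    plist <- per_label[[lab]]
    sizes <- vapply(plist, function(p) {
      s <- p["size"]; if (is.na(s)) 0 else unname(s)
    }, numeric(1))
    for (m in summed) {
      vals <- vapply(plist, function(p) unname(p[m]), numeric(1))
      if (all(is.na(vals))) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject = graph$subject_id, label = lab, metric = m,
        value = sum(vals, na.rm = TRUE), stringsAsFactors = FALSE)
    }
    for (m in weighted) {
      vals <- vapply(plist, function(p) unname(p[m]), numeric(1))
      keep <- !is.na(vals)
      if (!any(keep)) next
      wts <- sizes[keep]
      if (sum(wts) == 0) wts <- rep(1, sum(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = graph$subject_id, label = lab, metric = m,
        value = sum(vals[keep] * wts) / sum(wts), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(subject = character(0), label = character(0),
                      metric = character(0), value = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Morphometry table for a whole cohort
#'
#' Concatenates the per-subject aggregates of every graph in the cohort:
#' one row per (subject, label, metric), ready for population-level
#' statistics on a per-sulcus basis.
#'
#' @param cohort a [cohort()].
#' @param nomenclature optional [nomenclature()] (defaults to the cohort's
#'   shared one).
#' @return Long-format data frame with columns `subject`, `label`,
#'   `metric`, `value`.
#' @export
cohort_morphometry <- function(cohort, nomenclature = NULL) {
  if (is.null(nomenclature)) nomenclature <- cohort$nomenclature
  parts <- lapply(cohort$subjects, aggregate_morphometry,
                  nomenclature = nomenclature)
  if (length(parts) == 0L)
    return(data.frame(subject = character(0), label = character(0),
                      metric = character(0), value = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write a morphometry table to CSV
#'
#' Fixed column order `subject,label,metric,value`; values are written
#' with 17 significant digits so identical tables give identical bytes.
#'
#' @param table a morphometry data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_morphometry_csv <- function(table, path) {
  lines <- c("subject,label,metric,value",
             sprintf("%s,%s,%s,%s", table$subject, table$label,
                     table$metric, format_num(table$value)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a morphometry CSV
#'
#' @param path file written by [write_morphometry_csv()].
#' @return Long-format morphometry data frame.
#' @export
read_morphometry_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character",
                                        "character", "numeric"))
  sa_check(identical(names(out), c("subject", "label", "metric", "value")),
           "sa_parse_error", "morphometry CSV must have columns subject,label,metric,value")
  out
}
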