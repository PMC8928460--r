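#' Structural graphs of cortical folds
#'
#' A structural graph holds one subject's elementary cortical folds as
#' nodes and their topographic relations (junction and proximity) as edges.
#' Each node carries a geometric representation — a voxel set, a triangle
#' mesh, or both — plus a label from a nomenclature and a map of scalar
#' measurements. The graph is bound to a named referential: all of its
#' coordinates live in the subject's own native space.
#'
#' @param subject_id subject identifier string.
#' @param hemisphere one of `"left"`, `"right"`, `"both"`.
#' @param referential_id name of the native coordinate system.
#' @param metadata optional named character list.
#' @return An empty `structural_graph`.
#' @seealso [add_node()], [remove_node()], [validate_graph()]
#' @export
structural_graph <- function(subject_id, hemisphere = c("left", "right", "both"),
                             referential_id = paste0(subject_id, "_native"),
                             metadata = list()) {
  hemisphere <- match.arg(hemisphere)
  structure(list(subject_id = as.character(subject_id),
                 hemisphere = hemisphere,
                 referential_id = as.character(referential_id),
                 nodes = list(), edges = list(),
                 metadata = metadata),
            class = "structural_graph")
}

#' Label sentinel for unannotated structures
#'
#' The canonical spelling of the "not yet labeled" sentinel. A node whose
#' label equals this string is not checked against any nomenclature.
#' @export
UNKNOWN_LABEL <- "unknown"

#' Create a structure node
#'
#' @param node_id integer id, unique within its graph.
#' @param label structure name, or [UNKNOWN_LABEL] when unannotated.
#' @param voxel_rep optional [voxel_surface_set()].
#' @param mesh optional [triangle_mesh()].
#' @param properties named numeric vector of scalar measurements
#'   (e.g. `size`, `length`, `mean_depth`, `max_depth`, `thickness`,
#'   `opening`, `surface_area`).
#' @return An object of class `structure_node`. At least one of `voxel_rep`
#'   and `mesh` must be given: a node without any geometric representation
#'   is meaningless.
#' @export
structure_node <- function(node_id, label = UNKNOWN_LABEL, voxel_rep = NULL,
                           mesh = NULL, properties = numeric(0)) {
  sa_check(!is.null(voxel_rep) || !is.null(mesh), "sa_no_representation",
           "a node needs a voxel_rep or a mesh")
  if (!is.null(voxel_rep))
    stopifnot(inherits(voxel_rep, "voxel_surface_set"))
  if (!is.null(mesh))
    stopifnot(inherits(mesh, "triangle_mesh"))
  structure(list(node_id = as.integer(node_id), label = as.character(label),
                 voxel_rep = voxel_rep, mesh = mesh,
                 properties = properties),
            class = "structure_node")
}

#' Create a topographic relation between two folds
#'
#' @param edge_id integer id, unique within its graph.
#' @param kind `"junction"` (the folds touch) or `"proximity"` (they lie
#'   close without touching).
#' @param endpoints unordered pair of distinct node ids.
#' @param properties named numeric vector.
#' @return An object of class `structure_edge`.
#' @export
structure_edge <- function(edge_id, kind = c("junction", "proximity"),
                           endpoints, properties = numeric(0)) {
  kind <- match.arg(kind)
  endpoints <- as.integer(endpoints)
  sa_check(length(endpoints) == 2 && endpoints[1] != endpoints[2],
           "sa_invalid_edge", "endpoints must be two distinct node ids")
  structure(list(edge_id = as.integer(edge_id), kind = kind,
                 endpoints = endpoints, properties = properties),
            class = "structure_edge")
}

#' @export
print.structural_graph <- function(x, ...) {
  cat(sprintf("<structural_graph %s/%s: %d nodes, %d edges, referential '%s'>\n",
              x$subject_id, x$hemisphere, length(x$nodes), length(x$edges),
              x$referential_id))
  invisible(x)
}

graph_geometry <- function(graph) {
  for (n in graph$nodes)
    if (!is.null(n$voxel_rep)) return(n$voxel_rep$geometry)
  NULL
}

#' Insert a node into a structural graph
#'
#' Fails if the id is already taken, or if the node's voxel representation
#' uses a different volume geometry than the rest of the graph (all voxel
#' sets of one graph share a single grid).
#'
#' @param graph a [structural_graph()].
#' @param node a [structure_node()].
#' @return The updated graph.
#' @export
add_node <- function(graph, node) {
  stopifnot(inherits(graph, "structural_graph"),
            inherits(node, "structure_node"))
  key <- as.character(node$node_id)
  if (!is.null(graph$nodes[[key]]))
    sa_abort("sa_id_collision",
             sprintf("node id %d already present", node$node_id))
  geo <- graph_geometry(graph)
  if (!is.null(geo) && !is.null(node$voxel_rep) &&
      !geometry_equal(geo, node$voxel_rep$geometry))
    sa_abort("sa_geometry_mismatch",
             sprintf("node %d voxel geometry differs from the graph's",
                     node$node_id))
  graph$nodes[[key]] <- node
  graph
}

#' Remove a node and all its incident edges
#'
#' @param graph a [structural_graph()].
#' @param node_id id of the node to delete.
#' @return The updated graph; every edge touching the node is removed too.
#' @export
remove_node <- function(graph, node_id) {
  key <- as.character(as.integer(node_id))
  if (is.null(graph$nodes[[key]]))
    sa_abort("sa_not_found", sprintf("no node with id %s", key))
  graph$nodes[[key]] <- NULL
  keep <- vapply(graph$edges, function(e) !(node_id %in% e$endpoints),
                 logical(1))
  graph$edges <- graph$edges[keep]
  graph
}

#' Insert an edge
#'
#' @param graph a [structural_graph()].
#' @param edge a [structure_edge()]; both endpoints must exist.
#' @return The updated graph.
#' @export
add_edge <- function(graph, edge) {
  stopifnot(inherits(edge, "structure_edge"))
  key <- as.character(edge$edge_id)
  if (!is.null(graph$edges[[key]]))
    sa_abort("sa_id_collision",
             sprintf("edge id %d already present", edge$edge_id))
  for (ep in edge$endpoints)
    if (is.null(graph$nodes[[as.character(ep)]]))
      sa_abort("sa_not_found", sprintf("edge endpoint %d not in graph", ep))
  graph$edges[[key]] <- edge
  graph
}

#' Node ids adjacent to a node
#'
#' @param graph a [structural_graph()].
#' @param node_id node of interest.
#' @param kind optionally restrict to `"junction"` or `"proximity"` edges.
#' @return Sorted integer vector of neighbouring node ids.
#' @export
neighbors <- function(graph, node_id, kind = NULL) {
  out <- integer(0)
  for (e in graph$edges) {
    if (!is.null(kind) && e$kind != kind) next
    if (node_id %in% e$endpoints)
      out <- c(out, setdiff(e$endpoints, node_id))
  }
  sort(unique(out))
}

node_ids <- function(graph) {
  sort(unname(vapply(graph$nodes, function(n) n$node_id, integer(1))))
}

edge_ids <- function(graph) {
  sort(unname(vapply(graph$edges, function(e) e$edge_id, integer(1))))
}

next_free_id <- function(ids) if (length(ids) == 0L) 1L else max(ids) + 1L

#' Check every integrity rule of a structural graph
#'
#' Runs all type invariants — id uniqueness, edge endpoint resolution,
#' shared volume geometry, voxel-set bounds and 26-connectivity, triangle
#' validity, label membership when a nomenclature is supplied — and reports
#' each violation instead of stopping at the first.
#'
#' @param graph a [structural_graph()].
#' @param nomenclature optional [nomenclature()]; when given, every label
#'   other than [UNKNOWN_LABEL] must occur in it.
#' @return A data frame with columns `entity`, `rule`, `message`; zero rows
#'   when the graph is well formed.
#' @export
validate_graph <- function(graph, nomenclature = NULL) {
  bad <- list()
  flag <- function(entity, rule, message)
    bad[[length(bad) + 1L]] <<- data.frame(entity = entity, rule = rule,
                                           message = message)

  ids <- vapply(graph$nodes, function(n) n$node_id, integer(1))
  if (anyDuplicated(ids))
    flag("graph", "unique_node_ids",
         sprintf("duplicate node ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (key in names(graph$nodes)) {
    n <- graph$nodes[[key]]
    if (as.character(n$node_id) != key)
      flag(paste0("node:", key), "key_matches_id",
           sprintf("stored under key %s but node_id is %d", key, n$node_id))
    if (is.null(n$voxel_rep) && is.null(n$mesh))
      flag(paste0("node:", key), "has_representation",
           "node has neither voxel_rep nor mesh")
    if (!is.null(nomenclature) && n$label != UNKNOWN_LABEL &&
        !nom_contains(nomenclature, n$label))
      flag(paste0("node:", key), "label_in_nomenclature",
           sprintf("label '%s' absent from nomenclature", n$label))
  }

  geo <- graph_geometry(graph)
  for (key in names(graph$nodes)) {
    vr <- graph$nodes[[key]]$voxel_rep
    if (is.null(vr)) next
    if (!geometry_equal(vr$geometry, geo))
      flag(paste0("node:", key), "shared_geometry",
           "voxel geometry differs from the graph's")
    v <- vr$voxels
    inb <- v[, 1] >= 0L & v[, 2] >= 0L & v[, 3] >= 0L &
      v[, 1] < vr$geometry$shape[1] & v[, 2] < vr$geometry$shape[2] &
      v[, 3] < vr$geometry$shape[3]
    if (!all(inb))
      flag(paste0("node:", key), "voxels_in_bounds",
           sprintf("%d voxels outside the grid", sum(!inb)))
    if (nrow(v) == 0L)
      flag(paste0("node:", key), "voxels_nonempty", "empty voxel set")
    else if (max(voxel_components(v)) > 1L)
      flag(paste0("node:", key), "voxels_connected",
           sprintf("voxel set splits into %d 26-connected components",
                   max(voxel_components(v))))
  }

  eids <- vapply(graph$edges, function(e) e$edge_id, integer(1))
  if (anyDuplicated(eids))
    flag("graph", "unique_edge_ids",
         sprintf("duplicate edge ids: %s",
                 paste(unique(eids[duplicated(eids)]), collapse = ", ")))
  for (key in names(graph$edges)) {
    e <- graph$edges[[key]]
    for (ep in e$endpoints)
      if (is.null(graph$nodes[[as.character(ep)]]))
        flag(paste0("edge:", key), "endpoints_exist",
             sprintf("edge %s references absent node %d", key, ep))
    if (e$endpoints[1] == e$endpoints[2])
      flag(paste0("edge:", key), "no_self_loop",
           sprintf("edge %s is a self-loop on node %d", key, e$endpoints[1]))
  }

  if (length(bad) == 0L)
    data.frame(entity = character(0), rule = character(0),
               message = character(0))
  else
    do.call(rbind, bad)
}
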