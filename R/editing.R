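#' Label assignment with copy/paste semantics
#'
#' Annotation works like a clipboard: a label is picked from one node —
#' possibly in another subject's graph — and pasted onto a series of
#' selected nodes. `set_label()` is the paste; `copy_label()` fills the
#' clipboard.
#'
#' @param graph a [structural_graph()].
#' @param node_ids integer vector of nodes to annotate.
#' @param label structure name; must occur in `nomenclature`, or be
#'   [UNKNOWN_LABEL] (which clears the annotation).
#' @param nomenclature a [nomenclature()] validating the label, or `NULL`
#'   to skip validation.
#' @return The updated graph; only the listed nodes change.
#' @export
set_label <- function(graph, node_ids, label, nomenclature = NULL) {
  if (!is.null(nomenclature) && label != UNKNOWN_LABEL &&
      !nom_contains(nomenclature, label))
    sa_abort("sa_label_not_in_nomenclature",
             sprintf("label '%s' absent from nomenclature", label))
  for (id in node_ids) {
    key <- as.character(as.integer(id))
    if (is.null(graph$nodes[[key]]))
      sa_abort("sa_not_found", sprintf("no node with id %s", key))
  }
  for (id in node_ids)
    graph$nodes[[as.character(as.integer(id))]]$label <- label
  graph
}

#' @rdname set_label
#' @param node_id node to copy the label from.
#' @param allow_unknown permit copying the [UNKNOWN_LABEL] sentinel
#'   (default FALSE: copying from an unannotated node is almost always a
#'   selection mistake).
#' @return `copy_label()` returns a `label_clipboard`: the label plus its
#'   provenance (source subject and node).
#' @export
copy_label <- function(graph, node_id, allow_unknown = FALSE) {
  key <- as.character(as.integer(node_id))
  node <- graph$nodes[[key]]
  if (is.null(node))
    sa_abort("sa_not_found", sprintf("no node with id %s", key))
  if (node$label == UNKNOWN_LABEL && !allow_unknown)
    sa_abort("sa_unlabeled_source",
             sprintf("node %s carries no label to copy", key))
  structure(list(label = node$label, source_subject = graph$subject_id,
                 source_node = node$node_id),
            class = "label_clipboard")
}

#' @rdname set_label
#' @param clipboard a `label_clipboard` from [copy_label()]. The target
#'   graph may belong to a different subject.
#' @export
paste_label <- function(graph, node_ids, clipboard, nomenclature = NULL) {
  stopifnot(inherits(clipboard, "label_clipboard"))
  set_label(graph, node_ids, clipboard$label, nomenclature)
}

# Snap seed points (mm) to nearest voxels of a set; error when any seed is
# farther than `radius` voxel units (Chebyshev, in voxel coordinates).
snap_seeds <- function(seeds, vset, radius = 2) {
  vox <- world_to_voxel(vset$geometry, seeds)
  rows <- integer(nrow(vox))
  v <- vset$voxels
  for (i in seq_len(nrow(vox))) {
    cheb <- pmax(abs(v[, 1] - vox[i, 1]), abs(v[, 2] - vox[i, 2]),
                 abs(v[, 3] - vox[i, 3]))
    j <- which.min(cheb)
    if (cheb[j] > radius)
      sa_abort("sa_seed_off_structure",
               sprintf("seed point %d is %.1f voxels away from the fold (max %g)",
                       i, cheb[j], radius))
    rows[i] <- j
  }
  rows
}

# Cut spine: in-set shortest paths between consecutive snapped seeds,
# extended at both ends along +/- the dominant principal axis until the
# walk leaves the set. The extension walks the voxel set itself (greedy
# 26-neighbour steps with strictly increasing projection on the axis,
# preferring voxels close to the straight line through the first seed), so
# it follows curved one-voxel-thick sheets instead of stepping off them.
# Diagonal steps are thickened with their axis-aligned companions: a
# 26-path with diagonal moves does not separate a 26-connected sheet on
# its own. Returns row indices into vset$voxels, in path order.
cut_spine <- function(vset, seed_rows) {
  v <- vset$voxels
  spine <- seed_rows[1]
  if (length(seed_rows) > 1) {
    for (i in seq_len(length(seed_rows) - 1L)) {
      seg <- voxel_shortest_path(v, seed_rows[i], seed_rows[i + 1L])
      if (is.null(seg))
        sa_abort("sa_cut_ineffective", "seed points are not connected inside the fold")
      spine <- c(spine, seg[-1])
    }
  }
  # dominant principal axis in world mm, converted to voxel space
  w <- voxel_to_world(vset$geometry, v)
  pc <- stats::prcomp(w, center = TRUE, scale. = FALSE)
  dir_v <- solve(vset$geometry$voxel_to_world[1:3, 1:3], pc$rotation[, 1])
  dirn <- dir_v / sqrt(sum(dir_v^2))
  proj <- as.numeric(v %*% dirn)
  keys <- paste(v[, 1], v[, 2], v[, 3])
  row_of <- function(m) match(paste(m[, 1], m[, 2], m[, 3]), keys)
  anchor <- as.numeric(v[seed_rows[1], ])

  walk <- function(start_row, sgn) {
    rows <- integer(0)
    cur <- start_row
    repeat {
      nb <- matrix(v[cur, ], 26, 3, byrow = TRUE) + .offsets26
      cand <- row_of(nb)
      cand <- cand[!is.na(cand)]
      cand <- cand[sgn * proj[cand] > sgn * proj[cur] + 0.1]
      if (length(cand) == 0L) break
      rel <- v[cand, , drop = FALSE] -
        matrix(anchor, length(cand), 3, byrow = TRUE)
      t <- as.numeric(rel %*% dirn)
      perp <- rowSums((rel - outer(t, dirn))^2)
      cur <- cand[which.min(perp)]
      rows <- c(rows, cur)
    }
    rows
  }
  ordered <- c(rev(walk(spine[1], -1)), spine,
               walk(spine[length(spine)], +1))
  ordered <- ordered[!duplicated(ordered)]

  extra <- integer(0)
  if (length(ordered) > 1) {
    for (i in seq_len(length(ordered) - 1L)) {
      a <- v[ordered[i], ]
      d <- v[ordered[i + 1L], ] - a
      if (sum(d != 0L) < 2L) next
      comp <- rbind(c(d[1], 0L, 0L), c(0L, d[2], 0L), c(0L, 0L, d[3]))
      comp <- comp[d != 0L, , drop = FALSE]
      hit <- row_of(matrix(a, nrow(comp), 3, byrow = TRUE) + comp)
      extra <- c(extra, hit[!is.na(hit)])
    }
  }
  unique(c(ordered, extra))
}

#' Split a fold node in two along a cutting line
#'
#' Splits one fold into two new graph nodes along a cut line drawn through
#' one or several seed points — the repair applied when two sulci were
#' erroneously merged into a single fold during segmentation. The
#' procedure: (1) each seed (world mm) is snapped to the nearest voxel of
#' the fold, at most `snap_radius` voxels away; (2) consecutive snapped
#' seeds are joined by shortest 26-connected in-set paths, forming the cut
#' spine; (3) the spine is extended from both ends along the fold's
#' dominant principal axis (an approximation of the local depth direction)
#' until the walk leaves the voxel set; (4) removing the spine must leave
#' exactly two 26-connected components; (5) each spine voxel is handed to
#' the component nearest to it (ties to the larger component), so the two
#' children exactly partition the parent's voxels; (6) the parent node is
#' deleted, each former incident edge reattaches to the child nearest to
#' the former neighbour (minimum voxel-pair distance), and a junction edge
#' is added between the children, which both inherit the parent's label;
#' (7) any parent mesh is dropped — the children are voxel-list only until
#' remeshed.
#'
#' @param graph a [structural_graph()].
#' @param node_id id of the node to split; must have a voxel representation.
#' @param seed_points one mm triple or an n x 3 matrix of cut points, in
#'   the graph's native coordinates.
#' @param snap_radius maximum seed-to-fold snapping distance, voxel units
#'   (default 2).
#' @return A list with `graph` (updated) and `new_ids` (the two child node
#'   ids, in decreasing voxel-count order).
#' @export
split_node <- function(graph, node_id, seed_points, snap_radius = 2) {
  key <- as.character(as.integer(node_id))
  node <- graph$nodes[[key]]
  if (is.null(node))
    sa_abort("sa_not_found", sprintf("no node with id %s", key))
  if (is.null(node$voxel_rep))
    sa_abort("sa_no_representation",
             sprintf("node %s has no voxel representation to split", key))
  if (is.null(dim(seed_points)))
    seed_points <- matrix(seed_points, 1, 3)
  sa_check(nrow(seed_points) >= 1, "sa_seed_off_structure",
           "at least one seed point is required")
  vset <- node$voxel_rep
  v <- vset$voxels

  seed_rows <- snap_seeds(seed_points, vset, snap_radius)
  spine <- cut_spine(vset, seed_rows)
  rest <- setdiff(seq_len(nrow(v)), spine)
  if (length(rest) == 0L)
    sa_abort("sa_cut_ineffective", "cut consumed the entire fold")
  comp <- voxel_components(v[rest, , drop = FALSE])
  ncomp <- max(comp)
  if (ncomp == 1L)
    sa_abort("sa_cut_ineffective", "cut left the fold in one piece")
  if (ncomp > 2L)
    sa_abort("sa_ambiguous_cut",
             sprintf("cut shattered the fold into %d pieces", ncomp))

  rows1 <- rest[comp == 1L]
  rows2 <- rest[comp == 2L]
  # hand each spine voxel to the nearest component, ties to the larger one
  larger_first <- length(rows1) >= length(rows2)
  w <- voxel_to_world(vset$geometry, v)
  w1 <- w[rows1, , drop = FALSE]; w2 <- w[rows2, , drop = FALSE]
  for (s in spine) {
    d1 <- min(colSums((t(w1) - w[s, ])^2))
    d2 <- min(colSums((t(w2) - w[s, ])^2))
    if (d1 < d2 || (d1 == d2 && larger_first)) rows1 <- c(rows1, s)
    else rows2 <- c(rows2, s)
  }
  if (length(rows1) < length(rows2)) { tmp <- rows1; rows1 <- rows2; rows2 <- tmp }

  ids <- node_ids(graph)
  id1 <- next_free_id(ids)
  id2 <- id1 + 1L
  child <- function(id, rows) structure_node(
    id, label = node$label,
    voxel_rep = voxel_surface_set(v[rows, , drop = FALSE], vset$geometry,
                                  check = FALSE))
  n1 <- child(id1, rows1)
  n2 <- child(id2, rows2)

  # re-home former incident edges to the nearest child
  incident <- Filter(function(e) node$node_id %in% e$endpoints, graph$edges)
  graph <- remove_node(graph, node$node_id)
  graph <- add_node(graph, n1)
  graph <- add_node(graph, n2)
  eid <- next_free_id(edge_ids(graph))
  for (e in incident) {
    other <- setdiff(e$endpoints, node$node_id)
    if (length(other) == 0L) next
    ov <- graph$nodes[[as.character(other)]]$voxel_rep
    target <- if (is.null(ov)) id1 else {
      d1 <- voxel_set_min_distance(n1$voxel_rep$voxels, ov$voxels, vset$geometry)
      d2 <- voxel_set_min_distance(n2$voxel_rep$voxels, ov$voxels, vset$geometry)
      if (d1 <= d2) id1 else id2
    }
    graph <- add_edge(graph, structure_edge(eid, e$kind, c(target, other),
                                            e$properties))
    eid <- eid + 1L
  }
  graph <- add_edge(graph, structure_edge(eid, "junction", c(id1, id2)))
  list(graph = graph, new_ids = c(id1, id2))
}

#' Merge two fold nodes into one
#'
#' The inverse of [split_node()], used to undo a cut: the two voxel sets
#' are united under the first node's label, edges of both are re-homed to
#' the merged node (duplicates collapsed, junction preferred over
#' proximity), and any edge between the pair disappears.
#'
#' @param graph a [structural_graph()].
#' @param node_id_a,node_id_b nodes to merge; both need voxel
#'   representations on the same grid. The merged node keeps `node_id_a`
#'   and `a`'s label.
#' @return The updated graph.
#' @export
merge_nodes <- function(graph, node_id_a, node_id_b) {
  ka <- as.character(as.integer(node_id_a))
  kb <- as.character(as.integer(node_id_b))
  a <- graph$nodes[[ka]]; b <- graph$nodes[[kb]]
  if (is.null(a) || is.null(b))
    sa_abort("sa_not_found", "both nodes must exist")
  sa_check(!is.null(a$voxel_rep) && !is.null(b$voxel_rep),
           "sa_no_representation", "both nodes need voxel representations")
  sa_check(geometry_equal(a$voxel_rep$geometry, b$voxel_rep$geometry),
           "sa_geometry_mismatch", "nodes live on different grids")

  merged <- structure_node(
    a$node_id, label = a$label,
    voxel_rep = voxel_surface_set(rbind(a$voxel_rep$voxels,
                                        b$voxel_rep$voxels),
                                  a$voxel_rep$geometry, check = FALSE),
    properties = a$properties)
  incident <- Filter(function(e) any(c(a$node_id, b$node_id) %in% e$endpoints),
                     graph$edges)
  graph <- remove_node(graph, b$node_id)
  graph <- remove_node(graph, a$node_id)
  graph$nodes[[ka]] <- merged

  seen <- list()  # neighbour id -> kind already attached
  eid <- next_free_id(edge_ids(graph))
  for (e in incident) {
    other <- setdiff(e$endpoints, c(a$node_id, b$node_id))
    if (length(other) == 0L) next  # the a--b edge itself
    okey <- as.character(other)
    prev <- seen[[okey]]
    if (!is.null(prev)) {
      if (prev == "proximity" && e$kind == "junction") {
        keep <- Filter(function(x) !(other %in% x$endpoints &&
                                       a$node_id %in% x$endpoints),
                       graph$edges)
        graph$edges <- keep
      } else next
    }
    graph <- add_edge(graph, structure_edge(eid, e$kind,
                                            c(a$node_id, other),
                                            e$properties))
    seen[[okey]] <- e$kind
    eid <- eid + 1L
  }
  graph
}
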