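#' Decentralized graph of coordinate systems
#'
#' Every dataset lives in its own referential (named coordinate system);
#' there is no privileged central space. Referentials are joined by
#' transforms: affine 4x4 matrices, traversable in both directions (the
#' inverse is taken on the fly), and deformation fields, which are
#' directed — a dense non-linear mapping need not be invertible at every
#' point, so a field edge is never walked backwards. Coordinates are
#' carried from any referential to any other by composing the transforms
#' along a path of the graph.
#'
#' @return An empty `transformation_graph`.
#' @seealso [add_referential()], [add_affine()], [add_deformation_field()],
#'   [resolve_path()], [map_point()]
#' @export
transformation_graph <- function() {
  structure(list(referentials = character(0),
                 affines = list(), fields = list()),
            class = "transformation_graph")
}

#' @export
print.transformation_graph <- function(x, ...) {
  cat(sprintf("<transformation_graph: %d referentials, %d affines, %d fields>\n",
              length(x$referentials), length(x$affines), length(x$fields)))
  invisible(x)
}

#' Register a referential
#'
#' @param tg a [transformation_graph()].
#' @param ref_id non-empty referential name. Re-registering an existing
#'   name is a no-op.
#' @return The updated graph.
#' @export
add_referential <- function(tg, ref_id) {
  sa_check(is.character(ref_id) && length(ref_id) == 1 && nzchar(ref_id),
           "sa_invalid_referential", "ref_id must be a non-empty string")
  if (!(ref_id %in% tg$referentials))
    tg$referentials <- c(tg$referentials, ref_id)
  tg
}

#' Join two referentials with an affine transform
#'
#' @param tg a [transformation_graph()].
#' @param source,target referential names; registered automatically.
#' @param matrix 4x4 homogeneous matrix mapping source mm to target mm.
#'   Its 3x3 block must be invertible, since affine edges are traversed in
#'   both directions.
#' @return The updated graph.
#' @export
add_affine <- function(tg, source, target, matrix) {
  matrix <- unname(as.matrix(matrix))
  sa_check(all(dim(matrix) == c(4, 4)) &&
             isTRUE(all.equal(matrix[4, ], c(0, 0, 0, 1))),
           "sa_invalid_transform", "matrix must be 4x4 with last row (0,0,0,1)")
  d <- det(matrix[1:3, 1:3])
  sa_check(is.finite(d) && abs(d) > 1e-12, "sa_invalid_transform",
           "3x3 block must be invertible")
  sa_check(source != target, "sa_invalid_transform",
           "self-loop transforms are not allowed")
  tg <- add_referential(tg, source)
  tg <- add_referential(tg, target)
  tg$affines[[length(tg$affines) + 1L]] <-
    list(source = source, target = target, matrix = matrix)
  tg
}

#' Join two referentials with a deformation field
#'
#' The field is a vector volume sampled on a grid in the source space:
#' voxel `(i, j, k)` stores the target-space mm coordinates that the world
#' position of that source voxel maps to (absolute-coordinate convention).
#' Field edges are directed and never inverted.
#'
#' @param tg a [transformation_graph()].
#' @param source,target referential names.
#' @param field `shape x 3` numeric array of target mm coordinates.
#' @param geometry [volume_geometry()] of the field grid, in source space.
#' @return The updated graph.
#' @export
add_deformation_field <- function(tg, source, target, field, geometry) {
  sa_check(length(dim(field)) == 4 && dim(field)[4] == 3,
           "sa_invalid_transform",
           "field must be a 4D array with 3 components in the last axis")
  sa_check(all(dim(field)[1:3] == geometry$shape), "sa_invalid_transform",
           "field grid does not match its geometry")
  sa_check(source != target, "sa_invalid_transform",
           "self-loop transforms are not allowed")
  tg <- add_referential(tg, source)
  tg <- add_referential(tg, target)
  tg$fields[[length(tg$fields) + 1L]] <-
    list(source = source, target = target, field = field,
         geometry = geometry)
  tg
}

# Directed edge table: one row per traversable step.
tg_edge_table <- function(tg) {
  rows <- list()
  for (i in seq_along(tg$affines)) {
    a <- tg$affines[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      from = a$source, to = a$target, kind = "affine", index = i,
      direction = "forward", stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      from = a$target, to = a$source, kind = "affine", index = i,
      direction = "inverse", stringsAsFactors = FALSE)
  }
  for (i in seq_along(tg$fields)) {
    f <- tg$fields[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      from = f$source, to = f$target, kind = "field", index = i,
      direction = "forward", stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    data.frame(from = character(0), to = character(0), kind = character(0),
               index = integer(0), direction = character(0))
  else do.call(rbind, rows)
}

#' Find the chain of transforms joining two referentials
#'
#' Breadth-first search over the transformation graph: the returned path
#' has the fewest edges among all paths; when several shortest paths
#' exist, the one whose sequence of traversed referential names is
#' lexicographically smallest is chosen, so resolution is deterministic.
#' Affine edges may be traversed forwards or backwards; deformation-field
#' edges only forwards.
#'
#' @param tg a [transformation_graph()].
#' @param source,target registered referential names.
#' @return `NULL` when the referentials are not connected. Otherwise a
#'   list of steps (empty for `source == target`), each a list with
#'   elements `kind` ("affine" or "field"), `direction` ("forward" or
#'   "inverse"), `from`, `to`, and the transform payload (`matrix`, or
#'   `field` + `geometry`).
#' @export
resolve_path <- function(tg, source, target) {
  for (r in c(source, target))
    if (!(r %in% tg$referentials))
      sa_abort("sa_not_found", sprintf("unknown referential '%s'", r))
  if (source == target) return(list())
  edges <- tg_edge_table(tg)
  # distance-to-target over reversed edges, then a greedy lexicographic
  # descent from the source along distance-decreasing edges
  dist <- stats::setNames(rep(Inf, length(tg$referentials)), tg$referentials)
  dist[target] <- 0
  frontier <- target
  while (length(frontier) > 0L) {
    nxt <- character(0)
    for (r in frontier) {
      preds <- edges$from[edges$to == r]
      new <- preds[!is.finite(dist[preds])]
      dist[new] <- dist[r] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  if (!is.finite(dist[source])) return(NULL)

  path <- list()
  cur <- source
  while (cur != target) {
    out <- edges[edges$from == cur, , drop = FALSE]
    out <- out[is.finite(dist[out$to]) & dist[out$to] == dist[cur] - 1, ,
               drop = FALSE]
    out <- out[order(out$to, out$kind, out$index), , drop = FALSE]
    step <- out[1, ]
    payload <- if (step$kind == "affine")
      list(matrix = tg$affines[[step$index]]$matrix)
    else
      list(field = tg$fields[[step$index]]$field,
           geometry = tg$fields[[step$index]]$geometry)
    path[[length(path) + 1L]] <- c(
      list(kind = step$kind, direction = step$direction,
           from = step$from, to = step$to), payload)
    cur <- step$to
  }
  path
}

#' Collapse an affine-only path into a single matrix
#'
#' Multiplies the step matrices (inverting the ones traversed backwards)
#' in traversal order, yielding one 4x4 matrix whose action on a point
#' equals applying the whole chain.
#'
#' @param path a path as returned by [resolve_path()].
#' @return 4x4 homogeneous matrix; the identity for an empty path.
#' @export
compose_affine_path <- function(path) {
  m <- diag(4)
  for (step in path) {
    if (step$kind != "affine")
      sa_abort("sa_not_composable",
               "path contains a deformation-field step; fields compose pointwise, not as one matrix")
    sm <- if (step$direction == "inverse") solve(step$matrix) else step$matrix
    m <- sm %*% m
  }
  m
}

# Trilinear interpolation of a scalar 3D array at fractional 0-based voxel
# coordinates (n x 3). Out-of-grid rows yield NA.
interp_trilinear <- function(arr, vox) {
  shp <- dim(arr)[1:3]
  n <- nrow(vox)
  out <- rep(NA_real_, n)
  inside <- vox[, 1] >= 0 & vox[, 1] <= shp[1] - 1 &
    vox[, 2] >= 0 & vox[, 2] <= shp[2] - 1 &
    vox[, 3] >= 0 & vox[, 3] <= shp[3] - 1
  if (!any(inside)) return(out)
  v <- vox[inside, , drop = FALSE]
  i0 <- pmin(floor(v), matrix(shp - 2, nrow(v), 3, byrow = TRUE))
  i0 <- pmax(i0, 0)
  f <- v - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    idx <- cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz) + 1L
    acc <- acc + w * arr[idx]
  }
  out[inside] <- acc
  out
}

apply_field <- function(field, geometry, points) {
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1, 3) else points
  vox <- world_to_voxel(geometry, p)
  out <- matrix(NA_real_, nrow(p), 3)
  for (c in 1:3)
    out[, c] <- interp_trilinear(field[, , , c], vox)
  if (anyNA(out))
    sa_abort("sa_out_of_field",
             sprintf("%d point(s) outside the deformation-field grid",
                     sum(!stats::complete.cases(out))))
  if (single) as.numeric(out) else out
}

#' Carry points from one referential to another
#'
#' Resolves the transform chain with [resolve_path()] and applies each
#' step: affine steps exactly, deformation-field steps by trilinear
#' interpolation of the field at the current position (converted to field
#' voxel coordinates through the field's geometry).
#'
#' @param tg a [transformation_graph()].
#' @param points mm triple or n x 3 matrix, in `source` coordinates.
#' @param source,target referential names.
#' @return The points expressed in `target` coordinates, same shape.
#' @export
map_point <- function(tg, points, source, target) {
  path <- resolve_path(tg, source, target)
  if (is.null(path))
    sa_abort("sa_unreachable",
             sprintf("no transform path from '%s' to '%s'", source, target))
  for (step in path) {
    if (step$kind == "affine") {
      m <- if (step$direction == "inverse") solve(step$matrix) else step$matrix
      points <- apply_affine(m, points)
    } else {
      points <- apply_field(step$field, step$geometry, points)
    }
  }
  points
}

#' Map a whole mesh into another referential
#'
#' Applies [map_point()] to every vertex; the triangle list is unchanged.
#'
#' @param tg a [transformation_graph()].
#' @param mesh a [triangle_mesh()] with vertices in `source` coordinates.
#' @param source,target referential names.
#' @return A [triangle_mesh()] in `target` coordinates.
#' @export
map_mesh <- function(tg, mesh, source, target) {
  triangle_mesh(map_point(tg, mesh$vertices, source, target),
                mesh$triangles)
}
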