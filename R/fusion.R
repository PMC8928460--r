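#' Scalar volume container
#'
#' A 3D (or 4D, with time as the fourth axis) scalar image together with
#' its grid geometry.
#'
#' @param data 3D or 4D numeric array.
#' @param geometry a [volume_geometry()] matching the first three axes.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, geometry) {
  nd <- length(dim(data))
  sa_check(nd %in% c(3L, 4L), "sa_invalid_volume",
           "volume data must be a 3D or 4D array")
  sa_check(all(dim(data)[1:3] == geometry$shape), "sa_invalid_volume",
           "data dimensions do not match the geometry's shape")
  structure(list(data = data, geometry = geometry), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume %s>\n", paste(dim(x$data), collapse = "x")))
  invisible(x)
}

#' Sample a volume onto mesh vertices (texture fusion)
#'
#' The fusion that paints an activation (or any scalar) volume onto a
#' cortical surface: each mesh vertex is carried into the volume's
#' referential through the transformation graph, converted to voxel
#' coordinates through the volume's geometry, and the volume is
#' interpolated there. Vertices falling outside the volume grid receive
#' the `background` value.
#'
#' @param volume a [scalar_volume()].
#' @param mesh a [triangle_mesh()].
#' @param tg optional [transformation_graph()]; `NULL` means mesh and
#'   volume already share a referential.
#' @param mesh_ref,volume_ref referential names (used when `tg` is given).
#' @param background value assigned to out-of-volume vertices (default 0).
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @param time_index 1-based frame selector for 4D volumes.
#' @return A `vertex_texture`: list with `values` (one per vertex) and
#'   `background`.
#' @export
sample_volume_on_mesh <- function(volume, mesh, tg = NULL, mesh_ref = NULL,
                                  volume_ref = NULL, background = 0,
                                  interpolation = c("trilinear", "nearest"),
                                  time_index = 1L) {
  interpolation <- match.arg(interpolation)
  arr <- volume$data
  if (length(dim(arr)) == 4L) {
    sa_check(time_index >= 1L && time_index <= dim(arr)[4],
             "sa_not_found", "time_index outside the 4D volume")
    arr <- arr[, , , time_index, drop = TRUE]
    dim(arr) <- volume$geometry$shape
  }
  pts <- mesh$vertices
  if (!is.null(tg))
    pts <- map_point(tg, pts, mesh_ref, volume_ref)
  vox <- world_to_voxel(volume$geometry, pts)
  vals <- if (interpolation == "trilinear") interp_trilinear(arr, vox)
  else {
    shp <- volume$geometry$shape
    r <- round(vox)
    inside <- r[, 1] >= 0 & r[, 1] < shp[1] & r[, 2] >= 0 & r[, 2] < shp[2] &
      r[, 3] >= 0 & r[, 3] < shp[3]
    out <- rep(NA_real_, nrow(r))
    out[inside] <- arr[r[inside, , drop = FALSE] + 1L]
    out
  }
  vals[is.na(vals)] <- background
  structure(list(values = vals, background = background),
            class = "vertex_texture")
}

#' Intersect a triangle mesh with a plane
#'
#' Computes the intersection contour of a mesh and the plane
#' `normal . x = offset` — the fusion drawn when a surface is displayed
#' over a slice plane. Each triangle crossing the plane contributes one
#' segment; segments sharing an endpoint (within `merge_tol` mm) are
#' chained into polylines, and chains that come back to their start are
#' closed explicitly (first point repeated at the end). Vertices lying
#' exactly on the plane count as being on the positive side, so the
#' degenerate touching cases are handled deterministically.
#'
#' @param mesh a [triangle_mesh()].
#' @param normal plane normal (non-zero triple; need not be unit).
#' @param offset plane offset: the plane is `{x : <normal, x> = offset}`.
#' @param merge_tol endpoint-merging tolerance in mm (default 1e-9).
#' @return A `plane_polylines` object: list with `normal`, `offset`, and
#'   `polylines` (possibly empty list of k x 3 point matrices).
#' @export
mesh_plane_intersection <- function(mesh, normal, offset, merge_tol = 1e-9) {
  normal <- as.numeric(normal)
  sa_check(sqrt(sum(normal^2)) > 0, "sa_invalid_plane",
           "plane normal must be non-zero")
  v <- mesh$vertices
  d <- as.numeric(v %*% normal) - offset
  pos <- d >= 0  # on-plane vertices count as positive side
  segs <- list()
  for (i in seq_len(nrow(mesh$triangles))) {
    tri <- mesh$triangles[i, ]
    s <- pos[tri]
    if (all(s) || !any(s)) next
    pts <- matrix(0, 0, 3)
    eps <- rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
    for (e in seq_len(3)) {
      a <- eps[e, 1]; b <- eps[e, 2]
      if (pos[a] == pos[b]) next
      t <- d[a] / (d[a] - d[b])
      pts <- rbind(pts, v[a, ] + t * (v[b, ] - v[a, ]))
    }
    if (nrow(pts) == 2) segs[[length(segs) + 1L]] <- pts
  }
  polylines <- chain_segments(segs, merge_tol)
  structure(list(normal = normal, offset = offset, polylines = polylines),
            class = "plane_polylines")
}

# Chain 2-point segments into polylines by matching endpoints within tol.
chain_segments <- function(segs, tol) {
  out <- list()
  used <- rep(FALSE, length(segs))
  near <- function(p, q) sqrt(sum((p - q)^2)) <= tol
  for (i in seq_along(segs)) {
    if (used[i]) next
    used[i] <- TRUE
    chain <- segs[[i]]
    repeat {
      extended <- FALSE
      tail_pt <- chain[nrow(chain), ]
      head_pt <- chain[1, ]
      for (j in seq_along(segs)) {
        if (used[j]) next
        s <- segs[[j]]
        if (near(s[1, ], tail_pt)) {
          chain <- rbind(chain, s[2, ]); used[j] <- TRUE; extended <- TRUE
        } else if (near(s[2, ], tail_pt)) {
          chain <- rbind(chain, s[1, ]); used[j] <- TRUE; extended <- TRUE
        } else if (near(s[1, ], head_pt)) {
          chain <- rbind(s[2, , drop = FALSE], chain); used[j] <- TRUE
          extended <- TRUE
        } else if (near(s[2, ], head_pt)) {
          chain <- rbind(s[1, , drop = FALSE], chain); used[j] <- TRUE
          extended <- TRUE
        }
        if (extended) break
      }
      if (!extended) break
    }
    # close loops explicitly
    if (nrow(chain) > 2 &&
        sqrt(sum((chain[1, ] - chain[nrow(chain), ])^2)) <= tol)
      chain[nrow(chain), ] <- chain[1, ]
    out[[length(out) + 1L]] <- unname(chain)
  }
  out
}

#' Total length of intersection polylines
#'
#' @param polylines a `plane_polylines` object.
#' @return Summed segment lengths in mm.
#' @export
polyline_length <- function(polylines) {
  sum(vapply(polylines$polylines, function(p) {
    if (nrow(p) < 2) return(0)
    sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  }, numeric(1)))
}
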