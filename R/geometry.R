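#' Volume geometry: grid shape, voxel size and voxel-to-world mapping
#'
#' A `volume_geometry` ties a discrete voxel grid to physical space. Voxel
#' indices are 0-based integer triples; `voxel_to_world` is a 4x4 homogeneous
#' matrix mapping the index \code{(i, j, k, 1)} to millimetre coordinates,
#' following the usual qform/sform convention of NIfTI-1. Every voxel-based
#' structure representation carries one of these, so each dataset lives in
#' its own native coordinate system.
#'
#' @param shape integer triple, voxels per axis (all >= 1).
#' @param voxel_size positive real triple, voxel edge lengths in mm.
#' @param voxel_to_world 4x4 homogeneous matrix (voxel index -> world mm).
#'   Defaults to a diagonal scaling by `voxel_size`.
#' @return An object of class `volume_geometry`.
#' @examples
#' g <- volume_geometry(c(128, 128, 128), c(1, 1, 1))
#' voxel_to_world(g, c(10, 20, 30))
#' @export
volume_geometry <- function(shape, voxel_size = c(1, 1, 1),
                            voxel_to_world = NULL) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  sa_check(length(shape) == 3 && all(shape >= 1L),
           "sa_invalid_geometry", "shape must be 3 integers >= 1")
  sa_check(length(voxel_size) == 3 && all(voxel_size > 0),
           "sa_invalid_geometry", "voxel_size must be 3 positive reals")
  if (is.null(voxel_to_world)) {
    voxel_to_world <- diag(c(voxel_size, 1))
  }
  voxel_to_world <- unname(as.matrix(voxel_to_world))
  sa_check(all(dim(voxel_to_world) == c(4, 4)),
           "sa_invalid_geometry", "voxel_to_world must be 4x4")
  sa_check(isTRUE(all.equal(voxel_to_world[4, ], c(0, 0, 0, 1))),
           "sa_invalid_geometry", "last row of voxel_to_world must be (0,0,0,1)")
  det3 <- det(voxel_to_world[1:3, 1:3])
  sa_check(is.finite(det3) && abs(det3) > 1e-12,
           "sa_invalid_geometry", "upper-left 3x3 block must be invertible")
  structure(list(shape = shape, voxel_size = voxel_size,
                 voxel_to_world = voxel_to_world),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf("<volume_geometry %dx%dx%d, voxel %.3gx%.3gx%.3g mm>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Convert between voxel indices and world coordinates
#'
#' `voxel_to_world()` maps (possibly fractional) 0-based voxel coordinates to
#' world mm; `world_to_voxel()` is its inverse. Both accept a single triple
#' or an n x 3 matrix and return the same shape.
#'
#' @param geometry a [volume_geometry()].
#' @param points numeric triple or n x 3 matrix.
#' @return Coordinates in the target space, same shape as `points`.
#' @export
voxel_to_world <- function(geometry, points) {
  apply_affine(geometry$voxel_to_world, points)
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(geometry, points) {
  apply_affine(solve(geometry$voxel_to_world), points)
}

# Apply a 4x4 homogeneous matrix to a point triple or n x 3 matrix.
apply_affine <- function(mat, points) {
  single <- is.null(dim(points))
  p <- if (single) matrix(as.numeric(points), 1, 3) else
    matrix(as.numeric(points), nrow = nrow(points), ncol = 3)
  out <- p %*% t(mat[1:3, 1:3]) +
    matrix(mat[1:3, 4], nrow(p), 3, byrow = TRUE)
  if (single) as.numeric(out) else out
}

geometry_equal <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size - b$voxel_size)) <= tol &&
    max(abs(a$voxel_to_world - b$voxel_to_world)) <= tol
}
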