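#' Triangle mesh in world coordinates
#'
#' @param vertices n x 3 numeric matrix of vertex positions (world mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices. Each
#'   triangle must reference three distinct existing vertices.
#' @return An object of class `triangle_mesh`.
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    rbind(c(1, 2, 3)))
#' @export
triangle_mesh <- function(vertices, triangles) {
  v <- matrix(as.numeric(vertices), ncol = 3)
  t <- matrix(as.integer(triangles), ncol = 3)
  sa_check(nrow(t) == 0L || (min(t) >= 1L && max(t) <= nrow(v)),
           "sa_invalid_mesh", "triangle index out of range")
  degen <- t[, 1] == t[, 2] | t[, 1] == t[, 3] | t[, 2] == t[, 3]
  sa_check(!any(degen), "sa_invalid_mesh",
           "degenerate triangle (repeated vertex index)")
  structure(list(vertices = v, triangles = t), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d triangles>\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

mesh_equal <- function(a, b, tol = 1e-9) {
  nrow(a$vertices) == nrow(b$vertices) &&
    nrow(a$triangles) == nrow(b$triangles) &&
    (nrow(a$vertices) == 0L || max(abs(a$vertices - b$vertices)) <= tol) &&
    identical(a$triangles, b$triangles)
}

#' Axis-aligned unit cube test mesh
#'
#' Twelve triangles over the cube `[0,1]^3`; handy for exercising
#' mesh--plane intersections and volume sampling.
#'
#' @param origin corner of the cube (default the world origin).
#' @param size edge length in mm.
#' @return A [triangle_mesh()].
#' @export
cube_mesh <- function(origin = c(0, 0, 0), size = 1) {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)) * size
  v <- v + matrix(origin, 8, 3, byrow = TRUE)
  # vertex numbering from expand.grid: x fastest
  quads <- rbind(
    c(1, 2, 4, 3),  # z = 0
    c(5, 7, 8, 6),  # z = 1
    c(1, 5, 6, 2),  # y = 0
    c(3, 4, 8, 7),  # y = 1
    c(1, 3, 7, 5),  # x = 0
    c(2, 6, 8, 4))  # x = 1
  tr <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  triangle_mesh(v, tr)
}
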