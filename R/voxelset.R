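#' Voxel-set representation of a cortical fold
#'
#' A fold is stored as the set of voxels of its "negative cast": the
#' cerebrospinal-fluid-filled ribbon that moulds the fold, extracted as a
#' thin voxel surface. The set must be non-empty, lie inside its grid and
#' form a single 26-connected component (one fold is one connected piece).
#'
#' @param voxels n x 3 integer matrix of 0-based voxel indices (rows may be
#'   in any order; duplicates are removed).
#' @param geometry the [volume_geometry()] the indices refer to.
#' @param check validate bounds and connectivity (default TRUE). Internal
#'   callers that construct sets known to be valid may skip the check.
#' @return An object of class `voxel_surface_set`.
#' @export
voxel_surface_set <- function(voxels, geometry, check = TRUE) {
  v <- matrix(as.integer(voxels), ncol = 3)
  v <- unique(v)
  if (check) {
    sa_check(nrow(v) >= 1, "sa_invalid_voxel_set", "voxel set is empty")
    inb <- v[, 1] >= 0L & v[, 2] >= 0L & v[, 3] >= 0L &
      v[, 1] < geometry$shape[1] & v[, 2] < geometry$shape[2] &
      v[, 3] < geometry$shape[3]
    sa_check(all(inb), "sa_invalid_voxel_set",
             "voxel indices outside the volume grid")
    comp <- voxel_components(v)
    sa_check(max(comp) == 1L, "sa_invalid_voxel_set",
             "voxel set is not a single 26-connected component")
  }
  structure(list(voxels = v, geometry = geometry),
            class = "voxel_surface_set")
}

#' @export
print.voxel_surface_set <- function(x, ...) {
  cat(sprintf("<voxel_surface_set: %d voxels>\n", nrow(x$voxels)))
  invisible(x)
}

# 26-neighbourhood offsets (3^3 - 1 rows).
.offsets26 <- local({
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0L, , drop = FALSE]
})

# Collision-free linear key for voxel triples (shifted to be non-negative).
voxel_keys <- function(v, origin, span) {
  (v[, 1] - origin[1]) +
    span[1] * ((v[, 2] - origin[2]) + span[2] * (v[, 3] - origin[3]))
}

# Label 26-connected components of an n x 3 voxel index matrix.
# Returns an integer vector of component ids (1-based), in input row order.
# Plain frontier-expansion BFS, vectorised over the whole frontier.
voxel_components <- function(v) {
  n <- nrow(v)
  if (n == 0L) return(integer(0))
  origin <- c(min(v[, 1]), min(v[, 2]), min(v[, 3])) - 2L
  span <- c(max(v[, 1]), max(v[, 2]), max(v[, 3])) - origin + 3L
  keys <- voxel_keys(v, origin, span)
  ord <- order(keys)
  skeys <- keys[ord]
  comp <- integer(n)
  cur <- 0L
  for (seed in seq_len(n)) {
    if (comp[seed] != 0L) next
    cur <- cur + 1L
    comp[seed] <- cur
    frontier <- seed
    while (length(frontier) > 0L) {
      f <- v[frontier, , drop = FALSE]
      nb <- f[rep(seq_len(nrow(f)), each = 26L), , drop = FALSE] +
        .offsets26[rep(seq_len(26L), nrow(f)), , drop = FALSE]
      nkeys <- voxel_keys(nb, origin, span)
      fi <- findInterval(nkeys, skeys)
      valid <- fi > 0L & skeys[pmax(fi, 1L)] == nkeys
      hit <- ord[fi[valid]]
      hit <- unique(hit[comp[hit] == 0L])
      comp[hit] <- cur
      frontier <- hit
    }
  }
  comp
}

# findInterval returns 0 for keys below the range; guard wrapper used above
# relies on pmax + key re-check, so no further handling needed here.

# Shortest 26-connected path inside a voxel set between two member rows.
# Returns row indices of the path including both endpoints, or NULL if
# disconnected. Deterministic: neighbours discovered in sorted key order.
voxel_shortest_path <- function(v, from_row, to_row) {
  n <- nrow(v)
  origin <- c(min(v[, 1]), min(v[, 2]), min(v[, 3])) - 2L
  span <- c(max(v[, 1]), max(v[, 2]), max(v[, 3])) - origin + 3L
  keys <- voxel_keys(v, origin, span)
  ord <- order(keys)
  skeys <- keys[ord]
  parent <- integer(n)
  parent[from_row] <- -1L
  frontier <- from_row
  while (length(frontier) > 0L && parent[to_row] == 0L) {
    f <- v[frontier, , drop = FALSE]
    src <- rep(frontier, each = 26L)
    nb <- f[rep(seq_len(nrow(f)), each = 26L), , drop = FALSE] +
      .offsets26[rep(seq_len(26L), nrow(f)), , drop = FALSE]
    nkeys <- voxel_keys(nb, origin, span)
    fi <- findInterval(nkeys, skeys)
    valid <- fi > 0L & skeys[pmax(fi, 1L)] == nkeys
    hit <- ord[fi[valid]]; src <- src[valid]
    new <- parent[hit] == 0L & hit != from_row
    hit <- hit[new]; src <- src[new]
    first <- !duplicated(hit)
    hit <- hit[first]; src <- src[first]
    parent[hit] <- src
    frontier <- hit
  }
  if (parent[to_row] == 0L && to_row != from_row) return(NULL)
  path <- to_row
  while (path[1] != from_row) path <- c(parent[path[1]], path)
  path
}

# Membership test: which rows of `query` (n x 3) are present in set `v`.
voxel_member <- function(query, v) {
  all_v <- rbind(v, query)
  origin <- c(min(all_v[, 1]), min(all_v[, 2]), min(all_v[, 3])) - 2L
  span <- c(max(all_v[, 1]), max(all_v[, 2]), max(all_v[, 3])) - origin + 3L
  keys <- voxel_keys(v, origin, span)
  qkeys <- voxel_keys(query, origin, span)
  qkeys %in% keys
}

# Minimum Euclidean distance (mm) between two voxel sets, computed on voxel
# centre world coordinates. Bounding boxes are intersected (with a margin)
# first so only nearby voxels enter the pairwise computation; `upper` is the
# distance beyond which the exact value is not needed (Inf is returned).
voxel_set_min_distance <- function(a, b, geometry, upper = Inf) {
  if (is.finite(upper)) {
    margin <- ceiling(upper / min(geometry$voxel_size)) + 1L
    lo <- pmax(apply(a, 2, min), apply(b, 2, min)) - margin
    hi <- pmin(apply(a, 2, max), apply(b, 2, max)) + margin
    if (any(lo > hi + 2L * margin)) return(Inf)
    keep_a <- a[, 1] >= lo[1] & a[, 1] <= hi[1] & a[, 2] >= lo[2] &
      a[, 2] <= hi[2] & a[, 3] >= lo[3] & a[, 3] <= hi[3]
    keep_b <- b[, 1] >= lo[1] & b[, 1] <= hi[1] & b[, 2] >= lo[2] &
      b[, 2] <= hi[2] & b[, 3] >= lo[3] & b[, 3] <= hi[3]
    a <- a[keep_a, , drop = FALSE]
    b <- b[keep_b, , drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  }
  pa <- voxel_to_world(geometry, a)
  pb <- voxel_to_world(geometry, b)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * (pa %*% t(pb))
  sqrt(max(0, min(d2)))
}

# Minimum Chebyshev distance in voxel index units (0 = shared voxel,
# 1 = 26-adjacent). Same bounding-box prefilter as above.
voxel_set_chebyshev <- function(a, b, upper = Inf) {
  if (is.finite(upper)) {
    margin <- as.integer(upper) + 1L
    lo <- pmax(apply(a, 2, min), apply(b, 2, min)) - margin
    hi <- pmin(apply(a, 2, max), apply(b, 2, max)) + margin
    keep_a <- a[, 1] >= lo[1] & a[, 1] <= hi[1] & a[, 2] >= lo[2] &
      a[, 2] <= hi[2] & a[, 3] >= lo[3] & a[, 3] <= hi[3]
    keep_b <- b[, 1] >= lo[1] & b[, 1] <= hi[1] & b[, 2] >= lo[2] &
      b[, 2] <= hi[2] & b[, 3] >= lo[3] & b[, 3] <= hi[3]
    a <- a[keep_a, , drop = FALSE]
    b <- b[keep_b, , drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  }
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- pmax(abs(b[, 1] - a[i, 1]), abs(b[, 2] - a[i, 2]),
              abs(b[, 3] - a[i, 3]))
    best <- min(best, min(d))
    if (best == 0) break
  }
  best
}

# Bounding box of a voxel set: 2 x 3 matrix (min row, max row).
voxel_bbox <- function(v) {
  rbind(c(min(v[, 1]), min(v[, 2]), min(v[, 3])),
        c(max(v[, 1]), max(v[, 2]), max(v[, 3])))
}
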