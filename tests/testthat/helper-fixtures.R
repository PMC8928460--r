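# Shared fixture builders. Everything is generated in code from explicit
# seeds; nothing is read from disk.

# A flat one-voxel-thick ribbon fold: length `len` along x, depth along z,
# at y = y0, on a 1 mm isotropic grid.
ribbon_fold <- function(len = 20, depth = 10, y0 = 20,
                        geometry = volume_geometry(c(64, 64, 64))) {
  generate_fold(rbind(c(10, y0, 0), c(10 + len, y0, 0)), depth,
                jitter = 0, geometry = geometry)
}

ribbon_graph <- function(...) {
  g <- structural_graph("rib", referential_id = "rib_native")
  add_node(g, structure_node(1L, label = "S.Fr.1",
                             voxel_rep = ribbon_fold(...)))
}

# Random affine with a well-conditioned linear part.
random_affine <- function() {
  m <- diag(4)
  m[1:3, 1:3] <- matrix(stats::rnorm(9, sd = 0.3), 3, 3) + diag(3)
  m[1:3, 4] <- stats::rnorm(3, sd = 10)
  m
}

# Random nomenclature tree with n entries and occasional colors.
random_nomenclature <- function(n = 50) {
  make_entry <- function(name, depth) {
    n_children <- if (depth >= 3) 0 else stats::rpois(1, 1.2)
    kids <- list()
    for (i in seq_len(n_children)) {
      nm <- sprintf("%s.%d", name, i)
      kids[[i]] <- make_entry(nm, depth + 1)
    }
    color <- if (stats::runif(1) < 0.4)
      as.integer(floor(stats::runif(3, 0, 256))) else NULL
    nomenclature_entry(name, color = color, children = kids)
  }
  root <- nomenclature_entry("root", children = lapply(seq_len(n), function(i)
    make_entry(sprintf("e%d", i), 1)))
  nomenclature(root)
}

# Random transformation graph over <= n_refs referentials with n_edges
# affine edges (guaranteed connected is NOT required).
random_transform_graph <- function(n_refs = 6, n_edges = 8) {
  refs <- paste0("R", seq_len(n_refs))
  tg <- transformation_graph()
  for (r in refs) tg <- add_referential(tg, r)
  for (i in seq_len(n_edges)) {
    ends <- sample(refs, 2)
    tg <- add_affine(tg, ends[1], ends[2], random_affine())
  }
  tg
}

# Independent path-enumeration oracle over a transformation graph:
# depth-first enumeration of all simple paths up to `max_len` edges,
# honouring field directedness. Returns a list of paths; each path is a
# data frame (kind, index, direction).
enumerate_paths <- function(tg, source, target, max_len = 4) {
  edges <- list()
  for (i in seq_along(tg$affines)) {
    a <- tg$affines[[i]]
    edges[[length(edges) + 1]] <- list(from = a$source, to = a$target,
                                       kind = "affine", index = i,
                                       direction = "forward")
    edges[[length(edges) + 1]] <- list(from = a$target, to = a$source,
                                       kind = "affine", index = i,
                                       direction = "inverse")
  }
  for (i in seq_along(tg$fields)) {
    f <- tg$fields[[i]]
    edges[[length(edges) + 1]] <- list(from = f$source, to = f$target,
                                       kind = "field", index = i,
                                       direction = "forward")
  }
  out <- list()
  walk <- function(at, visited, acc) {
    if (length(acc) > max_len) return()
    if (at == target && length(acc) > 0) {
      out[[length(out) + 1]] <<- acc
      return()
    }
    for (e in edges) {
      if (e$from != at || e$to %in% visited) next
      walk(e$to, c(visited, e$to), c(acc, list(e)))
    }
  }
  if (source == target) return(list(list()))
  walk(source, source, list())
  out
}

apply_affine_points <- function(m, pts) {
  t(m[1:3, 1:3] %*% t(pts) + m[1:3, 4])
}

# Among all enumerated shortest paths, the one whose traversed ref_id
# sequence is lexicographically smallest (the package's declared
# tie-break), reconstructed independently from the enumeration.
oracle_best_path <- function(tg, source, target, max_len = 5) {
  paths <- enumerate_paths(tg, source, target, max_len)
  if (length(paths) == 0) return(NULL)
  lens <- lengths(paths)
  shortest <- paths[lens == min(lens)]
  keys <- vapply(shortest, function(p)
    paste(vapply(p, function(e) e$to, character(1)), collapse = "\xff"),
    character(1))
  shortest[[order(keys)[1]]]
}

# Compose an enumerated affine-only oracle path into a matrix using a
# naive triple-loop matrix product (independent of compose_affine_path).
oracle_compose <- function(tg, path) {
  out <- diag(4)
  for (e in path) {
    m <- tg$affines[[e$index]]$matrix
    if (e$direction == "inverse") m <- solve(m)
    prod <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) for (k in 1:4)
      prod[i, j] <- prod[i, j] + m[i, k] * out[k, j]
    out <- prod
  }
  out
}

# Deformation field realizing a known affine: every voxel stores the
# affine image of its own world position.
make_affine_field <- function(mat, geo) {
  idx <- as.matrix(expand.grid(0:(geo$shape[1] - 1), 0:(geo$shape[2] - 1),
                               0:(geo$shape[3] - 1)))
  w <- voxel_to_world(geo, idx)
  tgt <- apply_affine_points(mat, w)
  fld <- array(0, c(geo$shape, 3))
  for (c in 1:3) {
    a <- array(0, geo$shape)
    a[idx + 1L] <- tgt[, c]
    fld[, , , c] <- a
  }
  fld
}

# Brute-force 26-connected component labeling by repeated sweeps —
# independent of the package's BFS implementation.
brute_components <- function(v) {
  n <- nrow(v)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      adj <- abs(v[, 1] - v[i, 1]) <= 1 & abs(v[, 2] - v[i, 2]) <= 1 &
        abs(v[, 3] - v[i, 3]) <= 1
      mn <- min(lab[adj])
      if (any(lab[adj] != mn)) {
        lab[adj] <- mn
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, sort(unique(lab)))
}

# Small generator config for fast tests.
small_config <- function(seed = 1, n_subjects = 1, folds = 24, ...) {
  generator_config(seed = seed, n_subjects = n_subjects,
                   folds_per_subject = folds,
                   volume_shape = c(72L, 72L, 72L), ...)
}
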