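#' Configuration for the synthetic sulcal-graph generator
#'
#' The generator emulates, at desk scale, the variability a fold-extraction
#' pipeline produces on real hemispheres: a nominal sulcus may appear as a
#' single long fold, be interrupted into several pieces (optionally with
#' parallel overlapping segments), carry small or long side branches at
#' shifted positions, lose a part, or (as an annotation stressor) be absent
#' from a subject altogether. Folds are parametric ribbons — a curve swept
#' along a depth direction — rasterized into the voxel grid as one-voxel-
#' thick 26-connected sheets, an idealization of the "negative cast" voxel
#' representation of a real fold.
#'
#' @param seed integer RNG seed; every downstream quantity is a pure
#'   function of it.
#' @param n_subjects number of subjects to generate.
#' @param folds_per_subject nominal number of fold sites per subject
#'   (default 300, the typical fold count of one hemisphere); events may
#'   raise or lower the realized node count.
#' @param volume_shape voxel grid per subject (default 128^3).
#' @param voxel_size mm per voxel (default 1 mm isotropic).
#' @param nomenclature optional [nomenclature()]; defaults to a synthetic
#'   tree with one leaf per fold site ([synthetic_nomenclature()]).
#' @param variability named list of event probabilities in `[0, 1]`:
#'   `interruption`, `parallel_overlap` (conditional on interruption),
#'   `small_branch`, `long_branch`, `missing_part`, `dropout`.
#' @param jitter_sd geometric jitter of fold placement, mm (default 1).
#' @param proximity_threshold distance under which two non-touching folds
#'   get a proximity edge, mm (default 3).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_subjects = 1L,
                             folds_per_subject = 300L,
                             volume_shape = c(128L, 128L, 128L),
                             voxel_size = c(1, 1, 1),
                             nomenclature = NULL,
                             variability = list(),
                             jitter_sd = 1,
                             proximity_threshold = 3) {
  defaults <- list(interruption = 0.15, parallel_overlap = 0.5,
                   small_branch = 0.15, long_branch = 0.1,
                   missing_part = 0.1, dropout = 0)
  for (nm in names(variability)) {
    sa_check(nm %in% names(defaults), "sa_invalid_config",
             sprintf("unknown variability event '%s'", nm))
    p <- variability[[nm]]
    sa_check(is.numeric(p) && p >= 0 && p <= 1, "sa_invalid_config",
             sprintf("probability for '%s' must be in [0,1]", nm))
    defaults[[nm]] <- p
  }
  sa_check(n_subjects >= 0, "sa_invalid_config", "n_subjects must be >= 0")
  sa_check(folds_per_subject >= 1, "sa_invalid_config",
           "folds_per_subject must be >= 1")
  if (is.null(nomenclature))
    nomenclature <- synthetic_nomenclature(folds_per_subject)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 folds_per_subject = as.integer(folds_per_subject),
                 volume_shape = as.integer(volume_shape),
                 voxel_size = as.numeric(voxel_size),
                 nomenclature = nomenclature,
                 variability = defaults,
                 jitter_sd = jitter_sd,
                 proximity_threshold = proximity_threshold),
            class = "generator_config")
}

#' Synthetic hierarchical nomenclature
#'
#' Builds a three-level tree (brain > lobes > sulcus leaves) with
#' `n_labels` leaves named `S.<lobe>.<index>`. Lobes carry colours; every
#' third leaf has its own colour, the rest inherit, which exercises colour
#' resolution in context.
#'
#' @param n_labels number of leaf entries.
#' @return A [nomenclature()].
#' @export
synthetic_nomenclature <- function(n_labels = 300L) {
  lobes <- c("Fr", "Par", "Temp", "Occ", "Limb", "Ins")
  lobe_colors <- rbind(c(220, 60, 60), c(60, 160, 220), c(80, 200, 120),
                       c(230, 200, 60), c(170, 100, 220), c(240, 140, 60))
  kids <- lapply(seq_along(lobes), function(i) {
    leaf_idx <- if (i > n_labels) integer(0)
    else seq(i, n_labels, by = length(lobes))
    leaves <- lapply(seq_along(leaf_idx), function(j) {
      own <- if (leaf_idx[j] %% 3L == 0L)
        ((lobe_colors[i, ] + leaf_idx[j] * 7L) %% 256L) else NULL
      nomenclature_entry(sprintf("S.%s.%d", lobes[i], j), color = own)
    })
    nomenclature_entry(paste0("lobe.", lobes[i]), color = lobe_colors[i, ],
                       children = leaves)
  })
  kids <- kids[vapply(kids, function(k) length(k$children) > 0, logical(1))]
  nomenclature(nomenclature_entry("brain", children = kids))
}

leaf_names <- function(entry) {
  if (length(entry$children) == 0L) return(entry$name)
  unlist(lapply(entry$children, leaf_names), use.names = FALSE)
}

#' Rasterize one synthetic fold
#'
#' Sweeps a template curve along a depth direction and rasterizes the
#' resulting ribbon into the voxel grid: a point lands in the voxel whose
#' index is the floor of its continuous voxel coordinate. Sampling is
#' dense enough (0.35 voxel steps) that the result is always a single
#' 26-connected sheet. With `jitter > 0` a smooth sinusoidal lateral
#' displacement (amplitude capped at 2 mm, drawn from the current RNG
#' state) bends the ribbon.
#'
#' @param template_curve k x 3 matrix of mm points (k >= 2, non-zero
#'   length).
#' @param depth sweep extent along `depth_dir`, mm (> 0).
#' @param jitter lateral jitter amplitude scale, mm.
#' @param geometry target [volume_geometry()].
#' @param depth_dir unit sweep direction (default +z).
#' @return A [voxel_surface_set()]; points falling outside the grid are
#'   clamped to its boundary.
#' @export
generate_fold <- function(template_curve, depth, jitter = 0,
                          geometry = volume_geometry(c(128, 128, 128)),
                          depth_dir = c(0, 0, 1)) {
  crv <- matrix(as.numeric(template_curve), ncol = 3)
  sa_check(is.finite(depth) && depth > 0, "sa_degenerate_input",
           "depth must be > 0")
  seg <- diff(crv)
  seglen <- sqrt(rowSums(seg^2))
  L <- sum(seglen)
  sa_check(nrow(crv) >= 2 && L > 0, "sa_degenerate_input",
           "template curve must have positive length")
  step <- 0.35 * min(geometry$voxel_size)
  ns <- max(2L, ceiling(L / step))
  s <- (seq_len(ns) - 0.5) * L / ns
  cum <- c(0, cumsum(seglen))
  si <- findInterval(s, cum, rightmost.closed = TRUE)
  si <- pmin(si, nrow(seg))
  t_in_seg <- (s - cum[si]) / seglen[si]
  pts <- crv[si, , drop = FALSE] + seg[si, , drop = FALSE] * t_in_seg

  depth_dir <- depth_dir / sqrt(sum(depth_dir^2))
  if (jitter > 0) {
    # fixed spatial wavelength (not relative to curve length) keeps the
    # lateral slope small enough that rasterized samples stay 26-adjacent
    # even on short branch curves
    amp <- min(abs(stats::rnorm(1, 0, jitter)), 2)
    wavelength <- stats::runif(1, 15, 40)
    phase <- stats::runif(1, 0, 2 * pi)
    tangent <- colSums(seg)
    tangent <- tangent / sqrt(sum(tangent^2))
    lat <- c(tangent[2] * depth_dir[3] - tangent[3] * depth_dir[2],
             tangent[3] * depth_dir[1] - tangent[1] * depth_dir[3],
             tangent[1] * depth_dir[2] - tangent[2] * depth_dir[1])
    nl <- sqrt(sum(lat^2))
    if (nl > 1e-9) {
      lat <- lat / nl
      off <- amp * sin(2 * pi * s / wavelength + phase)
      pts <- pts + outer(off, lat)
    }
  }

  nt <- max(1L, ceiling(depth / step))
  t <- (seq_len(nt) - 0.5) * depth / nt
  all_pts <- pts[rep(seq_len(ns), nt), , drop = FALSE] +
    outer(rep(t, each = ns), depth_dir)
  vox <- floor(world_to_voxel(geometry, all_pts))
  for (c in 1:3) {
    vox[, c] <- pmax(0, pmin(geometry$shape[c] - 1L, vox[, c]))
  }
  voxel_surface_set(unique(vox), geometry, check = FALSE)
}

# Draw the variability events for one fold site.
draw_events <- function(p) {
  ev <- character(0)
  if (stats::runif(1) < p$dropout) return("dropout")
  if (stats::runif(1) < p$interruption) {
    ev <- c(ev, "interruption")
    if (stats::runif(1) < p$parallel_overlap) ev <- c(ev, "parallel_overlap")
  }
  if (stats::runif(1) < p$small_branch) ev <- c(ev, "small_branch")
  if (stats::runif(1) < p$long_branch) ev <- c(ev, "long_branch")
  if (stats::runif(1) < p$missing_part) ev <- c(ev, "missing_part")
  ev
}

# Curve pieces realizing a configuration: list of k x 3 matrices (mm).
site_curves <- function(center, u, L, events) {
  lat <- c(-u[2], u[1], 0)
  a <- center - u * L / 2
  b <- center + u * L / 2
  pieces <- list()
  if ("missing_part" %in% events) b <- a + u * L * stats::runif(1, 0.5, 0.7)
  if ("interruption" %in% events) {
    cutpos <- stats::runif(1, 0.35, 0.65)
    gap <- stats::runif(1, 1.5, 3)
    m1 <- a + u * (sum((b - a) * u) * cutpos - gap / 2)
    m2 <- a + u * (sum((b - a) * u) * cutpos + gap / 2)
    pieces <- c(pieces, list(rbind(a, m1)))
    second <- rbind(m2, b)
    if ("parallel_overlap" %in% events) {
      shift <- lat * stats::runif(1, 2, 3.5)
      overlap <- u * stats::runif(1, 2, 4)
      second <- rbind(m2 - overlap + shift, b + shift)
    }
    pieces <- c(pieces, list(second))
  } else {
    pieces <- c(pieces, list(rbind(a, b)))
  }
  if ("small_branch" %in% events) {
    at <- a + u * sum((b - a) * u) * stats::runif(1, 0.2, 0.8)
    dir <- u * cos(pi / 3) + lat * sin(pi / 3) * sample(c(-1, 1), 1)
    pieces <- c(pieces, list(rbind(at, at + dir * stats::runif(1, 3, 6))))
  }
  if ("long_branch" %in% events) {
    at <- a + u * sum((b - a) * u) * stats::runif(1, 0.3, 0.7) +
      lat * stats::runif(1, 3, 5)
    dir <- u * cos(pi / 4) + lat * sin(pi / 4) * sample(c(-1, 1), 1)
    pieces <- c(pieces, list(rbind(at, at + dir * stats::runif(1, 8, 13))))
  }
  pieces
}

#' Generate one subject's structural graph
#'
#' Lays one fold site per nomenclature leaf on a jittered 3D grid inside
#' the volume, draws the variability configuration of each site, rasterizes
#' the resulting fold pieces, then derives topographic edges: a junction
#' where two folds touch (26-adjacent voxel sets), a proximity edge where
#' the minimum inter-fold distance is below the configured threshold.
#'
#' @param config a [generator_config()].
#' @param subject_index 1-based index; the subject's RNG substream is
#'   derived from `config$seed` and this index, so subjects are
#'   reproducible independently of generation order.
#' @return List with `graph` (a labeled [structural_graph()]), `labels`
#'   (data frame `node_id`, `label` — the ground truth), and `events`
#'   (data frame `label`, `event`).
#' @export
generate_subject <- function(config, subject_index = 1L) {
  sid <- sprintf("sub-%03d", subject_index)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed((config$seed + 104729L * as.integer(subject_index)) %%
             2147483647L)

  geo <- volume_geometry(config$volume_shape, config$voxel_size)
  graph <- structural_graph(sid, hemisphere = "left",
                            referential_id = paste0(sid, "_native"))
  labels <- leaf_names(config$nomenclature$root)
  n_sites <- min(config$folds_per_subject, length(labels))
  labels <- labels[seq_len(n_sites)]

  # jittered grid of site centres, with a margin so folds stay in-volume
  extent <- config$volume_shape * config$voxel_size
  per_axis <- ceiling(n_sites^(1 / 3))
  margin <- 0.12 * extent
  cell <- (extent - 2 * margin) / per_axis
  grid_idx <- as.matrix(expand.grid(x = seq_len(per_axis),
                                    y = seq_len(per_axis),
                                    z = seq_len(per_axis)))[seq_len(n_sites), ,
                                                            drop = FALSE]
  Lbase <- 0.8 * min(cell[1], cell[2])
  Dbase <- 0.6 * cell[3]

  gt <- list(); evlog <- list()
  nid <- 1L
  for (i in seq_len(n_sites)) {
    center <- margin + (grid_idx[i, ] - 0.5) * cell +
      stats::rnorm(3, 0, config$jitter_sd)
    theta <- (i * 2.399963) %% (2 * pi) + stats::rnorm(1, 0, 0.2)
    u <- c(cos(theta), sin(theta), 0)
    L <- Lbase * stats::runif(1, 0.8, 1.2)
    depth <- Dbase * stats::runif(1, 0.7, 1.3)
    events <- draw_events(config$variability)
    for (e in events)
      evlog[[length(evlog) + 1L]] <- data.frame(label = labels[i], event = e,
                                                stringsAsFactors = FALSE)
    if (identical(events, "dropout")) next
    for (crv in site_curves(center, u, L, events)) {
      vs <- generate_fold(crv, depth, jitter = config$jitter_sd,
                          geometry = geo)
      graph <- add_node(graph, structure_node(nid, label = labels[i],
                                              voxel_rep = vs))
      gt[[length(gt) + 1L]] <- data.frame(node_id = nid, label = labels[i],
                                          stringsAsFactors = FALSE)
      nid <- nid + 1L
    }
  }
  graph <- derive_topography_edges(graph, config$proximity_threshold)
  list(graph = graph,
       labels = if (length(gt)) do.call(rbind, gt) else
         data.frame(node_id = integer(0), label = character(0)),
       events = if (length(evlog)) do.call(rbind, evlog) else
         data.frame(label = character(0), event = character(0)))
}

#' Derive junction and proximity edges from fold geometry
#'
#' Adds a junction edge between every pair of nodes whose voxel sets touch
#' (minimum Chebyshev index distance <= 1, i.e. 26-adjacent or sharing a
#' voxel) and a proximity edge between pairs within `threshold` mm that do
#' not touch. Existing edges are replaced. Candidate pairs are prefiltered
#' by dilated bounding-box overlap.
#'
#' @param graph a [structural_graph()] whose nodes have voxel
#'   representations.
#' @param threshold proximity distance, mm.
#' @return The graph with freshly derived edges.
#' @export
derive_topography_edges <- function(graph, threshold = 3) {
  graph$edges <- list()
  keys <- names(graph$nodes)
  n <- length(keys)
  if (n < 2L) return(graph)
  geo <- graph_geometry(graph)
  boxes <- lapply(graph$nodes, function(nd) voxel_bbox(nd$voxel_rep$voxels))
  dil <- ceiling(threshold / min(geo$voxel_size)) + 1L
  lo <- t(vapply(boxes, function(b) b[1, ], numeric(3))) - dil
  hi <- t(vapply(boxes, function(b) b[2, ], numeric(3))) + dil
  eid <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (any(pmax(lo[i, ], lo[j, ]) > pmin(hi[i, ], hi[j, ]))) next
      vi <- graph$nodes[[keys[i]]]$voxel_rep$voxels
      vj <- graph$nodes[[keys[j]]]$voxel_rep$voxels
      cheb <- voxel_set_chebyshev(vi, vj, upper = 1)
      kind <- if (is.finite(cheb) && cheb <= 1) "junction"
      else {
        d <- voxel_set_min_distance(vi, vj, geo, upper = threshold)
        if (is.finite(d) && d <= threshold) "proximity" else NA_character_
      }
      if (is.na(kind)) next
      graph <- add_edge(graph, structure_edge(
        eid, kind, c(graph$nodes[[keys[i]]]$node_id,
                     graph$nodes[[keys[j]]]$node_id)))
      eid <- eid + 1L
    }
  }
  graph
}

#' Generate a whole cohort with ground truth
#'
#' Produces `config$n_subjects` independent subjects (each from its own
#' seed-derived RNG substream) under the shared nomenclature, plus a
#' ground-truth manifest recording every node's true label and every
#' injected variability event — the reference that downstream selection
#' and consistency checks are validated against.
#'
#' @param config a [generator_config()].
#' @return List with `cohort` (a [cohort()]) and `manifest` (list with
#'   data frames `labels`: subject, node_id, label; `events`: subject,
#'   label, event).
#' @export
generate_cohort <- function(config) {
  graphs <- list(); lab <- list(); ev <- list()
  for (i in seq_len(config$n_subjects)) {
    subj <- generate_subject(config, i)
    graphs[[i]] <- subj$graph
    if (nrow(subj$labels))
      lab[[i]] <- cbind(subject = subj$graph$subject_id, subj$labels,
                        stringsAsFactors = FALSE)
    if (nrow(subj$events))
      ev[[i]] <- cbind(subject = subj$graph$subject_id, subj$events,
                       stringsAsFactors = FALSE)
  }
  empty_lab <- data.frame(subject = character(0), node_id = integer(0),
                          label = character(0))
  empty_ev <- data.frame(subject = character(0), label = character(0),
                         event = character(0))
  list(cohort = cohort(graphs, config$nomenclature),
       manifest = list(
         labels = if (length(lab)) do.call(rbind, lab) else empty_lab,
         events = if (length(ev)) do.call(rbind, ev) else empty_ev))
}
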