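#' Read and write structural graphs (".sgraph.json")
#'
#' The on-disk dialect is a single JSON object with sorted keys and
#' fixed float formatting, so writing the same graph twice gives the same
#' bytes. Voxel sets are stored as sorted 0-based index triples; meshes
#' either inline (`vertices` + 0-based `triangles`) or by reference to an
#' OBJ or GIFTI file (`obj_file` / `gifti_file`, relative to the graph
#' file). `write_graph()` always writes voxel sets and meshes inline.
#'
#' @param graph a [structural_graph()].
#' @param path file path.
#' @return `write_graph()` returns `path` invisibly; `read_graph()`
#'   returns the graph.
#' @export
write_graph <- function(graph, path) {
  geo <- graph_geometry(graph)
  nodes <- graph$nodes[order(vapply(graph$nodes, function(n) n$node_id,
                                    integer(1)))]
  edges <- graph$edges[order(vapply(graph$edges, function(e) e$edge_id,
                                    integer(1)))]
  node_json <- lapply(nodes, function(n) {
    vox <- NULL
    if (!is.null(n$voxel_rep)) {
      v <- n$voxel_rep$voxels
      v <- v[order(v[, 1], v[, 2], v[, 3]), , drop = FALSE]
      vox <- v
    }
    mesh <- NULL
    if (!is.null(n$mesh))
      mesh <- jobj(list(vertices = n$mesh$vertices,
                        triangles = n$mesh$triangles - 1L))
    jobj(list(node_id = n$node_id, label = n$label,
              properties = jobj(as.list(n$properties)),
              voxels = vox, mesh = mesh))
  })
  edge_json <- lapply(edges, function(e)
    jobj(list(edge_id = e$edge_id, kind = e$kind,
              endpoints = sort(e$endpoints),
              properties = jobj(as.list(e$properties)))))
  geo_json <- if (is.null(geo)) NULL else
    jobj(list(shape = geo$shape, voxel_size = geo$voxel_size,
              voxel_to_world = geo$voxel_to_world))
  doc <- jobj(list(
    format = "sgraph.json", version = "1.0",
    subject_id = graph$subject_id, hemisphere = graph$hemisphere,
    referential_id = graph$referential_id,
    metadata = jobj(graph$metadata),
    geometry = geo_json,
    nodes = jarr(unname(node_json)),
    edges = jarr(unname(edge_json))))
  invisible(write_canonical_json(doc, path))
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  doc <- read_json_checked(path, "sgraph.json")
  geo <- NULL
  if (!is.null(doc$geometry)) {
    g <- doc$geometry
    geo <- volume_geometry(int_vec(jfield(g, "shape", path)),
                           num_vec(jfield(g, "voxel_size", path)),
                           num_mat(jfield(g, "voxel_to_world", path)))
  }
  graph <- structural_graph(
    as.character(jfield(doc, "subject_id", path)),
    hemisphere = as.character(jfield(doc, "hemisphere", path)),
    referential_id = as.character(jfield(doc, "referential_id", path)),
    metadata = if (is.null(doc$metadata)) list() else doc$metadata)
  for (nj in doc$nodes) {
    vox <- NULL
    if (!is.null(nj$voxels)) {
      if (is.null(geo))
        sa_abort("sa_parse_error",
                 sprintf("%s: voxel sets present but no geometry", path))
      m <- num_mat(nj$voxels)
      vox <- voxel_surface_set(m, geo, check = FALSE)
    }
    mesh <- read_mesh_field(nj$mesh, dirname(path), path)
    props <- unlist(nj$properties)
    if (is.null(props)) props <- numeric(0)
    graph <- add_node(graph, structure_node(
      as.integer(jfield(nj, "node_id", path)),
      label = as.character(jfield(nj, "label", path)),
      voxel_rep = vox, mesh = mesh, properties = props))
  }
  for (ej in doc$edges) {
    graph <- add_edge(graph, structure_edge(
      as.integer(jfield(ej, "edge_id", path)),
      kind = as.character(jfield(ej, "kind", path)),
      endpoints = int_vec(jfield(ej, "endpoints", path)),
      properties = if (is.null(unlist(ej$properties))) numeric(0)
      else unlist(ej$properties)))
  }
  graph
}

read_mesh_field <- function(mj, dir, path) {
  if (is.null(mj)) return(NULL)
  if (!is.null(mj$obj_file))
    return(read_obj(file.path(dir, mj$obj_file)))
  if (!is.null(mj$gifti_file))
    return(read_gifti_mesh(file.path(dir, mj$gifti_file)))
  triangle_mesh(num_mat(jfield(mj, "vertices", path)),
                num_mat(jfield(mj, "triangles", path)) + 1L)
}

#' Structural equality of two graphs
#'
#' Deep comparison used for round-trip checks: voxel sets compared as
#' sets, reals to `tol`.
#'
#' @param a,b [structural_graph()] objects.
#' @param tol numeric tolerance (default 1e-9).
#' @return TRUE or FALSE.
#' @export
graph_equal <- function(a, b, tol = 1e-9) {
  if (!identical(a$subject_id, b$subject_id) ||
      !identical(a$hemisphere, b$hemisphere) ||
      !identical(a$referential_id, b$referential_id) ||
      length(a$nodes) != length(b$nodes) ||
      length(a$edges) != length(b$edges)) return(FALSE)
  for (key in names(a$nodes)) {
    na <- a$nodes[[key]]; nb <- b$nodes[[key]]
    if (is.null(nb) || na$label != nb$label) return(FALSE)
    if (xor(is.null(na$voxel_rep), is.null(nb$voxel_rep))) return(FALSE)
    if (!is.null(na$voxel_rep)) {
      va <- na$voxel_rep$voxels; vb <- nb$voxel_rep$voxels
      if (nrow(va) != nrow(vb)) return(FALSE)
      va <- va[order(va[, 1], va[, 2], va[, 3]), , drop = FALSE]
      vb <- vb[order(vb[, 1], vb[, 2], vb[, 3]), , drop = FALSE]
      if (!identical(va, vb)) return(FALSE)
      if (!geometry_equal(na$voxel_rep$geometry, nb$voxel_rep$geometry, tol))
        return(FALSE)
    }
    if (xor(is.null(na$mesh), is.null(nb$mesh))) return(FALSE)
    if (!is.null(na$mesh) && !mesh_equal(na$mesh, nb$mesh, tol)) return(FALSE)
    pa <- na$properties; pb <- nb$properties
    if (length(pa) != length(pb)) return(FALSE)
    if (length(pa) > 0) {
      if (!setequal(names(pa), names(pb))) return(FALSE)
      if (max(abs(pa[names(pb)] - pb)) > tol) return(FALSE)
    }
  }
  for (key in names(a$edges)) {
    ea <- a$edges[[key]]; eb <- b$edges[[key]]
    if (is.null(eb) || ea$kind != eb$kind ||
        !setequal(ea$endpoints, eb$endpoints)) return(FALSE)
  }
  TRUE
}
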