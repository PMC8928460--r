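#' Read and write Wavefront OBJ meshes
#'
#' Minimal OBJ subset: `v` vertex lines and `f` face lines (triangles;
#' `a/b/c` attribute syntax is accepted, only the vertex index is used).
#' The writer emits a version comment, vertices at 17 significant digits,
#' and nothing else, so output is deterministic.
#'
#' @param mesh a [triangle_mesh()].
#' @param path file path.
#' @return `write_obj()` returns `path` invisibly; `read_obj()` returns a
#'   [triangle_mesh()].
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c("# structatlas obj 1.0",
             sprintf("v %s %s %s",
                     format_num(mesh$vertices[, 1]),
                     format_num(mesh$vertices[, 2]),
                     format_num(mesh$vertices[, 3])),
             sprintf("f %d %d %d", mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 3]))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  if (!file.exists(path))
    sa_abort("sa_missing_file", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  parse_nums <- function(l, what) {
    toks <- strsplit(trimws(sub("^[vf] +", "", l)), "[ \t]+")
    out <- lapply(seq_along(toks), function(i) {
      tk <- toks[[i]]
      if (what == "f") tk <- sub("/.*$", "", tk)
      vals <- suppressWarnings(as.numeric(tk))
      if (length(vals) < 3 || anyNA(vals[1:3]))
        sa_abort("sa_parse_error",
                 sprintf("%s: malformed %s line: '%s'", path, what, l[i]))
      vals[1:3]
    })
    do.call(rbind, out)
  }
  if (length(vlines) == 0)
    sa_abort("sa_parse_error", sprintf("%s: no vertices", path))
  v <- parse_nums(vlines, "v")
  t <- if (length(flines)) parse_nums(flines, "f") else matrix(integer(0), 0, 3)
  triangle_mesh(v, t)
}

# Deterministic minimal GIFTI writer: ASCII-encoded data arrays.
gifti_header <- paste0(
  "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
  "<!DOCTYPE GIFTI SYSTEM \"http://www.nitrc.org/frs/download.php/115/gifti.dtd\">\n")

gifti_data_array <- function(intent, dtype, dims, values, fmt) {
  dimattrs <- paste(sprintf("Dim%d=\"%d\"", seq_along(dims) - 1L, dims),
                    collapse = " ")
  paste0("<DataArray Intent=\"", intent, "\" DataType=\"", dtype,
         "\" ArrayIndexingOrder=\"RowMajorOrder\" Dimensionality=\"",
         length(dims), "\" ", dimattrs,
         " Encoding=\"ASCII\" Endian=\"LittleEndian\">\n<Data>",
         paste(fmt(values), collapse = " "),
         "</Data>\n</DataArray>\n")
}

#' Read and write GIFTI surface and texture files
#'
#' Minimal GIFTI-1 support sufficient for exchange of triangle meshes
#' (POINTSET + TRIANGLE data arrays) and per-vertex scalar textures, with
#' ASCII data encoding. Triangle indices are 0-based on disk, per the
#' format, and converted to this package's 1-based convention in memory.
#'
#' @param mesh a [triangle_mesh()].
#' @param path `.gii` file path.
#' @return Writers return `path` invisibly; `read_gifti_mesh()` returns a
#'   [triangle_mesh()], `read_gifti_texture()` a numeric vector.
#' @export
write_gifti_mesh <- function(mesh, path) {
  vt <- t(mesh$vertices)  # row-major per-vertex triples
  tt <- t(mesh$triangles - 1L)
  xml <- paste0(
    gifti_header,
    "<GIFTI Version=\"1.0\" NumberOfDataArrays=\"2\">\n",
    gifti_data_array("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT64",
                     c(nrow(mesh$vertices), 3L), as.numeric(vt), format_num),
    gifti_data_array("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                     c(nrow(mesh$triangles), 3L), as.integer(tt),
                     as.character),
    "</GIFTI>\n")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(xml, con, sep = "", useBytes = TRUE)
  invisible(path)
}

read_gifti_arrays <- function(path) {
  if (!file.exists(path))
    sa_abort("sa_missing_file", sprintf("file not found: %s", path))
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    sa_abort("sa_parse_error",
             sprintf("cannot parse GIFTI %s: %s", path, conditionMessage(e))))
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  lapply(arrays, function(a) {
    enc <- xml2::xml_attr(a, "Encoding")
    if (!identical(enc, "ASCII"))
      sa_abort("sa_parse_error",
               sprintf("%s: unsupported GIFTI encoding '%s' (ASCII only)",
                       path, enc))
    dims <- integer(0)
    nd <- as.integer(xml2::xml_attr(a, "Dimensionality"))
    for (d in seq_len(nd) - 1L)
      dims <- c(dims, as.integer(xml2::xml_attr(a, paste0("Dim", d))))
    vals <- as.numeric(strsplit(trimws(
      xml2::xml_text(xml2::xml_find_first(a, ".//Data"))), "[ \t\n]+")[[1]])
    list(intent = xml2::xml_attr(a, "Intent"), dims = dims, values = vals)
  })
}

#' @rdname write_gifti_mesh
#' @export
read_gifti_mesh <- function(path) {
  arrays <- read_gifti_arrays(path)
  pts <- NULL; tri <- NULL
  for (a in arrays) {
    if (a$intent == "NIFTI_INTENT_POINTSET")
      pts <- matrix(a$values, ncol = 3, byrow = TRUE)
    if (a$intent == "NIFTI_INTENT_TRIANGLE")
      tri <- matrix(as.integer(a$values), ncol = 3, byrow = TRUE) + 1L
  }
  if (is.null(pts) || is.null(tri))
    sa_abort("sa_parse_error",
             sprintf("%s: missing POINTSET or TRIANGLE array", path))
  triangle_mesh(pts, tri)
}

#' @rdname write_gifti_mesh
#' @param values numeric vector, one value per mesh vertex.
#' @export
write_gifti_texture <- function(values, path) {
  xml <- paste0(
    gifti_header,
    "<GIFTI Version=\"1.0\" NumberOfDataArrays=\"1\">\n",
    gifti_data_array("NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT64",
                     length(values), as.numeric(values), format_num),
    "</GIFTI>\n")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(xml, con, sep = "", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_gifti_mesh
#' @export
read_gifti_texture <- function(path) {
  arrays <- read_gifti_arrays(path)
  if (length(arrays) == 0)
    sa_abort("sa_parse_error", sprintf("%s: no data arrays", path))
  arrays[[1]]$values
}
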