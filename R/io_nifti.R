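#' Read and write scalar volumes as NIfTI-1
#'
#' The voxel-to-world mapping is taken from the file's sform (preferred)
#' or qform; a file carrying neither is rejected rather than silently
#' assuming an orientation. Written files always carry an sform.
#'
#' @param volume a [scalar_volume()].
#' @param path `.nii` or `.nii.gz` path.
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a [scalar_volume()].
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::sform(img) <- structure(volume$geometry$voxel_to_world, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    sa_abort("sa_missing_file", sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    sa_abort("sa_parse_error",
             sprintf("cannot read NIfTI %s: %s", path, conditionMessage(e))))
  xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
  if (is.null(attr(xf, "code")) || attr(xf, "code") == 0L)
    sa_abort("sa_parse_error",
             sprintf("%s carries neither sform nor qform; orientation is ambiguous",
                     path))
  arr <- as.array(img)
  shp <- dim(arr)[1:3]
  mat <- matrix(as.numeric(xf), 4, 4)
  vsz <- sqrt(colSums(mat[1:3, 1:3]^2))
  geo <- volume_geometry(shp, vsz, mat)
  scalar_volume(arr, geo)
}

#' Read and write deformation fields as vector NIfTI volumes
#'
#' A deformation field is stored as a 4D NIfTI with a 3-length last axis:
#' voxel `(i, j, k)` holds a mm coordinate triple. Two storage conventions
#' exist in the wild; `convention = "absolute"` (this library's native
#' one) stores the target-space position itself, while
#' `convention = "displacement"` stores the offset from the voxel's own
#' world position — displacement files are converted to absolute form on
#' load.
#'
#' @param field `shape x 3` array of mm coordinates (absolute convention).
#' @param geometry source-space [volume_geometry()] of the field grid.
#' @param path `.nii` or `.nii.gz` path.
#' @return `write_deformation_field()` returns `path` invisibly;
#'   `read_deformation_field()` returns a list with `field` (absolute
#'   convention) and `geometry`.
#' @export
write_deformation_field <- function(field, geometry, path) {
  sa_check(length(dim(field)) == 4 && dim(field)[4] == 3,
           "sa_invalid_transform", "field must be 4D with 3 components")
  img <- RNifti::asNifti(field)
  RNifti::sform(img) <- structure(geometry$voxel_to_world, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_deformation_field
#' @param convention `"absolute"` or `"displacement"`.
#' @export
read_deformation_field <- function(path, convention = c("absolute",
                                                        "displacement")) {
  convention <- match.arg(convention)
  vol <- read_volume(path)
  arr <- vol$data
  if (length(dim(arr)) != 4 || dim(arr)[4] != 3)
    sa_abort("sa_parse_error",
             sprintf("%s is not a 3-component vector volume", path))
  geo <- vol$geometry
  if (convention == "displacement") {
    idx <- as.matrix(expand.grid(i = 0:(geo$shape[1] - 1),
                                 j = 0:(geo$shape[2] - 1),
                                 k = 0:(geo$shape[3] - 1)))
    world <- voxel_to_world(geo, idx)
    for (c in 1:3) {
      w <- array(0, geo$shape)
      w[idx + 1L] <- world[, c]
      arr[, , , c] <- arr[, , , c] + w
    }
  }
  list(field = arr, geometry = geo)
}

#' Read and write plain-text 4x4 affine transforms
#'
#' Four whitespace-separated numbers per line, four lines; lines starting
#' with `#` are comments (the writer records a format/version comment).
#'
#' @param matrix 4x4 homogeneous matrix.
#' @param path file path.
#' @return `write_affine()` returns `path` invisibly; `read_affine()`
#'   returns the 4x4 matrix.
#' @export
write_affine <- function(matrix, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c("# structatlas affine 1.0",
             vapply(1:4, function(i)
               paste(format_num(matrix[i, ]), collapse = " "), character(1)))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  if (!file.exists(path))
    sa_abort("sa_missing_file", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) != 4)
    sa_abort("sa_parse_error",
             sprintf("%s: expected 4 data lines, found %d", path,
                     length(lines)))
  rows <- lapply(seq_along(lines), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(lines[i], "[ \t]+")[[1]]))
    if (length(vals) != 4 || anyNA(vals))
      sa_abort("sa_parse_error",
               sprintf("%s: line %d is not 4 numbers", path, i))
    vals
  })
  do.call(rbind, rows)
}

#' Write a transformation graph to disk
#'
#' Writes every affine as a plain-text file and every deformation field as
#' a vector NIfTI, plus a JSON manifest listing
#' `{source, target, kind, file}` records, so the whole graph reloads with
#' [read_transform_manifest()].
#'
#' @param tg a [transformation_graph()].
#' @param dir output directory (created if needed).
#' @param name manifest file name.
#' @return Path of the manifest, invisibly.
#' @export
write_transform_graph <- function(tg, dir, name = "transforms.json") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- list()
  for (i in seq_along(tg$affines)) {
    a <- tg$affines[[i]]
    fn <- sprintf("affine_%03d.txt", i)
    write_affine(a$matrix, file.path(dir, fn))
    records[[length(records) + 1L]] <-
      jobj(list(source = a$source, target = a$target, kind = "affine",
                file = fn))
  }
  for (i in seq_along(tg$fields)) {
    f <- tg$fields[[i]]
    fn <- sprintf("field_%03d.nii.gz", i)
    write_deformation_field(f$field, f$geometry, file.path(dir, fn))
    records[[length(records) + 1L]] <-
      jobj(list(source = f$source, target = f$target, kind = "field",
                file = fn, convention = "absolute"))
  }
  doc <- jobj(list(format = "transform_manifest.json", version = "1.0",
                   referentials = sort(tg$referentials),
                   transforms = jarr(records)))
  invisible(write_canonical_json(doc, file.path(dir, name)))
}

#' Load a transformation graph from a manifest
#'
#' @param path manifest JSON path; transform files are resolved relative
#'   to it. A record whose file is missing raises an error naming the
#'   path.
#' @param tg optional existing [transformation_graph()] to extend.
#' @return A [transformation_graph()].
#' @export
read_transform_manifest <- function(path, tg = transformation_graph()) {
  doc <- read_json_checked(path, "transform_manifest.json")
  dir <- dirname(path)
  for (r in doc$referentials)
    tg <- add_referential(tg, as.character(r))
  for (rec in doc$transforms) {
    fn <- file.path(dir, jfield(rec, "file", path))
    if (!file.exists(fn))
      sa_abort("sa_missing_file",
               sprintf("manifest %s references missing file %s", path, fn))
    kind <- jfield(rec, "kind", path)
    src <- as.character(jfield(rec, "source", path))
    tgt <- as.character(jfield(rec, "target", path))
    if (kind == "affine") {
      tg <- add_affine(tg, src, tgt, read_affine(fn))
    } else if (kind == "field") {
      conv <- if (is.null(rec$convention)) "absolute" else rec$convention
      fld <- read_deformation_field(fn, convention = conv)
      tg <- add_deformation_field(tg, src, tgt, fld$field, fld$geometry)
    } else {
      sa_abort("sa_parse_error",
               sprintf("%s: unknown transform kind '%s'", path, kind))
    }
  }
  tg
}
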