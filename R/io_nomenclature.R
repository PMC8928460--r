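#' Read and write nomenclatures (".nom.json")
#'
#' Nested-object dialect: each entry is `{name, color?, children[]}`;
#' the file carries a format marker and version. Duplicate names anywhere
#' in the tree are a parse error (they would make label resolution
#' ambiguous).
#'
#' @param nom a [nomenclature()].
#' @param path file path.
#' @return `write_nomenclature()` returns `path` invisibly;
#'   `read_nomenclature()` returns the nomenclature.
#' @export
write_nomenclature <- function(nom, path) {
  entry_json <- function(e) {
    jobj(list(name = e$name,
              color = if (is.null(e$color)) NULL else e$color,
              children = jarr(unname(lapply(e$children, entry_json)))))
  }
  doc <- jobj(list(format = "nom.json", version = nom$version,
                   root = entry_json(nom$root)))
  invisible(write_canonical_json(doc, path))
}

#' @rdname write_nomenclature
#' @export
read_nomenclature <- function(path) {
  doc <- read_json_checked(path, "nom.json")
  parse_entry <- function(ej) {
    nomenclature_entry(
      as.character(jfield(ej, "name", path)),
      color = if (is.null(ej$color)) NULL else int_vec(ej$color),
      children = lapply(ej$children, parse_entry))
  }
  root <- parse_entry(jfield(doc, "root", path))
  nms <- entry_names(root)
  dup <- unique(nms[duplicated(nms)])
  if (length(dup) > 0)
    sa_abort("sa_parse_error",
             sprintf("%s: duplicate entry name(s): %s", path,
                     paste(dup, collapse = ", ")))
  nomenclature(root, version = as.character(doc$version))
}

#' Structural equality of two nomenclatures
#'
#' @param a,b [nomenclature()] objects.
#' @return TRUE or FALSE.
#' @export
nomenclature_equal <- function(a, b) {
  eq <- function(x, y) {
    if (x$name != y$name) return(FALSE)
    if (xor(is.null(x$color), is.null(y$color))) return(FALSE)
    if (!is.null(x$color) && !identical(as.integer(x$color),
                                        as.integer(y$color))) return(FALSE)
    if (length(x$children) != length(y$children)) return(FALSE)
    for (i in seq_along(x$children))
      if (!eq(x$children[[i]], y$children[[i]])) return(FALSE)
    TRUE
  }
  eq(a$root, b$root)
}
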