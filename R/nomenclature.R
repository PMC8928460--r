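#' Hierarchical nomenclature of brain structures
#'
#' A nomenclature is a tree in which each entry carries a structure name,
#' an optional display colour, and an ordered list of children — e.g. a
#' lobe entry whose children are the sulci it contains. Names are unique
#' across the whole tree so that a node label resolves to exactly one
#' entry. Colours are inherited: an entry without its own colour takes the
#' nearest coloured ancestor's.
#'
#' @param name entry name (non-empty string).
#' @param color optional RGB triple, integers in `[0, 255]`.
#' @param children list of child `nomenclature_entry` objects.
#' @return `nomenclature_entry()` returns one tree node; `nomenclature()`
#'   wraps a root entry (checking tree-wide name uniqueness) into an object
#'   of class `nomenclature`.
#' @examples
#' nom <- nomenclature(nomenclature_entry("brain", children = list(
#'   nomenclature_entry("frontal", color = c(255, 0, 0), children = list(
#'     nomenclature_entry("S.C."), nomenclature_entry("S.F.sup."))))))
#' nom_contains(nom, "S.C.")
#' resolve_color(nom, "S.C.")   # inherited from "frontal"
#' @export
nomenclature_entry <- function(name, color = NULL, children = list()) {
  sa_check(is.character(name) && length(name) == 1 && nzchar(name),
           "sa_invalid_nomenclature", "entry name must be a non-empty string")
  if (!is.null(color)) {
    color <- as.integer(color)
    sa_check(length(color) == 3 && all(color >= 0L & color <= 255L),
             "sa_invalid_nomenclature", "color must be an RGB triple in [0,255]")
  }
  structure(list(name = name, color = color, children = children),
            class = "nomenclature_entry")
}

#' @rdname nomenclature_entry
#' @param root the root [nomenclature_entry()].
#' @param version free-form version string recorded in files.
#' @export
nomenclature <- function(root, version = "1.0") {
  stopifnot(inherits(root, "nomenclature_entry"))
  all_names <- entry_names(root)
  dup <- unique(all_names[duplicated(all_names)])
  sa_check(length(dup) == 0, "sa_invalid_nomenclature",
           sprintf("duplicate names in nomenclature: %s",
                   paste(dup, collapse = ", ")))
  structure(list(root = root, version = as.character(version)),
            class = "nomenclature")
}

#' @export
print.nomenclature <- function(x, ...) {
  cat(sprintf("<nomenclature v%s: %d entries, root '%s'>\n",
              x$version, length(entry_names(x$root)), x$root$name))
  invisible(x)
}

# Depth-first list of all names under (and including) an entry.
entry_names <- function(entry) {
  c(entry$name, unlist(lapply(entry$children, entry_names), use.names = FALSE))
}

# Path of entries from root to the named entry, or NULL.
entry_path <- function(entry, name) {
  if (entry$name == name) return(list(entry))
  for (ch in entry$children) {
    p <- entry_path(ch, name)
    if (!is.null(p)) return(c(list(entry), p))
  }
  NULL
}

#' Does a name occur in a nomenclature?
#'
#' @param nom a [nomenclature()].
#' @param name structure name to look up.
#' @return `TRUE` iff the name occurs anywhere in the tree.
#' @export
nom_contains <- function(nom, name) {
  !is.null(entry_path(nom$root, name))
}

#' Display colour of a structure, with ancestor inheritance
#'
#' An entry's own colour if set; otherwise the colour of the nearest
#' ancestor that has one; `NULL` when no ancestor up to the root is
#' coloured.
#'
#' @param nom a [nomenclature()].
#' @param name structure name (must occur in the tree).
#' @return Integer RGB triple, or `NULL`.
#' @export
resolve_color <- function(nom, name) {
  path <- entry_path(nom$root, name)
  if (is.null(path))
    sa_abort("sa_not_found", sprintf("name '%s' not in nomenclature", name))
  for (entry in rev(path))
    if (!is.null(entry$color)) return(entry$color)
  NULL
}

#' All names in the subtree rooted at a given entry
#'
#' Selecting a non-leaf structure (say, a sulcus made up of several parts)
#' means selecting every name below it, itself included.
#'
#' @param nom a [nomenclature()].
#' @param name structure name (must occur in the tree).
#' @return Character vector of names, depth-first order.
#' @export
subtree_labels <- function(nom, name) {
  path <- entry_path(nom$root, name)
  if (is.null(path))
    sa_abort("sa_not_found", sprintf("name '%s' not in nomenclature", name))
  entry_names(path[[length(path)]])
}
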