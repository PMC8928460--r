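# Canonical JSON writing: object keys sorted, floats at 17 significant
# digits, no whitespace variation — so the same in-memory object always
# produces byte-identical files. Reading goes through jsonlite.

format_num <- function(x) {
  out <- character(length(x))
  ints <- is.finite(x) & x == floor(x) & abs(x) < 1e15
  out[ints] <- sprintf("%.0f", x[ints])
  out[!ints] <- sprintf("%.17g", x[!ints])
  out
}

jobj <- function(x = list()) structure(x, class = "json_object")
jarr <- function(x = list()) structure(x, class = "json_array")

escape_json <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  s
}

to_canonical_json <- function(x) {
  if (is.null(x)) return("null")
  if (inherits(x, "json_object")) {
    nms <- sort(names(x))
    parts <- vapply(nms, function(nm)
      paste0("\"", escape_json(nm), "\":", to_canonical_json(x[[nm]])),
      character(1))
    return(paste0("{", paste(parts, collapse = ","), "}"))
  }
  if (inherits(x, "json_array")) {
    parts <- vapply(seq_along(x), function(i) to_canonical_json(x[[i]]),
                    character(1))
    return(paste0("[", paste(parts, collapse = ","), "]"))
  }
  if (is.matrix(x)) {
    rows <- vapply(seq_len(nrow(x)), function(i)
      to_canonical_json(x[i, ]), character(1))
    return(paste0("[", paste(rows, collapse = ","), "]"))
  }
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x))))
      return(to_canonical_json(jobj(x)))
    return(to_canonical_json(jarr(x)))
  }
  if (length(x) != 1) {
    parts <- vapply(seq_along(x), function(i) to_canonical_json(x[[i]]),
                    character(1))
    return(paste0("[", paste(parts, collapse = ","), "]"))
  }
  if (is.character(x)) return(paste0("\"", escape_json(x), "\""))
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.integer(x)) return(as.character(x))
  format_num(as.numeric(x))
}

write_canonical_json <- function(x, path) {
  con <- file(path, open = "wb")  # binary: no platform newline translation
  on.exit(close(con))
  writeLines(to_canonical_json(x), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_json_checked <- function(path, expected_format) {
  if (!file.exists(path))
    sa_abort("sa_missing_file", sprintf("file not found: %s", path))
  parsed <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e)
      sa_abort("sa_parse_error",
               sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  if (!is.list(parsed))
    sa_abort("sa_parse_error", sprintf("%s: top level is not an object", path))
  if (!identical(parsed$format, expected_format))
    sa_abort("sa_parse_error",
             sprintf("%s: expected format '%s', found '%s'", path,
                     expected_format,
                     if (is.null(parsed$format)) "<missing>" else parsed$format))
  ver <- parsed$version
  if (is.null(ver))
    sa_abort("sa_parse_error", sprintf("%s: missing version field", path))
  major <- suppressWarnings(as.integer(strsplit(as.character(ver), ".",
                                                fixed = TRUE)[[1]][1]))
  if (is.na(major) || major > 1L)
    sa_abort("sa_unsupported_version",
             sprintf("%s: version %s is newer than this library supports",
                     path, ver))
  parsed
}

# Field access with a parse error naming the missing field.
jfield <- function(obj, name, path) {
  if (is.null(obj[[name]]))
    sa_abort("sa_parse_error",
             sprintf("%s: missing required field '%s'", path, name))
  obj[[name]]
}

num_vec <- function(x) vapply(x, as.numeric, numeric(1))
int_vec <- function(x) vapply(x, function(v) as.integer(v), integer(1))

num_mat <- function(x) {
  if (length(x) == 0) return(matrix(numeric(0), 0, 3))
  do.call(rbind, lapply(x, num_vec))
}
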