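#' Resolve a charset partition definition against an alignment width
#'
#' Parses RAxML-style charset lines of the form
#' `NAME = 1-2008\3` or `NAME = 10-20, 35-40`, where ranges are 1-based
#' inclusive and `\3` keeps every third column starting at the range
#' start (codon-position notation). Single columns (`NAME = 7`) are also
#' accepted. Columns may belong to at most one partition.
#'
#' @param text Character vector of charset lines (or one string with
#'   newlines). Blank lines and `#` comments are ignored.
#' @param width Number of columns in the alignment the scheme refers to.
#' @return A `"partition_scheme"`: a named list of sorted integer column
#'   vectors.
#' @examples
#' resolve_partitions("p3 = 1-6\\3", width = 6)   # columns 1, 4
#' @export
resolve_partitions <- function(text, width) {
  stopifnot(is.numeric(width), width >= 1)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  scheme <- list()
  owner <- integer(width)  # 0 = unassigned, else index of owning partition
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.+'-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3)
      stopf("cannot parse charset line: '%s'", ln)
    name <- m[2]
    if (name %in% names(scheme)) stopf("duplicate partition name: %s", name)
    cols <- integer(0)
    for (piece in trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])) {
      pm <- regmatches(piece,
        regexec("^(\\d+)(?:\\s*-\\s*(\\d+))?(?:\\s*\\\\\\s*(\\d+))?$", piece))[[1]]
      if (length(pm) == 0 || !nzchar(pm[1]))
        stopf("cannot parse charset range '%s' in partition %s", piece, name)
      from <- as.integer(pm[2])
      to <- if (nzchar(pm[3])) as.integer(pm[3]) else from
      stride <- if (nzchar(pm[4])) as.integer(pm[4]) else 1L
      if (from > to) stopf("empty range %d-%d in partition %s", from, to, name)
      if (from < 1 || to > width)
        stopf("partition %s: columns %d-%d outside alignment 1-%d",
              name, from, to, width)
      cols <- c(cols, seq.int(from, to, by = stride))
    }
    cols <- sort(unique(cols))
    clash <- cols[owner[cols] != 0L]
    if (length(clash))
      stopf("column %d assigned to both partition %s and partition %s",
            clash[1], names(scheme)[owner[clash[1]]], name)
    owner[cols] <- length(scheme) + 1L
    scheme[[name]] <- cols
  }
  structure(scheme, width = as.integer(width), class = "partition_scheme")
}

#' Build a partition scheme directly from column index vectors
#' @param ... Named integer vectors of 1-based column indices.
#' @param width Alignment width.
#' @return A `"partition_scheme"`.
#' @export
partition_scheme <- function(..., width) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && is.null(names(parts)))
    parts <- parts[[1]]
  txt <- vapply(names(parts), function(nm)
    paste0(nm, " = ", paste(parts[[nm]], collapse = ", ")), character(1))
  resolve_partitions(paste(txt, collapse = "\n"), width)
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat("Partition scheme over", attr(x, "width"), "columns\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %6d sites\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Number of columns per partition
#' @param scheme A `"partition_scheme"`.
#' @return Named integer vector of partition lengths.
#' @export
partition_lengths <- function(scheme) {
  vapply(scheme, length, integer(1))
}

#' Map every column to its partition name (NA when unassigned)
#' @noRd
partition_of_column <- function(scheme) {
  width <- attr(scheme, "width")
  out <- rep(NA_character_, width)
  for (nm in names(scheme)) out[scheme[[nm]]] <- nm
  out
}

check_scheme_width <- function(scheme, matrix) {
  if (attr(scheme, "width") != ncol(matrix))
    stopf("partition scheme is for width %d but alignment has %d columns",
          attr(scheme, "width"), ncol(matrix))
  invisible(NULL)
}

#' Serialize a partition scheme to charset text
#' @param scheme A `"partition_scheme"`.
#' @return Character vector of `NAME = i, j, ...` lines.
#' @keywords internal
#' @export
format_partitions <- function(scheme) {
  vapply(names(scheme), function(nm) {
    cols <- scheme[[nm]]
    # compress runs (with stride detection for codon partitions)
    if (length(cols) > 2) {
      d <- unique(diff(cols))
      if (length(d) == 1) {
        rng <- if (d == 1) sprintf("%d-%d", cols[1], cols[length(cols)])
               else sprintf("%d-%d\\%d", cols[1], cols[length(cols)], d)
        return(paste0(nm, " = ", rng))
      }
    }
    paste0(nm, " = ", paste(cols, collapse = ", "))
  }, character(1))
}
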