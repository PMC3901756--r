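#' Read an aligned FASTA file into a sequence matrix
#'
#' The alignment is stored as a plain character matrix (taxa in rows,
#' columns are alignment positions, symbols uppercased). Gaps (`-`),
#' unknowns (`?`, `N`) and IUPAC ambiguity codes are preserved but are
#' treated as missing data by every downstream computation.
#'
#' @param path Path to a FASTA file. Records may wrap lines.
#' @return A character matrix with unique row names (taxon labels).
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = FALSE, forceDNAtolower = FALSE,
                             seqtype = "DNA")
  seqs <- lapply(recs, function(s) toupper(as.character(s)))
  labels <- vapply(recs, function(s) attr(s, "name"), character(1))
  as_seq_matrix(seqs, labels)
}

#' @rdname read_fasta
#' @param matrix A character matrix as returned by [read_fasta()].
#' @param width Line-wrap width for sequence lines.
#' @export
write_fasta <- function(matrix, path, width = 80) {
  matrix <- validate_seq_matrix(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(matrix))) {
    writeLines(paste0(">", rownames(matrix)[i]), con)
    s <- paste(matrix[i, ], collapse = "")
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

as_seq_matrix <- function(seqs, labels) {
  if (anyDuplicated(labels))
    stopf("duplicate sequence headers: %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  lens <- lengths(seqs)
  if (length(unique(lens)) > 1)
    stopf("sequences are not aligned: lengths %s",
          paste(sort(unique(lens)), collapse = ", "))
  m <- do.call(rbind, seqs)
  rownames(m) <- unname(labels)
  validate_seq_matrix(m)
}

validate_seq_matrix <- function(m) {
  stopifnot(is.matrix(m), is.character(m))
  if (is.null(rownames(m))) stopf("sequence matrix must have taxon row names")
  m[] <- toupper(m)
  allowed <- c(DNA_BASES, MISSING_SYMBOLS, "U")
  bad <- setdiff(unique(as.vector(m)), allowed)
  if (length(bad))
    stopf("unexpected symbols in alignment: %s", paste(bad, collapse = " "))
  m
}

# Logical matrix marking missing cells (gaps, ?, N, ambiguity codes).
missing_mask <- function(m) {
  matrix(is_missing_symbol(m), nrow = nrow(m), dimnames = dimnames(m))
}
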