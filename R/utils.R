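# Symbols treated as missing in every downstream computation: gaps,
# unknowns and all IUPAC ambiguity codes (a partially known base cannot
# contribute a definite state to rate estimation or p-distances).
MISSING_SYMBOLS <- c("-", "?", "N", "R", "Y", "S", "W", "K", "M",
                     "B", "D", "H", "V", "X", ".")

DNA_BASES <- c("A", "C", "G", "T")

is_missing_symbol <- function(x) toupper(x) %in% MISSING_SYMBOLS

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Write a data frame as TSV with a '#'-prefixed provenance header.
# Numeric columns are formatted at 6 significant digits so output files
# are byte-stable across platforms.
write_report_tsv <- function(df, path, provenance = character()) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(signif(x, 6), format = "g", digits = 6))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance))
    writeLines(paste0("# ", names(provenance), ": ", provenance), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_report_tsv <- function(path) {
  read.delim(path, comment.char = "#", sep = "\t", stringsAsFactors = FALSE)
}
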