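#' Classify one alignment column
#'
#' Missing symbols (gaps, `?`, `N`, ambiguity codes) are ignored. A
#' column is `conserved` when at most one distinct state is present,
#' `parsimony_informative` when at least two states are each present in
#' at least two taxa, and `variable_uninformative` otherwise (variation
#' carried only by singletons). An all-missing column is classified
#' `conserved`; [site_class_summary()] tallies such columns separately.
#'
#' @param column Character vector, one symbol per taxon.
#' @return One of `"conserved"`, `"variable_uninformative"`,
#'   `"parsimony_informative"`.
#' @examples
#' classify_site(c("A", "A", "C", "C"))  # parsimony_informative
#' classify_site(c("A", "A", "A", "C"))  # variable_uninformative
#' @export
classify_site <- function(column) {
  obs <- toupper(column[!is_missing_symbol(column)])
  states <- unique(obs)
  if (length(states) <= 1) return("conserved")
  counts <- table(obs)
  if (sum(counts >= 2) >= 2) "parsimony_informative" else "variable_uninformative"
}

#' Classify every column of an alignment
#' @param matrix Sequence matrix (see [read_fasta()]).
#' @return Character vector of classifications, one per column.
#' @export
classify_sites <- function(matrix) {
  matrix <- validate_seq_matrix(matrix)
  apply(matrix, 2, classify_site)
}

#' Per-partition site-class summary
#'
#' Counts conserved, variable and parsimony-informative columns for each
#' partition. "Variable" includes parsimony-informative sites, so
#' `n_conserved + n_variable = n_sites`; the output header documents
#' this convention. All-missing columns are counted as conserved and
#' also reported in `n_all_missing`.
#'
#' @param matrix Sequence matrix.
#' @param scheme A `"partition_scheme"` resolved against `matrix`.
#' @return A data frame with one row per partition: `partition`,
#'   `n_sites`, `n_conserved`, `n_variable`, `n_parsimony_informative`,
#'   `n_all_missing` and the corresponding proportions.
#' @export
site_class_summary <- function(matrix, scheme) {
  matrix <- validate_seq_matrix(matrix)
  check_scheme_width(scheme, matrix)
  cls <- classify_sites(matrix)
  all_missing <- colSums(!missing_mask(matrix)) == 0
  rows <- lapply(names(scheme), function(nm) {
    cols <- scheme[[nm]]
    if (length(cols) == 0) warnf("partition %s is empty", nm)
    k <- cls[cols]
    n <- length(cols)
    n_cons <- sum(k == "conserved")
    n_pi <- sum(k == "parsimony_informative")
    n_var <- n - n_cons
    data.frame(partition = nm, n_sites = n, n_conserved = n_cons,
               n_variable = n_var, n_parsimony_informative = n_pi,
               n_all_missing = sum(all_missing[cols]),
               prop_conserved = if (n) n_cons / n else NA_real_,
               prop_variable = if (n) n_var / n else NA_real_,
               prop_parsimony_informative = if (n) n_pi / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
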