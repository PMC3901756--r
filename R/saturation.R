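#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing positions among positions where both symbols
#' are non-missing (pairwise deletion). No multiple-hit correction is
#' applied — under saturation the p-distance plateaus near the
#' stationary ceiling (3/4 for equal base frequencies) while the true
#' evolutionary distance keeps growing.
#'
#' @param seq_a,seq_b Character vectors of equal length.
#' @return List with `p` (proportion, `NA` when no positions are
#'   comparable) and `n_compared`.
#' @examples
#' p_distance(c("A","C","G","T"), c("A","C","G","A"))  # p = 0.25
#' @export
p_distance <- function(seq_a, seq_b) {
  if (length(seq_a) != length(seq_b))
    stopf("sequences differ in length (%d vs %d)", length(seq_a), length(seq_b))
  comp <- !is_missing_symbol(seq_a) & !is_missing_symbol(seq_b)
  n <- sum(comp)
  p <- if (n == 0) NA_real_ else mean(toupper(seq_a[comp]) != toupper(seq_b[comp]))
  list(p = p, n_compared = n)
}

#' Substitution-saturation table: p-distances vs patristic distances
#'
#' For every unordered taxon pair and every partition, computes the
#' uncorrected p-distance over the partition's columns and the patristic
#' distance on the reference time tree, plus a per-partition OLS
#' summary (slope, intercept, Pearson r) of p on tree distance.
#' Saturated partitions show a plateau (slope flattening, p near the
#' stationary ceiling) at large tree distances; clock-like unsaturated
#' partitions stay near-linear.
#'
#' @param matrix Sequence matrix; all taxa must be tips of `tree`.
#' @param tree Reference `"phylo"` tree (any tree whose branch lengths
#'   define the comparison distances).
#' @param scheme Optional `"partition_scheme"`; default treats the whole
#'   alignment as one partition `"all"`.
#' @return A list of class `"saturation_table"` with `pairs` (partition,
#'   taxon_a, taxon_b, n_compared, p_distance, tree_distance) and
#'   `summary` (partition, slope, intercept, pearson_r, n_pairs). Pairs
#'   with zero comparable sites are dropped with a warning.
#' @export
saturation_table <- function(matrix, tree, scheme = NULL) {
  matrix <- validate_seq_matrix(matrix)
  missing_taxa <- setdiff(rownames(matrix), tree$tip.label)
  if (length(missing_taxa))
    stopf("alignment taxa not in tree: %s", paste(missing_taxa, collapse = ", "))
  if (is.null(scheme))
    scheme <- resolve_partitions(sprintf("all = 1-%d", ncol(matrix)),
                                 ncol(matrix))
  check_scheme_width(scheme, matrix)
  taxa <- rownames(matrix)
  pm <- patristic_matrix(tree)
  miss <- missing_mask(matrix)
  pair_idx <- utils::combn(length(taxa), 2)
  rows <- list()
  dropped <- 0L
  for (nm in names(scheme)) {
    cols <- scheme[[nm]]
    sub <- matrix[, cols, drop = FALSE]
    submiss <- miss[, cols, drop = FALSE]
    for (k in seq_len(ncol(pair_idx))) {
      i <- pair_idx[1, k]; j <- pair_idx[2, k]
      comp <- !submiss[i, ] & !submiss[j, ]
      n <- sum(comp)
      if (n == 0) { dropped <- dropped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        partition = nm, taxon_a = taxa[i], taxon_b = taxa[j],
        n_compared = n,
        p_distance = mean(sub[i, comp] != sub[j, comp]),
        tree_distance = pm[taxa[i], taxa[j]],
        stringsAsFactors = FALSE)
    }
  }
  if (dropped > 0)
    warnf("%d taxon pair(s) had no comparable sites and were dropped", dropped)
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  summ <- do.call(rbind, lapply(split(pairs, pairs$partition), function(d) {
    fit <- lm(p_distance ~ tree_distance, data = d)
    data.frame(partition = d$partition[1],
               slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               pearson_r = if (nrow(d) > 2) cor(d$p_distance, d$tree_distance)
                           else NA_real_,
               n_pairs = nrow(d), stringsAsFactors = FALSE)
  }))
  summ <- summ[match(names(scheme), summ$partition), ]
  rownames(summ) <- NULL
  structure(list(pairs = pairs, summary = summ), class = "saturation_table")
}

#' @export
print.saturation_table <- function(x, ...) {
  cat("Saturation table:", nrow(x$pairs), "pairs across",
      nrow(x$summary), "partition(s)\n")
  print(x$summary)
  invisible(x)
}
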