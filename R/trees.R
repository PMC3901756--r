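#' Parse a Newick string into a rooted phylogenetic tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is
#' an ape `"phylo"` object with branch lengths interpreted as time in Ma.
#' Unrooted input (a basal multifurcation) is accepted and treated as
#' rooted at that node, with a warning.
#'
#' @param text A Newick string, terminated by `;`.
#' @return An object of class `"phylo"`.
#' @examples
#' tr <- read_newick("((A:2,B:2):3,C:5);")
#' root_age(tr)
#' @seealso [write_newick()], [patristic_distance()], [root_age()]
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  # locate unbalanced parentheses before handing off, so the error can
  # name a character offset
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stopf("unbalanced parentheses in Newick string at offset %d", i)
  }
  if (depth != 0L)
    stopf("unbalanced parentheses in Newick string: %d '(' left open", depth)
  if (!grepl(";\\s*$", text))
    stopf("Newick string must end with ';'")
  # single-tip trees ("A:7;") are valid here but not parseable by ape
  if (!grepl("(", text, fixed = TRUE)) {
    m <- regmatches(text, regexec("^\\s*([^:;,()\\s]+):([0-9.eE+-]+)\\s*;\\s*$",
                                  text))[[1]]
    if (length(m) != 3) stopf("could not parse Newick string")
    tree <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                           edge.length = as.numeric(m[3]),
                           tip.label = m[2], Nnode = 1L),
                      class = "phylo")
    return(tree)
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stopf("could not parse Newick string")
  validate_tree(tree)
}

#' @rdname read_newick
#' @param tree A `"phylo"` tree.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Read/write a Newick tree file
#' @param path File path.
#' @keywords internal
#' @export
read_newick_file <- function(path) {
  read_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate tip labels: %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stopf("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stopf("negative branch lengths are not allowed")
  if (!ape::is.rooted(tree)) {
    warnf("tree has a basal multifurcation; treating it as rooted at that node")
  }
  tree
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths along the tree path between tips `a` and `b`,
#' in Ma. On an ultrametric tree this equals twice the age of the pair's
#' most recent common ancestor.
#'
#' @param tree A `"phylo"` tree.
#' @param a,b Tip labels.
#' @return Distance in Ma (a single number).
#' @examples
#' tr <- read_newick("((A:2,B:2):3,C:5);")
#' patristic_distance(tr, "A", "C")  # 10
#' @export
patristic_distance <- function(tree, a, b) {
  labs <- tree$tip.label
  if (!a %in% labs) stopf("tip label not in tree: %s", a)
  if (!b %in% labs) stopf("tip label not in tree: %s", b)
  if (a == b) return(0)
  pm <- patristic_matrix(tree)
  pm[a, b]
}

#' All pairwise patristic distances
#' @inheritParams patristic_distance
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Root age and ultrametricity of a time tree
#'
#' `root_age()` returns the maximum root-to-tip path length (the age of
#' the root in Ma for an ultrametric tree). `check_ultrametric()` tests
#' whether all root-to-tip paths agree within `tol * root_age`.
#'
#' @param tree A `"phylo"` tree.
#' @param tol Relative tolerance on the spread of root-to-tip depths.
#' @return `root_age()`: a number (Ma). `check_ultrametric()`: logical.
#' @export
root_age <- function(tree) {
  max(tip_depths(tree))
}

#' @rdname root_age
#' @export
check_ultrametric <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  (max(d) - min(d)) <= tol * max(d)
}

tip_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  depths[seq_len(n_tip)]
}

warn_if_not_ultrametric <- function(tree, what) {
  if (!check_ultrametric(tree))
    warnf("%s assumes an ultrametric tree; root-to-tip depths differ", what)
  invisible(NULL)
}
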