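# Independent oracles used across the suite. These deliberately avoid
# the package's own pruning / classification code paths.

# Likelihood of one column by exhaustive enumeration of ancestral state
# assignments at all internal nodes (4^Nnode terms) — tractable for
# trees up to ~6 tips.
brute_force_loglik <- function(tree, column, lambda) {
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  elen <- tree$edge.length
  bases <- c("A", "C", "G", "T")
  tipstate <- function(lab) {
    s <- toupper(column[[lab]])
    if (s %in% bases) match(s, bases) else NA_integer_
  }
  P <- lapply(seq_len(nrow(edge)), function(k) jc_prob(lambda * elen[k]))
  states <- expand.grid(rep(list(1:4), tree$Nnode))
  tot <- 0
  for (r in seq_len(nrow(states))) {
    anc <- as.integer(states[r, ])
    pr <- 0.25
    for (k in seq_len(nrow(edge))) {
      a <- anc[edge[k, 1] - n_tip]
      ch <- edge[k, 2]
      if (ch <= n_tip) {
        st <- tipstate(tree$tip.label[ch])
        pr <- pr * (if (is.na(st)) 1 else P[[k]][a, st])
      } else {
        pr <- pr * P[[k]][a, anc[ch - n_tip]]
      }
    }
    tot <- tot + pr
  }
  log(tot)
}

# Second, independent site classifier: counts via table() logic written
# differently from classify_site().
recount_classes <- function(matrix) {
  missing_set <- c("-", "?", "N", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "X", ".")
  apply(matrix, 2, function(col) {
    col <- toupper(col)
    col <- col[!(col %in% missing_set)]
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) <= 1) return("conserved")
    if (length(tab) >= 2 && tab[2] >= 2) "parsimony_informative"
    else "variable_uninformative"
  })
}

# Shared expensive fixture, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

get_marker_fixture <- function() {
  if (is.null(.fixture_cache$bundle))
    .fixture_cache$bundle <- marker_fixture(seed = 1)
  .fixture_cache$bundle
}

get_marker_fixture_rates <- function() {
  if (is.null(.fixture_cache$rates)) {
    fx <- get_marker_fixture()
    .fixture_cache$rates <- estimate_all_rates(fx$matrix, fx$tree, fx$scheme)
  }
  .fixture_cache$rates
}
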