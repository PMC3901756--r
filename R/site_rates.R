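#' Jukes-Cantor transition probability matrix
#'
#' @param d Expected number of substitutions per site (branch length x
#'   rate); must be non-negative.
#' @return A 4x4 matrix over states A, C, G, T. The diagonal is
#'   `1/4 + 3/4 exp(-4d/3)`, off-diagonals `1/4 - 1/4 exp(-4d/3)`.
#' @examples
#' jc_prob(0)            # identity
#' jc_prob(0.75)[1, 1]   # 0.525911
#' @export
jc_prob <- function(d) {
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 0)
    stopf("d must be a single non-negative number")
  e <- exp(-4 * d / 3)
  P <- matrix((1 - e) / 4, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  diag(P) <- (1 + 3 * e) / 4
  P
}

# --- vectorized Felsenstein pruning under JC69 ------------------------------
#
# make_pruner() precomputes tip partial-likelihood matrices and the
# postorder edge list once, and returns a function mapping a per-site
# rate vector to per-site log-likelihoods in a single vectorized pass.
# Under JC the matrix-vector product P %*% v collapses to
#   e * v + (1 - e)/4 * sum(v),   e = exp(-4 * lambda * t / 3),
# which vectorizes across sites with site-specific lambda. Partial
# likelihoods are rescaled at every internal node to avoid underflow on
# deep trees. Root state frequencies are uniform (1/4).

make_pruner <- function(tree, matrix) {
  n_tip <- length(tree$tip.label)
  absent <- setdiff(tree$tip.label, rownames(matrix))
  nsites <- ncol(matrix)
  tree_po <- stats::reorder(tree, "postorder")
  edge <- tree_po$edge
  elen <- tree_po$edge.length
  tip_partial <- vector("list", n_tip)
  for (i in seq_len(n_tip)) {
    lab <- tree$tip.label[i]
    p <- matrix(0, nsites, 4)
    if (lab %in% absent) {
      p[] <- 1
    } else {
      sym <- toupper(matrix[lab, ])
      miss <- is_missing_symbol(sym)
      p[miss, ] <- 1
      idx <- match(sym, DNA_BASES)
      ok <- which(!miss)
      p[cbind(ok, idx[ok])] <- 1
    }
    tip_partial[[i]] <- p
  }
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L

  function(lambda) {
    lambda <- rep_len(lambda, nsites)
    partial <- vector("list", n_node)
    partial[seq_len(n_tip)] <- tip_partial
    logscale <- numeric(nsites)
    for (k in seq_len(nrow(edge))) {
      par <- edge[k, 1]
      ch <- edge[k, 2]
      V <- partial[[ch]]
      e <- exp(-4 / 3 * lambda * elen[k])
      contrib <- V * e + (1 - e) / 4 * rowSums(V)
      if (is.null(partial[[par]])) {
        partial[[par]] <- contrib
      } else {
        p <- partial[[par]] * contrib
        mx <- pmax(p[, 1], p[, 2], p[, 3], p[, 4])
        mx[mx == 0] <- 1
        logscale <- logscale + log(mx)
        partial[[par]] <- p / mx
      }
      if (ch > n_tip) partial[ch] <- list(NULL)
    }
    log(rowSums(partial[[root]]) / 4) + logscale
  }
}

# Arrange a column (named vector or tree-tip-ordered vector) as a
# one-column matrix over the tree's tips; taxa absent from the column
# become '?'.
column_as_matrix <- function(tree, column) {
  labs <- tree$tip.label
  if (!is.null(names(column))) {
    unknown <- setdiff(names(column), labs)
    if (length(unknown))
      stopf("column taxa not in tree: %s", paste(unknown, collapse = ", "))
    sym <- setNames(rep("?", length(labs)), labs)
    sym[names(column)] <- column
  } else {
    if (length(column) != length(labs))
      stopf("unnamed column must have one symbol per tree tip")
    sym <- setNames(column, labs)
  }
  matrix(sym, ncol = 1, dimnames = list(labs, NULL))
}

#' Log-likelihood of a single alignment column at a given rate
#'
#' Felsenstein pruning under JC69 on the fixed tree, with uniform 1/4
#' root state frequencies. Branch `b` contributes `d = lambda *
#' length(b)` expected substitutions. Missing symbols enter as partial
#' vectors of ones; taxa in the tree but absent from the column are
#' treated as missing.
#'
#' @param tree A `"phylo"` time tree.
#' @param column Character vector of symbols, named by taxon (or
#'   unnamed, in tree tip order).
#' @param lambda Substitution rate (per site per Ma), `>= 0`.
#' @return Log-likelihood (a single number).
#' @export
site_loglik <- function(tree, column, lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0)
  make_pruner(tree, column_as_matrix(tree, column))(lambda)
}

#' Maximum-likelihood substitution rate for one column
#'
#' Maximizes [site_loglik()] over `[0, lambda_max]` by Brent's method.
#' Degenerate columns (constant, all-missing, or fewer than two
#' non-missing taxa) get `lambda = 0` with the boundary flag set, so
#' downstream informativeness sums stay defined.
#'
#' @inheritParams site_loglik
#' @param lambda_max Upper search bound; default `20 / root_age(tree)`,
#'   i.e. up to ~20 expected changes root-to-tip, well past saturation.
#' @param tol Absolute tolerance on lambda.
#' @return List with `lambda`, `loglik`, `boundary`.
#' @export
estimate_site_rate <- function(tree, column, lambda_max = NULL, tol = 1e-8) {
  warn_if_not_ultrametric(tree, "estimate_site_rate")
  if (is.null(lambda_max)) lambda_max <- 20 / root_age(tree)
  m <- column_as_matrix(tree, column)
  obs <- m[!is_missing_symbol(m), 1]
  if (length(obs) < 2 || length(unique(obs)) < 2) {
    f <- make_pruner(tree, m)
    return(list(lambda = 0, loglik = f(0), boundary = TRUE))
  }
  f <- make_pruner(tree, m)
  # the profile likelihood can develop a saturation plateau near
  # lambda_max besides the interior mode; bracket the global optimum on
  # a coarse log grid before running Brent inside the bracket
  grid <- c(0, exp(seq(log(lambda_max * 1e-3), log(lambda_max),
                       length.out = 24)))
  ll_grid <- vapply(grid, f, numeric(1))
  j <- which.max(ll_grid)
  lo <- grid[max(j - 1L, 1L)]
  hi <- grid[min(j + 1L, length(grid))]
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  cand <- c(0, opt$maximum, lambda_max)
  ll <- c(ll_grid[1], opt$objective, ll_grid[length(grid)])
  best <- which.max(ll)
  lam <- cand[best]
  list(lambda = lam, loglik = ll[best],
       boundary = lam <= tol * lambda_max * 10 || lam >= lambda_max * (1 - 1e-6))
}

#' Estimate a substitution rate for every alignment column
#'
#' Runs the JC69 pruning-likelihood estimator independently for each
#' column of the alignment on the fixed ultrametric tree. Internally all
#' sites are optimized together: a coarse log-spaced grid over
#' `[0, lambda_max]` brackets each site's optimum, then a vectorized
#' golden-section refinement evaluates all sites per iteration in a
#' single pruning pass, which keeps full-matrix runs (thousands of
#' sites, dozens of taxa) in seconds.
#'
#' @param matrix Sequence matrix (taxa x columns); all taxa must be tips
#'   of `tree`.
#' @param tree A `"phylo"` ultrametric time tree (warns otherwise).
#' @param scheme Optional `"partition_scheme"` used to label rows.
#' @param lambda_max,tol As in [estimate_site_rate()].
#' @param grid_size Number of points in the bracketing grid.
#' @return A site-rate table: data frame with `site`, `partition`,
#'   `lambda`, `loglik`, `boundary`, one row per column in order.
#' @seealso [write_rate_table()], [read_rate_table()]
#' @export
estimate_all_rates <- function(matrix, tree, scheme = NULL,
                               lambda_max = NULL, tol = 1e-8,
                               grid_size = 24) {
  matrix <- validate_seq_matrix(matrix)
  missing_taxa <- setdiff(rownames(matrix), tree$tip.label)
  if (length(missing_taxa))
    stopf("alignment taxa not in tree: %s", paste(missing_taxa, collapse = ", "))
  warn_if_not_ultrametric(tree, "estimate_all_rates")
  if (is.null(lambda_max)) lambda_max <- 20 / root_age(tree)
  nsites <- ncol(matrix)

  n_states <- apply(matrix, 2, function(col) {
    obs <- col[!is_missing_symbol(col)]
    if (length(obs) < 2) 0L else length(unique(obs))
  })
  degen <- n_states < 2
  lambda <- numeric(nsites)
  loglik <- numeric(nsites)
  boundary <- degen

  f_all <- make_pruner(tree, matrix)
  if (any(degen)) loglik[degen] <- f_all(rep(0, nsites))[degen]

  act <- which(!degen)
  if (length(act)) {
    f <- make_pruner(tree, matrix[, act, drop = FALSE])
    grid <- c(0, exp(seq(log(lambda_max * 1e-3), log(lambda_max),
                         length.out = grid_size)))
    ll_grid <- vapply(grid, function(g) f(g), numeric(length(act)))
    if (length(act) == 1) ll_grid <- matrix(ll_grid, nrow = 1)
    best_j <- max.col(ll_grid, ties.method = "first")
    lo <- grid[pmax(best_j - 1L, 1L)]
    hi <- grid[pmin(best_j + 1L, length(grid))]

    gr <- (sqrt(5) - 1) / 2
    c1 <- hi - gr * (hi - lo)
    d1 <- lo + gr * (hi - lo)
    fc <- f(c1)
    fd <- f(d1)
    iter <- 0L
    while (max(hi - lo) > tol && iter < 100L) {
      left <- fc >= fd
      hi[left] <- d1[left]
      d1[left] <- c1[left]
      fd[left] <- fc[left]
      c1[left] <- hi[left] - gr * (hi[left] - lo[left])
      lo[!left] <- c1[!left]
      c1[!left] <- d1[!left]
      fc[!left] <- fd[!left]
      d1[!left] <- lo[!left] + gr * (hi[!left] - lo[!left])
      probe <- ifelse(left, c1, d1)
      fnew <- f(probe)
      fc[left] <- fnew[left]
      fd[!left] <- fnew[!left]
      iter <- iter + 1L
    }
    lam_hat <- (lo + hi) / 2
    ll_hat <- f(lam_hat)
    # endpoints can beat the interior when the likelihood is monotone
    at0 <- ll_grid[, 1] >= ll_hat
    lam_hat[at0] <- 0
    ll_hat[at0] <- ll_grid[at0, 1]
    lambda[act] <- lam_hat
    loglik[act] <- ll_hat
    boundary[act] <- lam_hat <= lambda_max * 1e-5 |
      lam_hat >= lambda_max * (1 - 1e-4)
  }

  part <- if (is.null(scheme)) NA_character_ else partition_of_column(scheme)
  data.frame(site = seq_len(nsites), partition = part,
             lambda = lambda, loglik = loglik, boundary = boundary,
             stringsAsFactors = FALSE)
}

#' Write / read a site-rate table as TSV
#'
#' The TSV layout (`site`, `partition`, `lambda`, `loglik`, `boundary`)
#' is also accepted from external tools, so externally derived rates can
#' be substituted for the built-in estimator anywhere a rate table is
#' consumed.
#'
#' @param rates Data frame as returned by [estimate_all_rates()].
#' @param path File path.
#' @param provenance Named character vector written as `#` header lines.
#' @export
write_rate_table <- function(rates, path, provenance = character()) {
  write_report_tsv(rates, path, provenance)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  df <- read_report_tsv(path)
  needed <- c("site", "lambda")
  if (!all(needed %in% names(df)))
    stopf("rate table must have columns: %s", paste(needed, collapse = ", "))
  if (any(df$lambda < 0)) stopf("negative rates in rate table")
  if (is.null(df$partition)) df$partition <- NA_character_
  if (is.null(df$boundary)) df$boundary <- FALSE
  df
}
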