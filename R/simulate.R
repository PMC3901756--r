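#' HKY85 transition probability matrix
#'
#' Closed-form transition probabilities under HKY85, with the rate
#' matrix normalized so `d` is the expected number of substitutions per
#' site. Reduces to [jc_prob()] when `kappa = 1` and frequencies are
#' equal.
#'
#' @param d Expected substitutions per site, `>= 0`.
#' @param kappa Transition/transversion rate ratio, `> 0`.
#' @param freq Base frequencies in order A, C, G, T; must sum to 1.
#' @return A 4x4 matrix (rows: from-state, columns: to-state).
#' @export
hky_prob <- function(d, kappa = 1, freq = rep(0.25, 4)) {
  stopifnot(d >= 0, kappa > 0, length(freq) == 4,
            abs(sum(freq) - 1) < 1e-8, all(freq > 0))
  P <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (i in 1:4)
    P[i, ] <- hky_row(i, d, kappa, freq)
  P
}

# One row of the HKY transition matrix, vectorized over d.
# Returns length(d) x 4. State order A, C, G, T; purines {A,G}.
hky_row <- function(from, d, kappa, freq) {
  piR <- freq[1] + freq[3]
  piY <- freq[2] + freq[4]
  beta <- 1 / (2 * (piR * piY + kappa * (freq[1] * freq[3] + freq[2] * freq[4])))
  grp <- c(piR, piY, piR, piY)
  purine <- c(TRUE, FALSE, TRUE, FALSE)
  e2 <- exp(-beta * d)
  out <- matrix(0, length(d), 4)
  for (j in 1:4) {
    e3 <- exp(-beta * d * (1 + grp[j] * (kappa - 1)))
    out[, j] <- if (j == from) {
      freq[j] + freq[j] * (1 / grp[j] - 1) * e2 + (grp[j] - freq[j]) / grp[j] * e3
    } else if (purine[j] == purine[from]) {  # transition
      freq[j] + freq[j] * (1 / grp[j] - 1) * e2 - freq[j] / grp[j] * e3
    } else {                                 # transversion
      freq[j] * (1 - e2)
    }
  }
  pmax(out, 0)  # clamp floating-point dust at d ~ 0
}

#' Partition specification for the sequence simulator
#'
#' @param name Partition name.
#' @param length Number of columns, `>= 1`.
#' @param mean_rate Mean substitution rate, per site per Ma, `>= 0`.
#' @param gamma_shape Shape of the gamma law for among-site rate
#'   variation (mean fixed at `mean_rate`), or `"equal"` for a single
#'   shared rate.
#' @param model `"JC"` or `"HKY"`.
#' @param kappa,freq HKY parameters (ignored for JC).
#' @return A `"sim_partition_spec"` list.
#' @export
sim_partition_spec <- function(name, length, mean_rate, gamma_shape = "equal",
                               model = c("JC", "HKY"), kappa = 1,
                               freq = rep(0.25, 4)) {
  model <- match.arg(model)
  stopifnot(length >= 1, mean_rate >= 0, kappa > 0,
            abs(sum(freq) - 1) < 1e-8)
  if (!identical(gamma_shape, "equal"))
    stopifnot(is.numeric(gamma_shape), gamma_shape > 0)
  if (model == "JC") { kappa <- 1; freq <- rep(0.25, 4) }
  structure(list(name = name, length = as.integer(length),
                 mean_rate = mean_rate, gamma_shape = gamma_shape,
                 model = model, kappa = kappa, freq = freq),
            class = "sim_partition_spec")
}

#' Simulate an ultrametric pure-birth tree with a fixed root age
#'
#' A Yule (pure-birth) topology on `n_tips` tips, with node heights
#' rescaled so the root sits at exactly `root_age` Ma. Ultrametric by
#' construction.
#'
#' @param n_tips Number of tips, `>= 2`.
#' @param root_age Root age in Ma, `> 0`.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return A `"phylo"` tree with tips `t1 ... tN`.
#' @export
simulate_tree <- function(n_tips, root_age, seed) {
  stopifnot(n_tips >= 2, root_age > 0)
  tree <- withr::with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tree$edge.length <- tree$edge.length * root_age / max(tip_depths(tree))
  tree
}

# Evolve states (integers 1..4) down the tree for nsites sites with
# per-site rates; returns tips x sites integer matrix.
evolve_states <- function(tree, lambda, kappa, freq) {
  nsites <- length(lambda)
  n_tip <- length(tree$tip.label)
  tree_cw <- stats::reorder(tree, "cladewise")
  edge <- tree_cw$edge
  elen <- tree_cw$edge.length
  root <- n_tip + 1L
  states <- vector("list", n_tip + tree$Nnode)
  states[[root]] <- sample.int(4, nsites, replace = TRUE, prob = freq)
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    d <- lambda * elen[k]
    ps <- states[[par]]
    child <- integer(nsites)
    for (s in 1:4) {
      idx <- which(ps == s)
      if (!length(idx)) next
      pr <- hky_row(s, d[idx], kappa, freq)
      u <- runif(length(idx))
      c1 <- pr[, 1]; c2 <- c1 + pr[, 2]; c3 <- c2 + pr[, 3]
      child[idx] <- 1L + (u > c1) + (u > c2) + (u > c3)
    }
    states[[ch]] <- child
  }
  out <- do.call(rbind, states[seq_len(n_tip)])
  rownames(out) <- tree$tip.label
  out
}

#' Simulate a partitioned alignment with known per-site rates
#'
#' Each partition's site rates are drawn from its rate law (recorded in
#' the output), root states from the model's stationary frequencies,
#' and characters evolved root-to-tips with branch contribution
#' `d = lambda * branch_length`.
#'
#' @param tree A `"phylo"` time tree.
#' @param specs List of [sim_partition_spec()] objects; partitions are
#'   laid out consecutively in the given order.
#' @param seed Integer seed; fully reproducible, global RNG untouched.
#' @return A `"sim_bundle"`: list with `tree`, `matrix` (sequence
#'   matrix), `true_rates` (data frame `site`, `partition`,
#'   `lambda_true`), `scheme`, `specs`, `seed`.
#' @export
simulate_alignment <- function(tree, specs, seed) {
  if (inherits(specs, "sim_partition_spec")) specs <- list(specs)
  withr::with_seed(seed, {
    blocks <- list(); rates <- list()
    for (sp in specs) {
      lam <- if (identical(sp$gamma_shape, "equal"))
        rep(sp$mean_rate, sp$length)
      else if (sp$mean_rate == 0)
        rep(0, sp$length)
      else
        rgamma(sp$length, shape = sp$gamma_shape,
               rate = sp$gamma_shape / sp$mean_rate)
      st <- evolve_states(tree, lam, sp$kappa, sp$freq)
      blocks[[sp$name]] <- matrix(DNA_BASES[st], nrow = nrow(st),
                                  dimnames = list(rownames(st), NULL))
      rates[[sp$name]] <- lam
    }
    m <- do.call(cbind, blocks)
    lens <- vapply(specs, `[[`, integer(1), "length")
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    charset <- paste(mapply(function(sp, a, b) sprintf("%s = %d-%d", sp$name, a, b),
                            specs, starts, ends), collapse = "\n")
    scheme <- resolve_partitions(charset, ncol(m))
    true_rates <- data.frame(
      site = seq_len(ncol(m)),
      partition = rep(vapply(specs, `[[`, character(1), "name"), lens),
      lambda_true = unlist(rates, use.names = FALSE),
      stringsAsFactors = FALSE)
    structure(list(tree = tree, matrix = m, true_rates = true_rates,
                   scheme = scheme, specs = specs, seed = seed),
              class = "sim_bundle")
  })
}

#' Blank out whole fragments at random (fragment-level missing data)
#'
#' For each (taxon, partition) cell independently with probability
#' `fragment_missing_rate`, all of that taxon's columns in that
#' partition are replaced by `?` — emulating specimens for which a gene
#' fragment failed to amplify.
#'
#' @param matrix Sequence matrix.
#' @param scheme `"partition_scheme"` defining the fragments.
#' @param fragment_missing_rate Probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The modified sequence matrix.
#' @export
inject_missing <- function(matrix, scheme, fragment_missing_rate, seed) {
  stopifnot(fragment_missing_rate >= 0, fragment_missing_rate <= 1)
  check_scheme_width(scheme, matrix)
  withr::with_seed(seed, {
    for (nm in names(scheme)) {
      drop <- runif(nrow(matrix)) < fragment_missing_rate
      if (any(drop)) matrix[drop, scheme[[nm]]] <- "?"
    }
  })
  matrix
}
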