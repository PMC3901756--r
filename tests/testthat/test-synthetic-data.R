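test_that("simulated trees are ultrametric, correctly aged and reproducible", {
  tr <- simulate_tree(2, 100, 1)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(sort(tr$edge.length), c(100, 100))

  tr40 <- simulate_tree(40, 110, 1)
  expect_true(check_ultrametric(tr40, tol = 1e-9))
  expect_equal(root_age(tr40), 110, tolerance = 1e-9)
  expect_identical(write_newick(simulate_tree(40, 110, 1)),
                   write_newick(tr40))
  expect_false(identical(write_newick(simulate_tree(40, 110, 2)),
                         write_newick(tr40)))
  # simulation must not disturb the session RNG
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_tree(10, 50, 7)); after <- runif(1)
  expect_identical(before, after)
})

test_that("HKY transition matrix rows sum to one and reduce to JC", {
  freq <- c(0.35, 0.12, 0.10, 0.43)
  for (d in c(0, 0.01, 0.5, 3)) {
    P <- hky_prob(d, kappa = 6, freq = freq)
    expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-12)
    expect_true(all(P >= 0))
    expect_equal(unname(hky_prob(d)), unname(jc_prob(d)), tolerance = 1e-12)
  }
  # detailed balance at stationarity: pi_i P_ij = pi_j P_ji
  P <- hky_prob(0.3, kappa = 4, freq = freq)
  for (i in 1:4) for (j in 1:4)
    expect_equal(freq[i] * P[i, j], freq[j] * P[j, i], tolerance = 1e-12)
})

test_that("zero-rate partitions are constant; JC mismatch matches closed form", {
  tr <- simulate_tree(6, 40, 3)
  b0 <- simulate_alignment(tr, sim_partition_spec("z", 50, 0), seed = 3)
  expect_true(all(apply(b0$matrix, 2, function(c) length(unique(c))) == 1))

  # 2-taxon tree at distance d: mismatch ~ Binomial(L, 3/4(1-e^{-4d/3}))
  cherry <- read_newick("(A:5,B:5);")
  lam <- 0.03; L <- 2000; d <- lam * 10
  b <- simulate_alignment(cherry, sim_partition_spec("p", L, lam, model = "JC"),
                          seed = 13)
  p_exp <- 0.75 * (1 - exp(-4 * d / 3))
  p_obs <- mean(b$matrix["A", ] != b$matrix["B", ])
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("HKY with kappa > 1 generates transition-rich divergence", {
  cherry <- read_newick("(A:4,B:4);")
  b <- simulate_alignment(cherry,
    sim_partition_spec("h", 3000, 0.01, model = "HKY", kappa = 4), seed = 17)
  a <- b$matrix["A", ]; bb <- b$matrix["B", ]
  diff <- a != bb
  purine <- function(x) x %in% c("A", "G")
  transitions <- sum(diff & (purine(a) == purine(bb)))
  transversions <- sum(diff & (purine(a) != purine(bb)))
  expect_gt(transitions / transversions, 1)
})

test_that("fragment-level missingness hits the requested rate", {
  tr <- simulate_tree(40, 110, 19)
  b <- simulate_alignment(tr, lapply(1:8, function(i)
    sim_partition_spec(paste0("f", i), 100, 0.001)), seed = 19)
  expect_identical(inject_missing(b$matrix, b$scheme, 0, seed = 1), b$matrix)
  expect_true(all(inject_missing(b$matrix, b$scheme, 1, seed = 1) == "?"))

  m <- inject_missing(b$matrix, b$scheme, 0.11, seed = 20)
  cells <- vapply(b$scheme, function(cols)
    apply(m[, cols, drop = FALSE] == "?", 1, all), logical(40))
  frac <- mean(cells)
  n <- length(cells)
  expect_lt(abs(frac - 0.11), 3 * sqrt(0.11 * 0.89 / n))
})

test_that("the emulated eight-fragment matrix has the reference layout", {
  fx <- get_marker_fixture()
  expect_equal(ncol(fx$matrix), 6095)
  expect_equal(unname(partition_lengths(fx$fragment_scheme)),
               c(2008L, 821L, 684L, 671L, 670L, 466L, 447L, 328L))
  expect_equal(sum(partition_lengths(fx$scheme)), 6095L)
  expect_equal(length(fx$scheme), 20)      # 6 coding x 3 positions + 2 ribosomal
  expect_equal(length(fx$tree$tip.label), 40)
  expect_equal(root_age(fx$tree), 110, tolerance = 1e-9)
  expect_true(check_ultrametric(fx$tree, tol = 1e-9))
  # codon partitions interleave with stride 3
  expect_equal(fx$scheme$CAD_pos2[1:3], c(2L, 5L, 8L))
  # rate ordering of the design: mito3 >> nuc3 > ribosomal > 1st/2nd
  cls <- tapply(fx$true_rates$lambda_true, fx$true_rates$rate_class, mean)
  expect_gt(cls["mito_pos3"], 2 * cls["nuc_pos3"])
  expect_gt(cls["nuc_pos3"], cls["ribo_16S"])
  expect_gt(cls["ribo_28S"], cls["mito_pos1"])
})

test_that("fixture generation is byte-identical for a fixed seed", {
  fx <- get_marker_fixture()
  fx2 <- marker_fixture(seed = 1)
  expect_identical(fx2$matrix, fx$matrix)
  expect_identical(write_newick(fx2$tree), write_newick(fx$tree))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_fixture_dir(fx, dir1)
  write_fixture_dir(fx2, dir2)
  for (f in c("alignment.fasta", "tree.nwk", "partitions.txt"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  # written fixture re-reads consistently
  m <- read_fasta(file.path(dir1, "alignment.fasta"))
  expect_identical(unname(m), unname(fx$matrix))
  sch <- resolve_partitions(paste(readLines(file.path(dir1, "partitions.txt")),
                                  collapse = "\n"), ncol(m))
  expect_equal(lapply(sch, identity), lapply(fx$scheme, identity))
})

test_that("realized fragment-level missingness of the fixture is near 11%", {
  fx <- get_marker_fixture()
  cells <- vapply(fx$fragment_scheme, function(cols)
    apply(fx$matrix[, cols, drop = FALSE] == "?", 1, all), logical(40))
  expect_lt(abs(mean(cells) - 0.11), 3 * sqrt(0.11 * 0.89 / length(cells)))
})
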