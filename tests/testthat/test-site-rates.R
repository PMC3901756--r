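test_that("JC transition probabilities match the closed form", {
  expect_equal(jc_prob(0), diag(4), ignore_attr = TRUE)
  expect_equal(unname(jc_prob(1e6)), matrix(0.25, 4, 4), tolerance = 1e-12)
  P <- jc_prob(0.75)
  expect_equal(P[1, 1], 0.25 + 0.75 * exp(-1), tolerance = 1e-9)
  expect_equal(P[1, 2], 0.25 - 0.25 * exp(-1), tolerance = 1e-9)
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE)
  expect_error(jc_prob(-0.1), "non-negative")
})

test_that("pruning likelihood equals brute-force enumeration on small trees", {
  bases <- c("A", "C", "G", "T", "?", "-")
  for (seed in 1:6) {
    n_tip <- sample(3:6, 1)
    tr <- simulate_tree(n_tip, 20, seed)
    withr::with_seed(seed * 100, {
      col <- setNames(sample(bases, n_tip, replace = TRUE), tr$tip.label)
    })
    for (lam in c(0, 0.005, 0.05, 0.4)) {
      expect_equal(site_loglik(tr, col, lam),
                   brute_force_loglik(tr, col, lam), tolerance = 1e-9)
    }
  }
})

test_that("degenerate and monotone columns hit the documented limits", {
  tr <- read_newick("((A:2,B:2):3,C:5);")
  # constant column at lambda 0: probability (1/4) * 1
  expect_equal(site_loglik(tr, c(A = "A", B = "A", C = "A"), 0), log(0.25))
  fit <- estimate_site_rate(tr, c(A = "A", B = "A", C = "A"))
  expect_equal(fit$lambda, 0)
  expect_true(fit$boundary)
  # all-missing column: likelihood 1, constant in lambda
  expect_equal(site_loglik(tr, c(A = "?", B = "-", C = "N"), 0.3), 0)
  # two differing taxa: likelihood increases towards saturation
  tr2 <- read_newick("(A:1,B:1);")
  ll <- vapply(c(0.01, 0.1, 1, 5), function(l)
    site_loglik(tr2, c(A = "A", B = "C"), l), numeric(1))
  expect_true(all(diff(ll) > 0))
  fit2 <- estimate_site_rate(tr2, c(A = "A", B = "C"), lambda_max = 2)
  expect_true(fit2$boundary)
  expect_gt(fit2$lambda, 2 * 0.99)
})

test_that("the optimizer attains the dense-grid maximum", {
  tr <- simulate_tree(8, 100, 3)
  b <- simulate_alignment(tr, sim_partition_spec("p", 30, 0.02, model = "JC"),
                          seed = 8)
  lam_max <- 20 / root_age(tr)
  grid <- seq(1e-6, lam_max, length.out = 400)
  rates <- estimate_all_rates(b$matrix, tr)
  for (j in c(1, 7, 13, 22, 30)) {
    col <- setNames(b$matrix[, j], rownames(b$matrix))
    grid_best <- max(vapply(grid, function(l) site_loglik(tr, col, l),
                            numeric(1)))
    expect_gte(rates$loglik[j], grid_best - 1e-6)
    fit <- estimate_site_rate(tr, col, lambda_max = lam_max)
    expect_gte(fit$loglik, grid_best - 1e-6)
  }
})

test_that("scalar and vectorized estimators agree", {
  tr <- simulate_tree(6, 60, 2)
  b <- simulate_alignment(tr, sim_partition_spec("p", 25, 0.01, model = "JC"),
                          seed = 2)
  all_rates <- estimate_all_rates(b$matrix, tr)
  for (j in seq_len(25)) {
    fit <- estimate_site_rate(tr, setNames(b$matrix[, j], rownames(b$matrix)))
    expect_equal(all_rates$lambda[j], fit$lambda, tolerance = 1e-4)
  }
})

test_that("gamma-rate recovery: mean estimate within 20% at 50 tips x 500 sites", {
  tr <- simulate_tree(50, 110, 11)
  b <- simulate_alignment(tr,
    sim_partition_spec("g", 500, 0.01, gamma_shape = 1, model = "JC"),
    seed = 12)
  rates <- estimate_all_rates(b$matrix, tr)
  expect_equal(nrow(rates), 500)
  expect_lt(abs(mean(rates$lambda) / 0.01 - 1), 0.2)
})

test_that("rate estimates are taxon-order invariant and scale-equivariant", {
  tr <- simulate_tree(10, 80, 6)
  b <- simulate_alignment(tr, sim_partition_spec("p", 40, 0.01, model = "JC"),
                          seed = 6)
  r1 <- estimate_all_rates(b$matrix, tr)
  r2 <- estimate_all_rates(b$matrix[sample(nrow(b$matrix)), ], tr)
  expect_equal(r2$lambda, r1$lambda, tolerance = 1e-6)
  # tree times x10  <=>  rates / 10
  tr10 <- tr
  tr10$edge.length <- tr$edge.length * 10
  r3 <- estimate_all_rates(b$matrix, tr10)
  expect_equal(r3$lambda * 10, r1$lambda, tolerance = 1e-4)
})

test_that("mean estimated rate is monotone in the simulation rate", {
  tr <- simulate_tree(20, 100, 5)
  means <- vapply(c(0.002, 0.01, 0.05), function(r) {
    b <- simulate_alignment(tr, sim_partition_spec("p", 150, r, model = "JC"),
                            seed = 5)
    mean(estimate_all_rates(b$matrix, tr)$lambda)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("rate tables round-trip through TSV and accept external layouts", {
  tr <- simulate_tree(6, 50, 9)
  b <- simulate_alignment(tr, sim_partition_spec("p", 10, 0.01), seed = 9)
  rates <- estimate_all_rates(b$matrix, tr, b$scheme)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(rates, path, provenance = c(tool = "test"))
  back <- read_rate_table(path)
  expect_equal(back$site, rates$site)
  expect_equal(back$lambda, signif(rates$lambda, 6), tolerance = 1e-6)
  expect_equal(back$partition, rates$partition)
  # minimal external table: site + lambda only
  ext <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("site\tlambda", "1\t0.01", "2\t0.02"), ext)
  got <- read_rate_table(ext)
  expect_equal(got$lambda, c(0.01, 0.02))
  expect_true(all(is.na(got$partition)))
})

test_that("non-ultrametric trees trigger a warning, not an error", {
  tr <- read_newick("((A:2,B:1):3,C:5);")
  expect_warning(estimate_site_rate(tr, c(A = "A", B = "C", C = "A")),
                 "ultrametric")
})
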