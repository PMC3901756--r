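test_that("per-site informativeness matches direct formula evaluation", {
  expect_equal(pi_rho(0, 5, "original"), 0)
  expect_equal(pi_rho(0, 5, "modified"), 0)
  expect_equal(pi_rho(0.05, 5, "original"), 16 * 0.0025 * 5 * exp(-1),
               tolerance = 1e-9)
  expect_equal(pi_rho(0.05, 5, "original"), 0.0735759, tolerance = 1e-6)
  # modified peak height is exp(-1)/4 regardless of rate
  for (lam in c(0.001, 0.02, 0.3))
    expect_equal(pi_rho(lam, pi_peak_time(lam), "modified"), exp(-1) / 4,
                 tolerance = 1e-12)
  expect_error(pi_rho(0.1, 0), "t must be")
  expect_error(pi_rho(-0.1, 1), "lambda")
})

test_that("original variant integrates to one; modified does not", {
  for (lam in c(0.001, 0.01, 0.1)) {
    I <- integrate(function(t) pi_rho(lam, t, "original"), 0, Inf,
                   rel.tol = 1e-9)
    expect_lt(abs(I$value - 1), 1e-6)
    Im <- integrate(function(t) pi_rho(lam, t, "modified"), 0, Inf,
                    rel.tol = 1e-9)
    expect_equal(Im$value, 1 / (16 * lam), tolerance = 1e-6)
  }
})

test_that("peak time is 1/(4 lambda) and agrees with a grid argmax", {
  expect_equal(pi_peak_time(0.025), 10)
  expect_equal(pi_peak_time(0.005), 50)
  expect_error(pi_peak_time(0), "undefined")
  for (lam in c(0.004, 0.02, 0.1)) {
    grid <- seq(0.001, 3 / (4 * lam), length.out = 5000)
    step <- diff(grid)[1]
    for (v in c("original", "modified")) {
      t_star <- grid[which.max(pi_rho(lam, grid, v))]
      expect_lt(abs(t_star - pi_peak_time(lam)), step + 1e-12)
    }
  }
})

test_that("original peak height grows with rate; modified stays flat", {
  lams <- c(0.002, 0.01, 0.05)
  orig <- vapply(lams, function(l) pi_rho(l, pi_peak_time(l), "original"),
                 numeric(1))
  expect_true(all(diff(orig) > 0))
  expect_equal(orig, 4 * lams / exp(1), tolerance = 1e-12)
  modif <- vapply(lams, function(l) pi_rho(l, pi_peak_time(l), "modified"),
                  numeric(1))
  expect_equal(modif, rep(exp(-1) / 4, 3))
})

test_that("crossing time matches root finding and the continuity limit", {
  expect_equal(pi_crossing_time(0.01, 0.04), log(4) / 0.12, tolerance = 1e-12)
  # numeric root of the modified-variant difference
  for (pair in list(c(0.01, 0.04), c(0.002, 0.01), c(0.05, 0.09))) {
    f <- function(t) pi_rho(pair[1], t, "modified") - pi_rho(pair[2], t, "modified")
    tx <- pi_crossing_time(pair[1], pair[2])
    root <- uniroot(f, c(tx / 10, tx * 10), tol = 1e-12)$root
    expect_equal(tx, root, tolerance = 1e-8)
    # the slow site leads beyond the crossing
    expect_gt(pi_rho(pair[1], tx * 2, "modified"),
              pi_rho(pair[2], tx * 2, "modified"))
    expect_lt(pi_rho(pair[1], tx / 2, "modified"),
              pi_rho(pair[2], tx / 2, "modified"))
    # exactly one sign change on (0, inf): check a wide log grid
    tt <- exp(seq(log(tx / 1e3), log(tx * 1e3), length.out = 4000))
    expect_equal(sum(diff(sign(f(tt))) != 0), 1)
  }
  # limit lambda_fast -> lambda_slow approaches the peak time
  expect_equal(pi_crossing_time(0.02, 0.02 * 1.001), pi_peak_time(0.02),
               tolerance = 1e-3)
  expect_error(pi_crossing_time(0.04, 0.01), "lambda_slow < lambda_fast")
})

test_that("partition profiles are additive and average per base", {
  rates <- data.frame(site = 1:700,
                      partition = c(rep("a", 100), rep("b", 500), rep("c", 100)),
                      lambda = c(rep(0.02, 100), rep(0.02, 500), rep(0.005, 100)))
  scheme <- resolve_partitions("a = 1-100\nb = 101-600\nc = 601-700", 700)
  grid <- seq(1, 100, length.out = 64)
  prof <- pi_profile(rates, scheme, grid = grid)

  # 100 identical-rate sites = 100 x the single-site curve
  a_mod <- prof$pi[prof$partition == "a" & prof$variant == "modified"]
  expect_equal(a_mod, 100 * pi_rho(0.02, grid, "modified"), tolerance = 1e-12)

  # concatenation = sum of partitions, pointwise (extensive variants;
  # the per-base average is intensive and deliberately not additive)
  whole <- pi_profile(data.frame(site = 1:700, partition = "all",
                                 lambda = rates$lambda),
                      resolve_partitions("all = 1-700", 700), grid = grid)
  for (v in c("original", "modified")) {
    tot <- Reduce(`+`, lapply(c("a", "b", "c"), function(p)
      prof$pi[prof$partition == p & prof$variant == v]))
    expect_equal(tot, whole$pi[whole$variant == v], tolerance = 1e-12)
  }

  # equal rate spectra, lengths 100 vs 500: average_modified equal,
  # modified differs by the length ratio
  a_avg <- prof$pi[prof$partition == "a" & prof$variant == "average_modified"]
  b_avg <- prof$pi[prof$partition == "b" & prof$variant == "average_modified"]
  b_mod <- prof$pi[prof$partition == "b" & prof$variant == "modified"]
  expect_equal(a_avg, b_avg, tolerance = 1e-12)
  expect_equal(b_mod, 5 * a_mod, tolerance = 1e-12)
})

test_that("profiles reject sites without rates and bad grids", {
  rates <- data.frame(site = 1:5, partition = "a", lambda = 0.01)
  scheme <- resolve_partitions("a = 1-6", 6)
  expect_error(pi_profile(rates, scheme, t_max = 10), "without rates")
  expect_error(pi_profile(rates, grid = c(0, 1, 2)), "strictly increasing")
  expect_error(pi_profile(rates, grid = c(3, 2, 1)), "strictly increasing")
})
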