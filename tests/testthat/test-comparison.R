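# Difference statistics, resampling significance, masking, bootstrap curve.

test_that("stat_d handles constants and recovers an injected replica-level shift", {
  b <- as_series(list(rep(5, 10), rep(5, 10)), "bound")
  u <- as_series(list(rep(3, 10), rep(3, 10)), "unbound")
  expect_identical(stat_d(b, u), 2)
  expect_identical(stat_d(b, b), 0)

  gen <- generate_descriptor_series(series_spec(
    n_replicas = 40, n_frames = 200, condition_shift = 0.9,
    between_replica_sd = 0.3, seed = 101))
  se <- sqrt(2 * 0.3^2 / 40)   # dominant between-replica term
  expect_lt(abs(stat_d(gen$bound, gen$unbound) - 0.9), 3 * se)

  expect_error(stat_d(as_series(1:10 * 1.0, "bound", units = "A"),
                      as_series(1:10 * 1.0, "unbound", units = "count")),
               class = "ensdiff_unit_error")
})

test_that("d/r matches uniform closed form, is scale invariant, and flags degenerate input", {
  set.seed(11)
  b <- as_series(runif(50000, 1, 2), "bound")
  u <- as_series(runif(50000, 0, 1), "unbound")
  # per-condition 2.5-97.5% trim: union range (1.975 - 0.025) = 1.95
  expect_equal(stat_d_over_r(b, u), 1 / 1.95, tolerance = 0.02)

  b10 <- as_series(lapply(b$values, `*`, 10), "bound")
  u10 <- as_series(lapply(u$values, `*`, 10), "unbound")
  expect_equal(stat_d_over_r(b10, u10), stat_d_over_r(b, u), tolerance = 1e-12)

  nc <- as_series(rnorm(100), "bound")
  expect_equal(stat_d_over_r(nc, as_series(nc$values[[1]], "unbound")), 0)

  expect_error(stat_d_over_r(as_series(rep(1, 50), "bound"),
                             as_series(rep(1, 50), "unbound")),
               class = "ensdiff_degenerate_range_error")
  expect_error(stat_d_over_r(as_series(rnorm(10), "bound"),
                             as_series(rnorm(10), "unbound")),
               class = "ensdiff_insufficient_data_error")
})

test_that("tvd endpoints, Gaussian closed form, symmetry and range hold", {
  set.seed(22)
  x <- as_series(rnorm(1000), "bound")
  expect_identical(stat_tvd(x, as_series(x$values[[1]], "unbound")), 0)

  lo <- as_series(runif(500, 0, 1), "bound")
  hi <- as_series(runif(500, 10, 11), "unbound")
  expect_identical(stat_tvd(lo, hi), 1)

  g0 <- as_series(rnorm(1e5, 0, 1), "bound")
  g1 <- as_series(rnorm(1e5, 1, 1), "unbound")
  expect_equal(stat_tvd(g0, g1), 2 * pnorm(0.5) - 1, tolerance = 0.01)

  # symmetry and [0,1] bounds on random inputs
  for (i in 1:5) {
    a <- as_series(rnorm(200, sd = runif(1, 0.5, 2)), "bound")
    b <- as_series(rnorm(200, mean = runif(1, -1, 1)), "unbound")
    t1 <- stat_tvd(a, b, warn_sensitivity = FALSE)
    t2 <- stat_tvd(b, a, warn_sensitivity = FALSE)
    expect_equal(t1, t2, tolerance = 1e-12)
    expect_gte(t1, 0); expect_lte(t1, 1)
  }

  expect_warning(got <- stat_tvd(as_series(rep(1, 5), "bound"),
                                 as_series(rep(1, 5), "unbound")),
                 "distinct")
  expect_identical(got, 0)
})

test_that("all four statistics agree with brute-force oracles on small series", {
  set.seed(33)
  for (i in 1:10) {
    vb <- rnorm(sample(5:20, 1), mean = runif(1, -1, 1))
    vu <- rnorm(sample(5:20, 1), sd = runif(1, 0.5, 2))
    b <- as_series(vb, "bound"); u <- as_series(vu, "unbound")
    expect_equal(stat_d(b, u), oracle_d(vb, vu), tolerance = 1e-12)
    expect_equal(stat_tvd(b, u, bins = 17, warn_sensitivity = FALSE),
                 oracle_tvd(vb, vu, bins = 17), tolerance = 1e-12)
    expect_equal(cohen_d(b, u), oracle_cohen(vb, vu), tolerance = 1e-12)
  }
  # d/r oracle needs enough values for the trim
  vb <- rnorm(60); vu <- rnorm(60, 0.4)
  expect_equal(stat_d_over_r(as_series(vb, "bound"), as_series(vu, "unbound")),
               oracle_dr(vb, vu), tolerance = 1e-12)
})

test_that("d, d/r and Cohen's d are antisymmetric under condition swap; tvd is symmetric", {
  set.seed(44)
  b <- as_series(lapply(1:4, function(i) rnorm(30, 0.5)), "bound")
  u <- as_series(lapply(1:4, function(i) rnorm(30)), "unbound")
  expect_equal(stat_d(b, u), -stat_d(u, b), tolerance = 1e-12)
  expect_equal(stat_d_over_r(b, u), -stat_d_over_r(u, b), tolerance = 1e-12)
  expect_equal(cohen_d(b, u), -cohen_d(u, b), tolerance = 1e-12)
  expect_equal(stat_tvd(b, u, warn_sensitivity = FALSE),
               stat_tvd(u, b, warn_sensitivity = FALSE), tolerance = 1e-12)
})

test_that("Cohen's d matches the definition on hand-listed values", {
  vb <- c(2.1, 1.9, 2.4, 2.0, 1.6, 2.2, 2.3, 1.8, 2.0, 2.1)
  vu <- c(1.0, 1.3, 0.8, 1.1, 0.9)
  expect_equal(cohen_d(as_series(vb, "bound"), as_series(vu, "unbound")),
               oracle_cohen(vb, vu), tolerance = 1e-12)
  expect_error(cohen_d(as_series(rep(1, 5), "bound"), as_series(rep(1, 5), "unbound")),
               class = "ensdiff_degenerate_range_error")
})

test_that("resampling q reaches 1 under a strong shift and 0 under exact ties", {
  gen <- generate_descriptor_series(series_spec(
    n_replicas = 8, n_frames = 100, condition_shift = 5,
    between_replica_sd = 0.2, seed = 55))
  q <- permutation_test(gen$bound, gen$unbound, "d", n_perm = 1000, seed = 1)
  expect_identical(q, 1)

  const_b <- as_series(list(rep(2, 10), rep(2, 10)), "bound")
  const_u <- as_series(list(rep(2, 10), rep(2, 10)), "unbound")
  expect_identical(permutation_test(const_b, const_u, "d", n_perm = 200, seed = 1), 0)

  expect_error(permutation_test(as_series(list(rnorm(5)), "bound"),
                                as_series(list(rnorm(5)), "unbound"), "d"),
               class = "ensdiff_insufficient_replicas_error")
})

test_that("masking keeps only top/bottom 5% signed values and top 5% tvd", {
  res <- structure(list(descriptor_name = "x", units = "A",
                        d = 0.3, d_over_r = 0.1, tvd = 0.4, cohen = 0.2,
                        q_d = 0.70, q_dr = 0.97, q_tvd = 0.04, q_cohen = 0.02),
                   class = "comparison_result")
  m <- significance_mask(res)
  expect_identical(m$masked_d, 0)        # q = 0.70: unlikely to be real
  expect_identical(m$masked_dr, 0.1)     # q = 0.97: top 5%
  expect_identical(m$masked_tvd, 0)      # tvd is one-sided; q = 0.04 fails
  expect_identical(m$masked_cohen, 0.2)  # q = 0.02: bottom 5%
  res$q_d <- 1.0
  expect_identical(significance_mask(res)$masked_d, 0.3)
})

test_that("bootstrap curve obeys closed forms and is monotone for iid replicas", {
  expect_true(all(bootstrap_replica_variance(rep(3, 20), c(1, 5), 500,
                                             seed = 2)$mean_abs_diff == 0))
  set.seed(66)
  means <- rnorm(50000)
  bc <- bootstrap_replica_variance(means, c(1, 4, 10, 25), n_boot = 50000, seed = 3)
  # E|X - Y| = 2/sqrt(pi) for X, Y iid standard normal
  expect_equal(bc$mean_abs_diff[bc$n == 1], 2 / sqrt(pi), tolerance = 0.02)
  expect_true(all(diff(bc$mean_abs_diff) < 0))
  expect_equal(bc$pct_reduction[bc$n == 25], 80, tolerance = 0.02)

  expect_error(bootstrap_replica_variance(means, 0), class = "ensdiff_argument_error")
  expect_error(bootstrap_replica_variance(rnorm(5), 10), class = "ensdiff_argument_error")
})
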