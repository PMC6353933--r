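test_that("exhaustive null enumerates all permutations with known values", {
  # monotone n = 3 pair, Spearman: rho over 3! permutations
  d <- abundance_pair("m", c(1, 10, 100), c(2, 3, 5))
  null <- exhaustive_null(d, "spearman_rho")
  expect_length(null, 6)
  expect_equal(sort(null), c(-1, -0.5, -0.5, 0.5, 0.5, 1))
  expect_equal(exact_two_tailed_p(null, 1), 2 / 6)
  # n = 2: reflection symmetry of the slope
  d2 <- abundance_pair("r", c(1, 10), c(2, 5))
  null2 <- exhaustive_null(d2, "pm_slope")
  expect_length(null2, 2)
  expect_equal(null2[1], -null2[2])
  # factorial bound
  big <- make_random_pair(9, pair_id = "big")
  expect_error(exhaustive_null(big), "n <= 8")
})

test_that("permutation test is deterministic and carries coherent fields", {
  set.seed(12)
  d <- make_random_pair(15, alpha = 0.8, noise_sd = 0.2)
  r1 <- permutation_test(d, "pm_slope", n_perm = 400, seed = 5)
  r2 <- permutation_test(d, "pm_slope", n_perm = 400, seed = 5)
  expect_identical(r1, r2)
  expect_length(r1$null_values, 400)
  expect_true(r1$p_two_tailed > 0 && r1$p_two_tailed <= 1)
  expect_true(r1$ci_low <= r1$ci_median && r1$ci_median <= r1$ci_high)
  expect_equal(r1$observed, loglog_fit(d)$alpha_hat)
  # a different seed gives a different null stream
  r3 <- permutation_test(d, "pm_slope", n_perm = 400, seed = 6)
  expect_false(identical(r1$null_values, r3$null_values))
  expect_error(permutation_test(d, n_perm = 0), "n_perm")
})

test_that("slope and Pearson statistics give identical permutation p-values", {
  # slope = r * sd(y)/sd(x) with both sds permutation-invariant, so the
  # two statistics order the null identically
  set.seed(34)
  for (i in 1:10) {
    d <- make_random_pair(12, alpha = runif(1, 0, 1))
    ps <- permutation_test(d, "pm_slope", n_perm = 300, seed = 9)
    pr <- permutation_test(d, "pearson_r", n_perm = 300, seed = 9)
    expect_equal(ps$p_two_tailed, pr$p_two_tailed)
  }
})

test_that("Monte-Carlo p agrees with the exhaustive oracle at small n", {
  set.seed(56)
  for (i in 1:12) {
    n <- sample(3:6, 1)
    d <- make_random_pair(n, alpha = runif(1, 0, 1),
                          pair_id = paste0("o", i))
    null <- exhaustive_null(d, "pm_slope")
    p_exact <- exact_two_tailed_p(null, loglog_fit(d)$alpha_hat)
    mc <- permutation_test(d, "pm_slope", n_perm = 2000, seed = i)
    se <- sqrt(p_exact * (1 - p_exact) / 2000)
    expect_lt(abs(mc$p_two_tailed - p_exact), 3 * se + 2 / 2001)
  }
})

test_that("null distribution of the slope is centred at zero", {
  cfg <- synthetic_config(alpha = 0.5, noise_sd = 0.4, zero_rate = 0,
                          n_sites = 39, seed = 21)
  d <- generate_pair(cfg, "centre")
  r <- permutation_test(d, "pm_slope", n_perm = 5000, seed = 2)
  expect_lt(abs(mean(r$null_values)),
            4 * sd(r$null_values) / sqrt(r$n_perm))
})

test_that("p-values are uniform under the independence null", {
  # 300 decoupled pairs; add-one p-values should be ~U(0,1]
  cfg <- synthetic_config(alpha = 0, noise_sd = 0.5, zero_rate = 0,
                          n_sites = 39, n_pairs = 300, seed = 1234)
  gen <- generate_collection(cfg)
  pvals <- vapply(gen$datasets, function(d)
    permutation_test(d, "pm_slope", n_perm = 500, seed = 77)$p_two_tailed,
    numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  rej <- mean(pvals < 0.05)
  expect_lt(abs(rej - 0.05), 2.58 * sqrt(0.05 * 0.95 / 300))
})

test_that("the test detects a strong coupling (power check)", {
  cfg <- synthetic_config(alpha = 1, noise_sd = 0.1, zero_rate = 0,
                          n_sites = 39, n_pairs = 60, seed = 8)
  gen <- generate_collection(cfg)
  pvals <- vapply(gen$datasets, function(d)
    permutation_test(d, "pm_slope", n_perm = 500, seed = 3)$p_two_tailed,
    numeric(1))
  expect_gt(mean(pvals < 0.05), 0.95)
})

test_that("randomized CI uses linear-interpolation percentiles", {
  d <- make_random_pair(10)
  r <- permutation_test(d, n_perm = 100, seed = 1)
  r$null_values <- as.numeric(1:100)
  expect_equal(randomized_ci(r), c(3.475, 50.5, 97.525))
  r$null_values <- rep(4, 100)
  expect_equal(randomized_ci(r), c(4, 4, 4))
  expect_error(randomized_ci(r, lower = 97.5, upper = 2.5), "percentile")
  expect_error(randomized_ci(r, lower = 0, upper = 97.5), "percentile")
})

test_that("degenerate statistics are refused with pair context", {
  flat <- abundance_pair("flatvirus", c(1, 10, 100), c(5, 5, 5))
  expect_error(permutation_test(flat, "pearson_r", n_perm = 10, seed = 1),
               "flatvirus.*degenerate")
  # pm_slope on constant virus is defined (slope 0, null all 0)
  r <- permutation_test(flat, "pm_slope", n_perm = 50, seed = 1)
  expect_equal(r$observed, 0)
  expect_equal(r$p_two_tailed, 1)
})
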