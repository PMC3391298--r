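test_that("permutation test degenerates correctly and records its pieces", {
  # fully tied scores: every permuted statistic equals the observed one
  tied <- labeled_scores(rep(1, 20), rep(c(0, 1), 10))
  res <- rocs_perm_test(tied, K = 50, seed = 1)
  expect_equal(res$p_value, 1)
  expect_length(res$null_values, 50)
  expect_equal(res$p_value, mean(res$null_values >= res$observed))

  expect_error(rocs_perm_test(six_feature(), K = 0),
               class = "rocsurface_invalid_input")

  # deterministic given seed, seed recorded
  r1 <- rocs_perm_test(six_feature(), K = 30, seed = 9)
  r2 <- rocs_perm_test(six_feature(), K = 30, seed = 9)
  expect_identical(r1$null_values, r2$null_values)
  expect_equal(r1$seed, 9L)

  td <- tidy(r1)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$p.value, r1$p_value)
  expect_identical(glance(r1), td)
})

test_that("perfect separation is highly significant under label permutation", {
  d <- labeled_scores(c(rnorm(100), rnorm(100, 10)), rep(c(0, 1), each = 100))
  res <- rocs_perm_test(d, K = 100, seed = 4)
  expect_equal(res$observed, 1)
  expect_lte(res$p_value, 0.05)
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(101)
  pvals <- vapply(1:200, function(i) {
    d <- labeled_scores(rnorm(50), sample(rep(c(TRUE, FALSE), c(10, 40))))
    rocs_perm_test(d, K = 100)$p_value
  }, numeric(1))
  # rejection rate at alpha = 0.05 within binomial noise around 5%
  rej <- mean(pvals <= 0.05)
  expect_gte(rej, 0.005)
  expect_lte(rej, 0.11)
  # and the bulk looks uniform: empirical CDF near the diagonal
  for (a in c(0.1, 0.25, 0.5, 0.75)) {
    expect_lt(abs(mean(pvals <= a) - a), 0.1)
  }
})

test_that("two-surface test: identical studies give zero difference, p = 1", {
  s1 <- simulate_two_class(n_neg = 200, n_pos = 50, mu_pos = 1, seed = 2)
  res <- rocs_diff_test(s1, s1, B = 99, seed = 3)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)
  expect_error(rocs_diff_test(s1, s1, B = 0),
               class = "rocsurface_invalid_input")
})

test_that("VUS is rank-invariant, so the rank transform preserves it", {
  set.seed(7)
  d <- simulate_two_class(n_neg = 300, n_pos = 100, mu_pos = 1, seed = 7)
  ranked <- d
  ranked$score <- as.double(rank_transform(d$score, seed = 1))
  expect_equal(vus(rocs_curve(d)), vus(rocs_curve(ranked)))
})

test_that("the two-surface test holds its size under unequal designs", {
  # both studies share N(0,1) negatives and N(1,1) positives; study sizes
  # and class ratios differ
  res <- simulate_size_power(mu1 = 1, mu2 = 1, n1_total = 1000,
                             n2_total = 2000, ratio1 = 1, ratio2 = 4,
                             reps = 100, B = 199, alpha = 0.05, seed = 21)
  expect_gte(res$rejection_rate, 0.0)
  expect_lte(res$rejection_rate, 0.13)
})

test_that("power decreases with class ratio at fixed mean difference", {
  rates <- vapply(c(1, 4, 16), function(r) {
    simulate_size_power(mu1 = 1, mu2 = 1.8, n1_total = 1000, n2_total = 1000,
                        ratio1 = r, ratio2 = r, reps = 30, B = 99,
                        alpha = 0.05, seed = 400 + r)$rejection_rate
  }, numeric(1))
  expect_gte(rates[1], rates[2] - 0.15)
  expect_gte(rates[2], rates[3] - 0.15)
  expect_gte(rates[1], rates[3])
  expect_gt(rates[1], 0.6)  # 1:1 ratio detects this separation reliably
})
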