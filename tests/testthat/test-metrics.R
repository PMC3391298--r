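test_that("worked examples: AUC, VUS and FCAUC step sums", {
  cv <- rocs_curve(six_feature())
  expect_equal(roc_auc(cv), 7 / 9)
  expect_equal(vus(cv), 11 / 15)
  expect_equal(fcauc(cv, fdr = 0.2), 2 / 3)

  # four positives ranked on top of four negatives: the 5-discovery cutoff
  # has FDR 1/5 <= 0.2, so the cap sits at TPR 1 and FCAUC = AUC = 1
  top4 <- rocs_curve(labeled_scores(8:1, c(1, 1, 1, 1, 0, 0, 0, 0)))
  expect_equal(top4$fdr, c(0, 0, 0, 0, 1/5, 2/6, 3/7, 1/2))
  expect_equal(fcauc(top4, fdr = 0.2), 1)
  expect_equal(roc_auc(top4), 1)
  expect_equal(vus(top4), 1)

  # fully tied scores: the single step is achieved at FPR = 1
  tied <- rocs_curve(labeled_scores(rep(1, 6), c(1, 1, 0, 0, 0, 0)))
  expect_equal(roc_auc(tied), 0)
})

test_that("perfect separation yields VUS = 1 at any class ratio", {
  for (ratio in c(1, 10, 100)) {
    n_pos <- 20
    n_neg <- ratio * n_pos
    d <- labeled_scores(
      c(seq_len(n_neg), n_neg + seq_len(n_pos)),
      rep(c(0, 1), c(n_neg, n_pos)))
    expect_identical(vus(rocs_curve(d)), 1)
  }
})

test_that("AUC equals brute-force Mann-Whitney pair counting (tie-free)", {
  set.seed(31)
  for (i in 1:200) {
    d <- random_labeled(sample(4:50, 1), ties = FALSE)
    expect_equal(roc_auc(rocs_curve(d, reorient = FALSE)), mw_auc(d))
  }
})

test_that("VUS matches the fine-grid Riemann oracle", {
  set.seed(13)
  for (n_pos in c(4, 5, 8, 10, 20, 25)) {   # divisors of the 1e5 grid
    n_neg <- sample(c(n_pos, 4 * n_pos), 1)
    d <- labeled_scores(rnorm(n_pos + n_neg),
                        sample(rep(c(TRUE, FALSE), c(n_pos, n_neg))))
    cv <- rocs_curve(d)
    expect_equal(vus(cv), riemann_vus(cv), tolerance = 1e-6)
  }
})

test_that("0 <= VUS <= AUC <= 1 and constant-TDR identity VUS = c * AUC", {
  set.seed(17)
  for (i in 1:60) {
    cv <- rocs_curve(random_labeled(sample(4:60, 1), ties = i %% 3 == 0))
    a <- roc_auc(cv); v <- vus(cv)
    expect_gte(v, 0); expect_lte(v, a + 1e-12); expect_lte(a, 1)
  }
  # force a constant TDR on random step curves
  for (i in 1:20) {
    cv <- rocs_curve(random_labeled(30))
    cc <- runif(1)
    forced <- cv
    forced$tdr <- rep(cc, nrow(cv))
    forced$fdr <- 1 - forced$tdr
    expect_equal(vus(forced), cc * roc_auc(forced))
  }
})

test_that("FCAUC is monotone in the FDR level with the right endpoints", {
  set.seed(23)
  for (i in 1:30) {
    cv <- rocs_curve(random_labeled(sample(6:60, 1), ties = i %% 2 == 0))
    bs <- sort(runif(6))
    vals <- vapply(bs, function(b) fcauc(cv, b), numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
    expect_lte(fcauc(cv, 0), fcauc(cv, bs[1]) + 1e-12)
    expect_equal(fcauc(cv, 1), roc_auc(cv))
  }
  expect_error(fcauc(rocs_curve(six_feature()), fdr = 1.5),
               class = "rocsurface_invalid_input")
})

test_that("class labels are not exchangeable: swap preserves AUC, moves VUS", {
  d <- six_feature()
  swapped <- labeled_scores(-d$score, !d$label)
  cv <- rocs_curve(d)
  cv_swap <- rocs_curve(swapped)
  expect_equal(roc_auc(cv_swap), roc_auc(cv))
  expect_false(isTRUE(all.equal(vus(cv_swap), vus(cv))))
})
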