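test_that("MCC follows the standard confusion formula", {
  expect_equal(mcc(10, 10, 0, 0), 1)
  expect_equal(mcc(1, 1, 1, 1), 0)
  expect_equal(mcc(2, 3, 1, 1),
               (2 * 3 - 1 * 1) / sqrt(3 * 3 * 4 * 4))
  expect_equal(mcc(0, 0, 10, 10), -1)
  expect_error(mcc(5, 0, 0, 0), class = "sf_input_error")
  expect_error(mcc(-1, 2, 3, 4), class = "sf_input_error")
})

test_that("ROC-AUC is the pairwise ranking probability with half ties", {
  expect_equal(roc_auc(c(10, 9, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  # score negation flips the curve
  set.seed(4)
  sc <- rnorm(50); lb <- rbinom(50, 1, 0.4)
  expect_equal(roc_auc(sc, lb), 1 - roc_auc(-sc, lb))
})

test_that("rank-sum Z reproduces textbook small-sample values", {
  rs <- rank_sum_z(6:10, 1:5)  # complete separation, n = 5 + 5
  expect_equal(rs$U, 25)
  expect_equal(rs$Z, 12.5 / sqrt(5 * 5 * 11 / 12))
  # antisymmetry under sample exchange
  set.seed(5)
  a <- rnorm(40); b <- rnorm(35, 0.3)
  expect_equal(rank_sum_z(a, b)$Z, -rank_sum_z(b, a)$Z)
})

test_that("binned rank-sum input reproduces the in-memory path exactly", {
  set.seed(6)
  for (t in 1:10) {
    a <- sample(1:15, 300, replace = TRUE)  # heavy ties
    b <- sample(3:20, 250, replace = TRUE)
    vals <- sort(unique(c(a, b)))
    binned <- data.frame(value = vals,
                         count_a = tabulate(match(a, vals), length(vals)),
                         count_b = tabulate(match(b, vals), length(vals)))
    expect_equal(rank_sum_z(binned)$Z, rank_sum_z(a, b)$Z,
                 tolerance = 1e-12)
  }
})

test_that("signed-rank Z matches closed forms and the reference code", {
  # perfectly symmetric pairs cancel
  expect_equal(signed_rank_z(c(-3, 3, -1, 1, -2, 2))$Z, 0)
  # all-positive differences, n = 10
  sr <- signed_rank_z(1:10)
  expect_equal(sr$W, 55)
  expect_equal(sr$Z, (55 - 27.5) / sqrt(96.25))
  expect_error(signed_rank_z(rep(0, 5)), class = "sf_input_error")
  # agreement with R's wilcox.test normal approximation (no continuity
  # correction) on random data
  set.seed(7)
  for (t in 1:50) {
    d <- round(rnorm(60, 0.2), 1)
    d <- d[d != 0]
    wt <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = FALSE))
    z_ref <- sign(signed_rank_z(d)$Z) * abs(stats::qnorm(wt$p.value / 2))
    expect_equal(signed_rank_z(d)$Z, z_ref, tolerance = 1e-6)
  }
})

test_that("rank-sum Z is calibrated under the null", {
  bad <- 0
  for (s in 1:30) {
    set.seed(s)
    if (abs(rank_sum_z(rnorm(2000), rnorm(2000))$Z) >= 3.5) bad <- bad + 1
  }
  expect_lte(bad, 1)
})

test_that("Bonferroni threshold transforms Z monotonically", {
  expect_equal(bonferroni_z_threshold(0.05, 1), qnorm(0.95))
  expect_equal(bonferroni_z_threshold(0.05, 20), qnorm(1 - 0.05 / 20))
  expect_gt(bonferroni_z_threshold(0.05, 100), bonferroni_z_threshold(0.05, 10))
})

test_that("positional profiles average aligned series with missingness", {
  one <- positional_profile(list(c(1, 2, 3, 4, 5)), anchors = 3,
                            offsets = -2:2)
  expect_equal(one$mu, c(1, 2, 3, 4, 5))
  two <- positional_profile(list(rep(0.2, 9), rep(0.4, 9)),
                            anchors = c(5, 5), offsets = -2:2)
  expect_equal(two$mu, rep(0.3, 5))
  off <- positional_profile(list(1:4), anchors = 2, offsets = -3:3)
  expect_true(is.na(off$mu[1]))
  expect_equal(off$n_cov, c(0L, 0L, 1L, 1L, 1L, 1L, 0L))
  # constant profile: normalised log-ratio is identically zero
  lr <- log_relative(two, half_span = 2)
  expect_equal(lr$log_ratio, rep(0, 5))
})

test_that("density log-ratios integrate to one and detect concentration", {
  set.seed(8)
  x <- rnorm(5000)
  d0 <- density_log_ratio(x, x, bins = 40)
  expect_equal(d0$log_ratio, rep(0, 40))
  w <- diff(d0$mid[1:2])
  expect_equal(sum(d0$f_a) * w, 1, tolerance = 1e-9)
  a <- rnorm(5000, 0, 0.3)
  b <- runif(5000, -3, 3)
  dd <- density_log_ratio(a, b, bins = 30)
  centre <- abs(dd$mid) < 0.3
  expect_gt(mean(dd$log_ratio[centre]), 0)
  expect_lt(mean(dd$log_ratio[abs(dd$mid) > 2]), 0)
})
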