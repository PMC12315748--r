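test_that("T-RT% evaluates the printed formula and its properties", {
  expect_equal(trt_percent(1.0, 1.0), 0)
  expect_equal(trt_percent(1.1, 0.9), 20)
  expect_equal(trt_percent(2.0, 1.0), 200 / 3)
  expect_error(trt_percent(1, -1), "positive sum")
  # symmetry, scale invariance, bounds
  set.seed(3)
  a <- runif(50, 0.1, 3); b <- runif(50, 0.1, 3)
  expect_equal(trt_percent(a, b), trt_percent(b, a))
  expect_equal(trt_percent(7.3 * a, 7.3 * b), trt_percent(a, b))
  expect_true(all(trt_percent(a, b) >= 0 & trt_percent(a, b) < 200))
})

test_that("mean T-RT% follows the half-normal closed form at small CV", {
  set.seed(11)
  n <- 10000; cv <- 0.05
  t1 <- 1 + rnorm(n, 0, cv); t2 <- 1 + rnorm(n, 0, cv)
  m <- mean(trt_percent(t1, t2))
  expect_gt(m, 5.0)   # analytic expectation 112.8 * cv = 5.64
  expect_lt(m, 6.3)
})

test_that("two-way ICC matches the mean-squares oracle", {
  m <- matrix(c(1, 1.1, 2, 2.1, 3, 3.05), ncol = 2, byrow = TRUE)
  # oracle: explicit two-way ANOVA decomposition computed longhand
  n <- 3; k <- 2
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  mse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + grand)^2) /
    ((n - 1) * (k - 1))
  icc_a_oracle <- (msr - mse) /
    (msr + (k - 1) * mse + k * (msc - mse) / n)
  res <- icc_two_way(m[, 1], m[, 2])
  expect_equal(res$icc, icc_a_oracle)
  # frozen cross-check values from an independent implementation
  expect_equal(res$icc, 0.996169, tolerance = 1e-5)
  expect_equal(res$ci, c(0.42, 1.00), tolerance = 0.01)
  resc <- icc_two_way(m[, 1], m[, 2], type = "consistency")
  expect_equal(resc$icc, (msr - mse) / (msr + (k - 1) * mse))
  expect_equal(resc$icc, 0.999573, tolerance = 1e-5)
})

test_that("ICC handles degenerate and invalid inputs", {
  x <- c(1, 2, 3, 4)
  expect_equal(icc_two_way(x, x)$icc, 1, tolerance = 1e-12)
  z <- icc_two_way(rep(1, 4), rep(1, 4))
  expect_true(z$undefined)
  expect_true(is.na(z$icc))
  expect_error(icc_two_way(c(1, 2), c(1, 2)), "at least 3")
})

test_that("absolute-agreement ICC is invariant to a common affine map", {
  set.seed(21)
  t1 <- rnorm(8, 10, 2); t2 <- t1 + rnorm(8, 0, 0.5)
  a <- icc_two_way(t1, t2)$icc
  b <- icc_two_way(3 * t1 + 7, 3 * t2 + 7)$icc
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("reliability bands reproduce the conventional cutpoints", {
  expect_equal(icc_band(0.97), "excellent")   # e.g. pons-level reliability
  expect_equal(icc_band(0.62), "moderate")
  expect_equal(icc_band(0.49), "poor")
  # boundaries assigned upward, deterministically
  expect_equal(icc_band(c(0.5, 0.75, 0.9)),
               c("moderate", "good", "excellent"))
  expect_error(icc_band(1.2), "exceed 1")
})

test_that("Bland-Altman bias and limits of agreement", {
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3))$bias, 0)
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3))$loa, c(0, 0))
  ba <- bland_altman(c(1.1, 0.9) + 1, c(1, 1) + 1)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa, c(-1.96, 1.96) * sd(c(0.1, -0.1)))
  expect_error(bland_altman(1, 1), ">= 2")
  # empirical LoA half-width tracks 1.96 sigma
  set.seed(31)
  sig <- 0.2
  t1 <- rnorm(1000, 5, 0.5); t2 <- t1 + rnorm(1000, 0, sig)
  half <- diff(bland_altman(t1, t2)$loa) / 2
  expect_lt(abs(half - 1.96 * sig) / (1.96 * sig), 0.10)
})

test_that("exact Wilcoxon p equals brute-force sign enumeration", {
  d6 <- c(0.3, -0.1, 0.25, 0.4, -0.05, 0.15)
  got <- paired_wilcoxon(d6 + 1, rep(1, 6))
  expect_true(got$exact)
  expect_equal(got$p_value, brute_signed_rank_p(d6))
  d7 <- c(0.12, -0.31, 0.05, 0.22, -0.18, 0.4, 0.09)
  expect_equal(paired_wilcoxon(d7 + 2, rep(2, 7))$p_value,
               brute_signed_rank_p(d7))
  d8 <- c(0.12, -0.31, 0.05, 0.22, -0.18, 0.4, 0.09, -0.02)
  expect_equal(paired_wilcoxon(d8 + 2, rep(2, 8))$p_value,
               brute_signed_rank_p(d8))
  # all-positive distinct differences at n = 6: two-sided p = 2/2^6
  allpos <- paired_wilcoxon(c(1.1, 1.2, 1.3, 1.4, 1.5, 1.6), rep(1, 6))
  expect_equal(allpos$p_value, 2 / 64)
  # zero differences are dropped; all-zero input is degenerate
  expect_true(paired_wilcoxon(rep(1, 5), rep(1, 5))$degenerate)
  expect_equal(paired_wilcoxon(c(1, 1, d6 + 1), c(1, 1, rep(1, 6)))$n_used,
               6L)
})

test_that("rank statistics match direct computation", {
  expect_equal(rank_association(1:5, (1:5)^3)$rho, 1)
  expect_equal(rank_association(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  set.seed(13)
  x <- rnorm(10); y <- x + rnorm(10)
  expect_equal(rank_association(x, y)$rho, cor(rank(x), rank(y)),
               tolerance = 1e-9)
  expect_true(rank_association(rep(1, 5), rnorm(5))$constant_input)
  kw <- group_difference(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
  expect_equal(kw$statistic,
               unname(kruskal.test(c(1, 2, 3, 7, 8, 9),
                                   factor(rep(c("a", "b"),
                                              each = 3)))$statistic))
  expect_error(group_difference(1:4, rep("a", 4)), "2 groups")
})
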