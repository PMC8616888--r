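test_that("uncertainty score is the interval width and shift-invariant", {
  expect_equal(uncertainty_score(0, 3), 3)
  x <- runif(10)
  expect_equal(uncertainty_score(x, x), rep(0, 10))
  lo <- runif(10)
  hi <- lo + runif(10)
  expect_equal(uncertainty_score(lo + 5, hi + 5), uncertainty_score(lo, hi),
               tolerance = 1e-12)
  expect_error(uncertainty_score(1, 0), "lo")
})

test_that("directionality ratio matches its definition and guards degeneracy", {
  expect_equal(directionality_ratio(0, 2, 1), 1)           # midpoint
  expect_equal(directionality_ratio(0, 3, 1), 2, tolerance = 1e-9)
  expect_true(is.na(directionality_ratio(0, 1, 1)))        # on the boundary
  expect_error(directionality_ratio(0, 1, 2), "inside")
  dr <- directionality_ratio(c(0, 0), c(2, 4), c(0.5, 1))
  expect_equal(dr, c(3, 3), tolerance = 1e-9)
})

test_that("directionality accuracy is 1 when targets always fall in the larger part", {
  set.seed(50)
  n <- 500
  pred <- rep(1, n)
  lo <- pred - runif(n, 0.1, 0.5)
  hi <- pred + (pred - lo) * runif(n, 1.5, 4)   # upper part always larger
  targets <- pred + (hi - pred) * runif(n, 0.1, 0.9)  # in the larger part
  da <- directionality_accuracy(lo, hi, pred, targets, dr_bins = 5)
  expect_true(all(da$da[da$count > 0] == 1))
  expect_equal(sum(da$count), n)
  expect_equal(sum(da$freq), 1, tolerance = 1e-12)
})

test_that("uniform targets in a DR=3 interval give accuracy near 3/4", {
  set.seed(51)
  n <- 20000
  lo <- rep(0, n)
  hi <- rep(4, n)
  pred <- rep(1, n)  # larger part is (1, 4]: 3/4 of the width
  targets <- runif(n, 0, 4)
  da <- directionality_accuracy(lo, hi, pred, targets, dr_bins = c(1, 2.9, 3.1))
  row <- which(da$count > 0)
  expect_length(row, 1)
  tol <- 3 * sqrt(0.75 * 0.25 / n)
  expect_lt(abs(da$da[row] - 0.75), tol)
})

test_that("symmetric intervals with symmetric noise give chance-level accuracy", {
  set.seed(52)
  n <- 20000
  pred <- rnorm(n)
  lo <- pred - 1
  hi <- pred + 1
  targets <- pred + rnorm(n, sd = 0.4)
  da <- directionality_accuracy(lo, hi, pred, targets, dr_bins = c(1, 1.001))
  expect_lt(abs(da$da[1] - 0.5), 3 * sqrt(0.25 / n))
})

test_that("empty bins report missing accuracy, not zero", {
  da <- directionality_accuracy(c(0, 0), c(3, 3), c(1, 1), c(2, 2),
                                dr_bins = c(1, 1.5, 2.5, 10))
  expect_true(is.na(da$da[da$count == 0][1]))
  expect_false(any(da$da[da$count > 0] == 0, na.rm = TRUE))
})

test_that("empirical coverage counts enlarged intervals correctly", {
  x <- runif(20)
  expect_equal(empirical_coverage(x - 0.1, x + 0.1, x, 2, 0.01), 1)
  # scalar hand check: 1.15 < 1 + 2 * 0.1
  expect_equal(empirical_coverage(0, 1, 1.15, 2, 0.1), 1)
  expect_equal(empirical_coverage(0, 1, 1.25, 2, 0.1), 0)
  # lambda = 1 gives the trivial bound 1 - 1/lambda = 0
  expect_gte(empirical_coverage(0, 1, 5, 1, 0.1), 0)
  # nondecreasing in lambda
  set.seed(53)
  lo <- rnorm(100)
  hi <- lo + runif(100)
  tg <- rnorm(100, sd = 2)
  covs <- vapply(c(0.5, 1, 2, 4, 8),
                 function(l) empirical_coverage(lo, hi, tg, l, 0.2),
                 numeric(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("PWCC matches the hand example and degenerates to NA", {
  pred <- c(0, 1, 0, -1)
  target <- rep(0, 4)
  u <- c(0.1, 0.9, 0.1, 0.9)
  expect_equal(pwcc(pred, target, u), 2.0, tolerance = 1e-9)
  # u proportional to the absolute error: correlation 1, PWCC = 1/MSE
  set.seed(54)
  p <- rnorm(50)
  t0 <- rnorm(50)
  u2 <- 3 * abs(p - t0)
  expect_equal(pwcc(p, t0, u2), 1 / mean((p - t0)^2), tolerance = 1e-9)
  expect_true(is.na(pwcc(p, t0, rep(1, 50))))
  expect_error(pwcc(1, 1, 1), "at least 2")
})

test_that("PWCC is permutation invariant and scales inversely with squared residuals", {
  set.seed(55)
  p <- rnorm(40)
  t0 <- rnorm(40)
  u <- abs(rnorm(40))
  v0 <- pwcc(p, t0, u)
  idx <- sample(40)
  expect_equal(pwcc(p[idx], t0[idx], u[idx]), v0, tolerance = 1e-12)
  c_scale <- 2.5
  expect_equal(pwcc(c_scale * p, c_scale * t0, c_scale * u), v0 / c_scale^2,
               tolerance = 1e-9)
})

test_that("heatmap change correlation flags degenerate cases and detects masks", {
  u <- runif(100)
  expect_true(is.na(heatmap_change_correlation(u, u, runif(100))))
  mask <- rep(0, 100)
  mask[40:60] <- 1
  expect_equal(heatmap_change_correlation(u, u + mask, mask), 1,
               tolerance = 1e-12)
  # mask plus small independent noise still correlates strongly
  set.seed(56)
  n <- 512
  mask <- rep(0, n)
  mask[100:149] <- 1
  du <- mask + rnorm(n, sd = 0.1)
  expect_gt(heatmap_change_correlation(rep(0, n), du, mask), 0.9)
})

test_that("uq_report validates its fields", {
  r <- uq_report(runif(10), coverage = c(lambda_2 = 0.9))
  expect_s3_class(r, "uq_report")
  expect_error(uq_report(c(-1, 1)), "nonnegative")
  expect_error(uq_report(runif(3), coverage = 1.2), "0, 1")
})
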