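test_that("MCDrop with dropout rate zero returns zero uncertainty", {
  net <- make_dense_net(c(3, 6, 3), dropout_sites = 1, dropout_rate = 0,
                        seed = 40)
  u <- mcdrop_uncertainty(net, rnorm(3), T = 4, seed = 1)
  expect_equal(as.numeric(u), rep(0, 3))
})

test_that("MCDrop equals the sample standard deviation of the stochastic passes", {
  net <- make_dense_net(c(4, 10, 4), dropout_sites = 1, dropout_rate = 0.4,
                        seed = 41)
  z <- matrix(rnorm(8), 4, 2)
  res <- mcdrop_uncertainty(net, z, T = 16, seed = 5, return_samples = TRUE)
  stacked <- simplify2array(lapply(res$samples, as.numeric))
  expect_equal(as.numeric(res$u), apply(stacked, 1, stats::sd),
               tolerance = 1e-12)
  # reproducibility of the mask stream
  res2 <- mcdrop_uncertainty(net, z, T = 16, seed = 5)
  expect_identical(res$u, res2)
})

test_that("a component observing passes {0, 2} has uncertainty sqrt(2)", {
  # one hidden unit with value 1; dropout at rate 0.5 maps it to 0 (dropped)
  # or 1/(1-0.5) = 2 (kept), so two passes can realise exactly {0, 2}
  net <- prediction_network(
    list(dense_layer(matrix(1), 0, "relu"),
         dense_layer(matrix(1), 0, "identity")),
    dropout_sites = 1, dropout_rate = 0.5)
  found <- FALSE
  for (s in 1:50) {
    res <- mcdrop_uncertainty(net, 1, T = 2, seed = s, return_samples = TRUE)
    vals <- sort(vapply(res$samples, as.numeric, numeric(1)))
    if (identical(vals, c(0, 2))) {
      expect_equal(as.numeric(res$u), sqrt(2), tolerance = 1e-9)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("MCDrop validates its preconditions", {
  net_nodrop <- make_dense_net(c(3, 5, 3), seed = 42)
  expect_error(mcdrop_uncertainty(net_nodrop, rnorm(3)), "dropout")
  net <- make_dense_net(c(3, 5, 3), dropout_sites = 1, seed = 43)
  expect_error(mcdrop_uncertainty(net, rnorm(3), T = 1), "T")
})

test_that("MCDrop estimate stabilises for large numbers of passes", {
  net <- make_dense_net(c(3, 8, 3), dropout_sites = 1, dropout_rate = 0.3,
                        seed = 44)
  z <- rnorm(3)
  u1 <- mean(mcdrop_uncertainty(net, z, T = 4096, seed = 7))
  u2 <- mean(mcdrop_uncertainty(net, z, T = 8192, seed = 8))
  expect_lt(abs(u1 - u2) / u2, 0.05)
})

test_that("ProbOut loss matches hand-computed values", {
  expect_equal(probout_loss(1, 1, 1), 0)
  expect_equal(probout_loss(1, 0, 1), 1, tolerance = 1e-9)
  expect_equal(probout_loss(0, 0, exp(1)), 1, tolerance = 1e-9)
  # batch summation
  expect_equal(probout_loss(c(1, 0), c(0, 0), c(1, exp(1))), 2,
               tolerance = 1e-9)
  expect_error(probout_loss(1, 1, 0), "positive")
})

test_that("ProbOut uncertainty is the square root of the variance", {
  expect_equal(probout_uncertainty(1), 1)
  expect_equal(probout_uncertainty(4), 2)
  v <- sort(runif(10, 0.1, 5))
  expect_true(all(diff(probout_uncertainty(v)) > 0))
  expect_error(probout_uncertainty(c(1, -1)), "positive")
})

test_that("the scalar ProbOut loss is minimised at var equal to the squared residual", {
  # the first-order condition -r^2/s^2 + 1/s = 0 gives s = r^2 on the branch
  # where log(s) >= 0, i.e. for residuals with r^2 >= 1
  for (r in c(1.2, 1.5, 3)) {
    opt <- stats::optimize(function(v) probout_loss(r, 0, v),
                           interval = c(1e-6, 50), tol = 1e-10)
    expect_equal(opt$minimum, r^2, tolerance = 1e-4)
  }
  # below r = 1 the l1 penalty's kink at var = 1 is the minimiser: the
  # penalty decreases toward 1 faster than the data term can compensate
  for (r in c(0.3, 0.7)) {
    opt <- stats::optimize(function(v) probout_loss(r, 0, v),
                           interval = c(1e-6, 50), tol = 1e-10)
    expect_equal(opt$minimum, 1, tolerance = 1e-4)
  }
})

test_that("ProbOut networks train and produce positive variances", {
  set.seed(45)
  n <- 32
  z <- matrix(runif(n * 60), n, 60)
  x <- 0.5 * z + matrix(rnorm(n * 60, sd = 0.05), n, 60)
  net <- make_probout_net(n_layers = 3, channels = 6, kernel_size = 3,
                          dropout_sites = 2, seed = 46)
  net <- train_probout(net, z, x, training_config(epochs = 15, batch_size = 16,
                                                  learning_rate = 3e-3,
                                                  seed = 47))
  pr <- probout_predict(net, z)
  expect_true(all(pr$var > 0))
  expect_equal(dim(pr$mean), dim(x))
  hist <- attr(net, "history")
  expect_lt(hist[length(hist)], hist[1])
})
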