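test_that("interval_box enforces its invariants", {
  b <- interval_box(c(0, 1), c(1, 2))
  expect_equal(interval_width(b), c(1, 1))
  expect_error(interval_box(c(0, 2), c(1, 1)), "lower <= upper")
  expect_error(interval_box(1, c(1, 2)), "identical shapes")
})

test_that("point parameter intervals reduce both rules to the base layer", {
  set.seed(3)
  W <- matrix(rnorm(12), 3, 4)
  b <- rnorm(3)
  z <- rnorm(4)
  W_box <- interval_box(W, W)
  b_box <- interval_box(b, b)
  out <- propagate_point_input(W_box, b_box, z, "relu")
  expect_equal(as.numeric(out$lower), as.numeric(pmax(W %*% z + b, 0)),
               tolerance = 1e-12)
  expect_equal(out$lower, out$upper, tolerance = 1e-12)

  z_pos <- abs(z)
  out2 <- propagate_nonneg_interval(W_box, b_box, interval_box(z_pos, z_pos),
                                    "relu")
  expect_equal(as.numeric(out2$lower), as.numeric(pmax(W %*% z_pos + b, 0)),
               tolerance = 1e-12)
  expect_equal(out2$lower, out2$upper, tolerance = 1e-12)
})

test_that("1x1 layer examples match the corner-sampling oracle exactly", {
  W_box <- interval_box(matrix(1), matrix(2))
  b_box <- interval_box(0, 0)

  # signed point input: pre-activation [-2, -1], ReLU clips to [0, 0]
  out <- propagate_point_input(W_box, b_box, -1, "relu")
  expect_equal(as.numeric(out$lower), 0, tolerance = 1e-9)
  expect_equal(as.numeric(out$upper), 0, tolerance = 1e-9)

  # positive point input: [0.5, 1]
  out <- propagate_point_input(W_box, b_box, 0.5, "relu")
  expect_equal(as.numeric(out$lower), 0.5, tolerance = 1e-9)
  expect_equal(as.numeric(out$upper), 1, tolerance = 1e-9)

  # sign-crossing weight interval, nonnegative input interval: [0, 1]
  out <- propagate_nonneg_interval(interval_box(matrix(-1), matrix(1)), b_box,
                                   interval_box(0.5, 1), "relu")
  expect_equal(as.numeric(out$lower), 0, tolerance = 1e-9)
  expect_equal(as.numeric(out$upper), 1, tolerance = 1e-9)

  # positive weight interval: [0.5, 2]
  out <- propagate_nonneg_interval(W_box, b_box, interval_box(0.5, 1), "relu")
  expect_equal(as.numeric(out$lower), 0.5, tolerance = 1e-9)
  expect_equal(as.numeric(out$upper), 2, tolerance = 1e-9)
})

test_that("propagation rules equal the corner-enumeration oracle on random layers", {
  for (seed in 1:8) {
    set.seed(seed)
    for (d in c(1, 2)) {
      W <- matrix(rnorm(d * d), d, d)
      dW <- matrix(abs(rnorm(d * d, sd = 0.4)), d, d)
      b <- rnorm(d)
      db <- abs(rnorm(d, sd = 0.2))
      W_box <- interval_box(W - dW, W + dW)
      b_box <- interval_box(b - db, b + db)
      for (act in c("relu", "identity")) {
        z <- rnorm(d)
        got <- propagate_point_input(W_box, b_box, z, act)
        want <- corner_oracle(W_box$lower, W_box$upper, b_box$lower,
                              b_box$upper, z, z, act)
        expect_equal(as.numeric(got$lower), as.numeric(want$lo),
                     tolerance = 1e-9)
        expect_equal(as.numeric(got$upper), as.numeric(want$hi),
                     tolerance = 1e-9)

        z_lo <- abs(rnorm(d, sd = 0.5))
        z_hi <- z_lo + abs(rnorm(d, sd = 0.5))
        got <- propagate_nonneg_interval(W_box, b_box,
                                         interval_box(z_lo, z_hi), act)
        want <- corner_oracle(W_box$lower, W_box$upper, b_box$lower,
                              b_box$upper, z_lo, z_hi, act)
        expect_equal(as.numeric(got$lower), as.numeric(want$lo),
                     tolerance = 1e-9)
        expect_equal(as.numeric(got$upper), as.numeric(want$hi),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("propagation rules enforce their preconditions", {
  W_box <- interval_box(matrix(1, 2, 3), matrix(2, 2, 3))
  b_box <- interval_box(rep(0, 2), rep(0, 2))
  expect_error(propagate_point_input(W_box, b_box, rnorm(5)), "features")
  expect_error(
    propagate_nonneg_interval(W_box, b_box,
                              interval_box(c(-0.1, 0, 0), c(1, 1, 1))),
    "nonneg")
})

test_that("wrap_network at zero width reproduces the base network", {
  net <- make_dense_net(c(4, 8, 8, 4), seed = 7)
  inn <- wrap_network(net, init_width = 0, eps0 = 0)
  z <- matrix(rnorm(12), 4, 3)
  res <- forward_interval(inn, z)
  expect_equal(res$lower, res$prediction, tolerance = 1e-12)
  expect_equal(res$upper, res$prediction, tolerance = 1e-12)
})

test_that("wrap_network places base parameters strictly inside positive-width intervals", {
  net <- make_dense_net(c(3, 6, 3), seed = 8)
  inn <- wrap_network(net, init_width = 0.01)
  for (i in seq_along(net$layers)) {
    expect_true(all(inn$params[[i]]$W_lo < net$layers[[i]]$W))
    expect_true(all(inn$params[[i]]$W_hi > net$layers[[i]]$W))
    expect_true(all(inn$params[[i]]$b_lo < net$layers[[i]]$b))
    expect_true(all(inn$params[[i]]$b_hi > net$layers[[i]]$b))
  }
  set.seed(9)
  for (r in 1:10) {
    z <- rnorm(3)
    res <- forward_interval(inn, z)
    expect_true(all(res$lower <= res$prediction))
    expect_true(all(res$prediction <= res$upper))
  }
  expect_error(wrap_network(net, interval_layers = c(1, 5)), "subset")
})

test_that("interval forward pass is sound under random parameter selections", {
  net <- make_dense_net(c(3, 8, 8, 3), seed = 10)
  inn <- wrap_network(net, init_width = 0.1, eps0 = 0.01)
  set.seed(20)
  z <- rnorm(3)
  res <- forward_interval(inn, z)
  for (r in 1:1000) {
    sel <- sample_network_in_intervals(inn)
    out <- predict_network(sel, z)
    expect_true(all(out >= res$lower))
    expect_true(all(out <= res$upper))
  }
})

test_that("widening a parameter interval never shrinks the output interval", {
  net <- make_dense_net(c(3, 6, 3), seed = 12)
  inn <- wrap_network(net, init_width = 0.05, eps0 = 0.01)
  set.seed(13)
  z <- rnorm(3)
  base_res <- forward_interval(inn, z)
  for (li in seq_along(inn$params)) {
    for (r in 1:5) {
      inn2 <- inn
      idx <- sample(length(inn2$params[[li]]$W_lo), 1)
      inn2$params[[li]]$W_lo[idx] <- inn2$params[[li]]$W_lo[idx] - 0.2
      inn2$params[[li]]$W_hi[idx] <- inn2$params[[li]]$W_hi[idx] + 0.3
      res2 <- forward_interval(inn2, z)
      expect_true(all(res2$lower <= base_res$lower + 1e-12))
      expect_true(all(res2$upper >= base_res$upper - 1e-12))
    }
  }
})

test_that("containment holds on convolutional networks with signed inputs", {
  net <- make_conv_net(n_layers = 4, channels = 6, kernel_size = 3,
                       dropout_sites = 2, seed = 14)
  inn <- wrap_network(net, init_width = 0.02)
  set.seed(15)
  z <- matrix(rnorm(20 * 4), 20, 4)  # signed inputs
  res <- forward_interval(inn, z)
  expect_true(all(res$lower <= res$prediction))
  expect_true(all(res$prediction <= res$upper))
  expect_true(all(res$upper - res$lower >= 0))
})

test_that("a trailing interval suffix gives the same bounds as point intervals up front", {
  net <- make_conv_net(n_layers = 4, channels = 5, kernel_size = 3,
                       dropout_sites = 2, seed = 16)
  inn_suffix <- wrap_network(net, interval_layers = 3:4, init_width = 0.05,
                             eps0 = 0.01)
  inn_full <- wrap_network(net, interval_layers = 1:4, init_width = 0,
                           eps0 = 0)
  inn_full$params[3:4] <- inn_suffix$params[3:4]
  set.seed(17)
  z <- matrix(rnorm(16 * 2), 16, 2)
  rs <- forward_interval(inn_suffix, z)
  rf <- forward_interval(inn_full, z)
  expect_equal(rs$lower, rf$lower, tolerance = 1e-12)
  expect_equal(rs$upper, rf$upper, tolerance = 1e-12)
  expect_true(all(rs$lower <= rs$prediction & rs$prediction <= rs$upper))
})

test_that("forward_interval refuses to run when the box constraints are violated", {
  net <- make_dense_net(c(3, 5, 3), seed = 18)
  inn <- wrap_network(net)
  inn$params[[2]]$W_lo[1, 1] <- net$layers[[2]]$W[1, 1] + 1
  expect_error(forward_interval(inn, rnorm(3)), "constraints violated")
})
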