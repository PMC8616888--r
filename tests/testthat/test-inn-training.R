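test_that("interval loss matches hand-computed values", {
  # target above the interval plus width penalty
  expect_equal(interval_loss(1.0, 0.2, 0.8, 0.1),
               (1.0 - 0.8)^2 + 0.1 * 0.6, tolerance = 1e-9)
  # target below the interval, no width penalty
  expect_equal(interval_loss(0.0, 0.2, 0.8, 0), 0.2^2, tolerance = 1e-9)
  # covered target, beta = 0: loss vanishes
  x <- runif(10)
  expect_equal(interval_loss(x, x - 0.1, x + 0.1, 0), 0)
  # batch summation
  expect_equal(interval_loss(c(1, 0), c(0.2, 0.2), c(0.8, 0.8), 0.1),
               0.04 + 0.04 + 0.1 * 1.2, tolerance = 1e-9)
  expect_error(interval_loss(0.5, 0.8, 0.2, 0), "lo")
})

test_that("projection clamps intervals against the frozen base parameters", {
  net <- make_dense_net(c(2, 4, 2), seed = 21)
  inn <- wrap_network(net, init_width = 0.1)
  expect_equal(project_constraints(inn)$params, inn$params, tolerance = 0)

  inn2 <- inn
  inn2$params[[1]]$W_lo[1, 1] <- net$layers[[1]]$W[1, 1] + 0.5
  inn2$params[[2]]$b_hi[2] <- net$layers[[2]]$b[2] - 0.5
  proj <- project_constraints(inn2)
  expect_equal(proj$params[[1]]$W_lo[1, 1], net$layers[[1]]$W[1, 1])
  expect_equal(proj$params[[2]]$b_hi[2], net$layers[[2]]$b[2])
  expect_silent(forward_interval(proj, rnorm(2)))
})

test_that("scalar clamp example: proposed lower bound above the weight is pulled back", {
  net <- prediction_network(list(dense_layer(matrix(1.0), 0, "identity")))
  inn <- wrap_network(net, eps0 = 0)
  inn$params[[1]]$W_lo[1, 1] <- 1.5
  proj <- project_constraints(inn)
  expect_equal(proj$params[[1]]$W_lo[1, 1], 1.0)
})

toy <- make_toy_problem(n_samples = 200, d = 6, seed = 11)
toy_net <- train_network(make_dense_net(c(6, 24, 24, 6), seed = 22),
                         toy$z, toy$x,
                         training_config(epochs = 60, batch_size = 32,
                                         learning_rate = 3e-3, seed = 22))

test_that("an extreme width penalty collapses the intervals", {
  inn <- wrap_network(toy_net)
  inn_big_beta <- train_inn(inn, toy$z, toy$x,
                            training_config(beta = 1e6, epochs = 40,
                                            batch_size = 32,
                                            learning_rate = 3e-3, seed = 23))
  res0 <- forward_interval(inn, toy$z)
  res1 <- forward_interval(inn_big_beta, toy$z)
  w0 <- mean(uncertainty_score(res0$lower, res0$upper))
  w1 <- mean(uncertainty_score(res1$lower, res1$upper))
  expect_lt(w1, 10 * w0)
})

test_that("beta = 0 lets intervals grow to cover nearly all training targets", {
  inn <- wrap_network(toy_net)
  inn0 <- train_inn(inn, toy$z, toy$x,
                    training_config(beta = 0, epochs = 120, batch_size = 32,
                                    learning_rate = 3e-3, seed = 24))
  res <- forward_interval(inn0, toy$z)
  cov <- mean(toy$x >= res$lower & toy$x <= res$upper)
  expect_gte(cov, 0.99)
})

test_that("interval training never touches the base network", {
  before <- predict_network(toy_net, toy$z)
  inn <- train_inn(wrap_network(toy_net), toy$z, toy$x,
                   training_config(beta = 0.01, epochs = 5, batch_size = 32,
                                   seed = 25))
  expect_identical(predict_network(inn$base, toy$z), before)
})

test_that("containment holds after optimizer steps (projection keeps it valid)", {
  inn <- train_inn(wrap_network(toy_net), toy$z, toy$x,
                   training_config(beta = 0.01, epochs = 3, batch_size = 16,
                                   seed = 26))
  set.seed(27)
  z_new <- matrix(rnorm(6 * 50), 6, 50)
  res <- forward_interval(inn, z_new)
  expect_true(all(res$lower <= res$prediction))
  expect_true(all(res$prediction <= res$upper))
})

test_that("larger beta does not increase mean interval width", {
  widths <- vapply(c(1e-4, 1e-2, 1), function(b) {
    inn <- train_inn(wrap_network(toy_net), toy$z, toy$x,
                     training_config(beta = b, epochs = 60, batch_size = 32,
                                     learning_rate = 3e-3, seed = 28))
    res <- forward_interval(inn, toy$z)
    mean(uncertainty_score(res$lower, res$upper))
  }, numeric(1))
  expect_lte(widths[2], widths[1] * 1.05)
  expect_lte(widths[3], widths[2] * 1.05)
})

test_that("training is reproducible under a fixed seed", {
  cfg <- training_config(beta = 0.01, epochs = 3, batch_size = 32, seed = 29)
  inn_a <- train_inn(wrap_network(toy_net), toy$z, toy$x, cfg)
  inn_b <- train_inn(wrap_network(toy_net), toy$z, toy$x, cfg)
  expect_identical(inn_a$params, inn_b$params)
  net_a <- train_network(make_dense_net(c(6, 12, 6), seed = 30), toy$z, toy$x,
                         training_config(epochs = 3, seed = 31))
  net_b <- train_network(make_dense_net(c(6, 12, 6), seed = 30), toy$z, toy$x,
                         training_config(epochs = 3, seed = 31))
  expect_identical(net_a$layers, net_b$layers)
})

test_that("select_beta returns the base network's mean absolute error", {
  # perfect predictor: floored at 1e-8
  id_net <- prediction_network(list(dense_layer(diag(3), rep(0, 3),
                                                "identity")))
  z <- matrix(runif(9), 3, 3)
  expect_equal(select_beta(id_net, z, z), 1e-8)
  # constant zero prediction against constant 0.5 targets
  zero_net <- prediction_network(list(dense_layer(matrix(0, 3, 3), rep(0, 3),
                                                  "identity")))
  x <- matrix(0.5, 3, 5)
  expect_equal(select_beta(zero_net, matrix(runif(15), 3, 5), x), 0.5,
               tolerance = 1e-12)
})

test_that("training reports a loss history and rejects bad configs", {
  expect_length(attr(toy_net, "history"), 60)
  expect_true(all(is.finite(attr(toy_net, "history"))))
  expect_error(training_config(epochs = 0), "epochs")
  expect_error(training_config(beta = -1), "beta")
})
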