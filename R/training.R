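# Optimisation: Adam on nested parameter lists, base-network training (MSE,
# dropout active), and post-hoc interval training with the hinge-plus-width
# loss under the box constraints (projection after every step).

#' Training configuration
#'
#' @param beta Nonnegative tightness parameter: weight of the l1 penalty on
#'   interval width. `NULL` lets [train_inn()] fall back to the interval
#'   network's stored value or to [select_beta()].
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling data order, dropout masks and any
#'   initialisation inside the training run; `NULL` uses the current RNG.
#' @param interval_layers Optional layer selector for interval training
#'   (passed to [wrap_network()] semantics); `NULL` keeps the wrapped choice.
#' @return A list of class `training_config`.
#' @export
training_config <- function(beta = NULL, epochs = 100, batch_size = 32,
                            learning_rate = 1e-3, seed = NULL,
                            interval_layers = NULL) {
  if (!is.null(beta) && beta < 0) stop_contract("`beta` must be nonnegative")
  if (epochs < 1) stop_contract("`epochs` must be >= 1")
  if (batch_size < 1) stop_contract("`batch_size` must be >= 1")
  if (learning_rate <= 0) stop_contract("`learning_rate` must be positive")
  structure(
    list(beta = beta, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = seed,
         interval_layers = interval_layers),
    class = "training_config"
  )
}

# ---- Adam on nested lists of arrays ------------------------------------------

adam_init <- function(params) {
  zero <- function(p) lapply(p, function(x) x * 0)
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g * g
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (state$m[[i]][[nm]] / c1) / (sqrt(state$v[[i]][[nm]] / c2) + eps)
    }
  }
  list(params = params, state = state)
}

# Canonicalise paired training arrays for a network; returns canonical z and
# x plus the batch count.
canonical_pair <- function(net, z, x) {
  zc <- canonical_input(net, z)
  if (net$kind == "dense") {
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    if (ncol(x) != ncol(zc)) stop_contract("z and x batch sizes differ")
    list(z = zc, x = x, n = ncol(zc))
  } else {
    if (is.null(dim(x))) x <- array(x, dim = c(1, length(x), 1))
    if (is.matrix(x)) x <- array(x, dim = c(1, nrow(x), ncol(x)))
    if (dim(x)[3] != dim(zc)[3]) stop_contract("z and x batch sizes differ")
    list(z = zc, x = x, n = dim(zc)[3])
  }
}

take_batch <- function(kind, a, idx) {
  if (kind == "dense") a[, idx, drop = FALSE] else a[, , idx, drop = FALSE]
}

#' Train a prediction network (mean squared error)
#'
#' Standard supervised training of the reconstruction network with Adam and
#' minibatches; dropout sites are active during training. The per-epoch mean
#' squared training error is returned as the `history` attribute.
#'
#' @param net A [prediction_network()].
#' @param z,x Paired inputs and targets: `n x batch` matrices for
#'   single-channel signals (or canonical arrays).
#' @param cfg A [training_config()].
#' @return The trained network, with attribute `history`.
#' @export
train_network <- function(net, z, x, cfg = training_config()) {
  dat <- canonical_pair(net, z, x)
  with_seed(cfg$seed, {
    params <- lapply(net$layers, function(l) list(W = l$W, b = l$b))
    state <- adam_init(params)
    history <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(dat$n)
      tot <- 0
      for (start in seq(1, dat$n, by = cfg$batch_size)) {
        bi <- idx[start:min(start + cfg$batch_size - 1, dat$n)]
        zb <- take_batch(net$kind, dat$z, bi)
        xb <- take_batch(net$kind, dat$x, bi)
        fw <- net_forward_internal(net, zb, dropout = TRUE, keep_cache = TRUE)
        resid <- fw$out - as.numeric(xb)
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop_contract("training loss became non-finite at epoch %d", ep)
        }
        tot <- tot + loss * length(bi)
        d_out <- 2 * resid / length(resid)
        bw <- net_backward_internal(net, fw$cache, d_out)
        upd <- adam_step(params, bw$grads, state, cfg$learning_rate)
        params <- upd$params
        state <- upd$state
        for (i in seq_along(net$layers)) {
          net$layers[[i]]$W <- params[[i]]$W
          net$layers[[i]]$b <- params[[i]]$b
        }
      }
      history[ep] <- tot / dat$n
    }
    attr(net, "history") <- history
    net
  })
}

#' Interval training loss (hinge outside the interval plus width penalty)
#'
#' For targets `x` and predicted bounds `[lo, hi]`, returns
#' `sum(max(x - hi, 0)^2) + sum(max(lo - x, 0)^2) + beta * sum(hi - lo)`:
#' components outside the interval are penalised by their squared distance to
#' the nearest bound and the l1 norm of the width keeps intervals tight.
#'
#' @param x Target array.
#' @param lo,hi Lower/upper prediction bounds (same shape as `x`,
#'   `lo <= hi` component-wise).
#' @param beta Nonnegative width penalty.
#' @return Nonnegative scalar loss.
#' @export
interval_loss <- function(x, lo, hi, beta) {
  check_same_shape(x, lo, "x", "lo")
  check_same_shape(x, hi, "x", "hi")
  if (any(lo > hi)) stop_contract("`lo` must not exceed `hi`")
  if (beta < 0) stop_contract("`beta` must be nonnegative")
  sum(pmax(x - hi, 0)^2) + sum(pmax(lo - x, 0)^2) + beta * sum(hi - lo)
}

#' Project interval parameters onto the feasible box
#'
#' Clamps every interval against the frozen base parameters:
#' `W_lo <- min(W_lo, W)`, `W_hi <- max(W_hi, W)` (biases analogously), so
#' that the constraints `W_lo <= W <= W_hi` hold exactly afterwards. Applied
#' after every optimiser step during interval training.
#'
#' @param inn An interval network.
#' @return The projected interval network.
#' @export
project_constraints <- function(inn) {
  for (i in seq_along(inn$params)) {
    l <- inn$base$layers[[i]]
    inn$params[[i]]$W_lo <- pmin(inn$params[[i]]$W_lo, l$W)
    inn$params[[i]]$W_hi <- pmax(inn$params[[i]]$W_hi, l$W)
    inn$params[[i]]$b_lo <- pmin(inn$params[[i]]$b_lo, l$b)
    inn$params[[i]]$b_hi <- pmax(inn$params[[i]]$b_hi, l$b)
  }
  inn
}

#' Tightness parameter heuristic
#'
#' Returns the mean absolute prediction error of the base network over the
#' given samples (floored at `1e-8`), the recommended order of magnitude for
#' the width penalty `beta`.
#'
#' @param net A trained [prediction_network()].
#' @param z,x Paired inputs and targets.
#' @param floor Lower bound on the returned value.
#' @return A positive scalar.
#' @export
select_beta <- function(net, z, x, floor = 1e-8) {
  dat <- canonical_pair(net, z, x)
  pred <- net_forward_internal(net, dat$z, dropout = FALSE)$out
  max(mean(abs(pred - as.numeric(dat$x))), floor)
}

#' Train the interval parameters of a wrapped network
#'
#' Post-hoc optimisation of the weight/bias intervals with the base network
#' frozen: Adam steps on the [interval_loss()] followed by exact projection
#' onto the box constraints after every step, so the containment guarantee
#' holds at all times. Only layers in `inn$interval_layers` are updated.
#'
#' @param inn An interval network from [wrap_network()].
#' @param z,x Paired training inputs and targets.
#' @param cfg A [training_config()]; `cfg$beta` overrides the network's
#'   stored tightness, and if both are missing [select_beta()] is used.
#' @return The trained interval network, with per-epoch total loss in the
#'   `history` attribute and the resolved `beta` stored on the network.
#' @export
train_inn <- function(inn, z, x, cfg = training_config()) {
  if (!inherits(inn, "interval_network")) {
    stop_contract("`inn` must be an interval_network")
  }
  net <- inn$base
  dat <- canonical_pair(net, z, x)
  beta <- cfg$beta %||% (if (is.finite(inn$beta)) inn$beta else NULL) %||%
    select_beta(net, z, x)
  inn$beta <- beta
  with_seed(cfg$seed, {
    trainable <- inn$interval_layers
    params <- lapply(inn$params, function(p) p)
    state <- adam_init(params[trainable])
    history <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(dat$n)
      tot <- 0
      for (start in seq(1, dat$n, by = cfg$batch_size)) {
        bi <- idx[start:min(start + cfg$batch_size - 1, dat$n)]
        zb <- take_batch(net$kind, dat$z, bi)
        xb <- as.numeric(take_batch(net$kind, dat$x, bi))
        fw <- inn_forward_internal(inn, zb, keep_cache = TRUE)
        lo <- as.numeric(fw$lo)
        hi <- as.numeric(fw$hi)
        r_hi <- pmax(xb - hi, 0)
        r_lo <- pmax(lo - xb, 0)
        loss <- sum(r_hi^2) + sum(r_lo^2) + beta * sum(hi - lo)
        if (!is.finite(loss)) {
          stop_contract("interval training loss became non-finite at epoch %d", ep)
        }
        tot <- tot + loss
        d_hi <- -2 * r_hi + beta
        d_lo <- 2 * r_lo - beta
        gr <- inn_backward_internal(inn, fw$cache, d_lo, d_hi)
        upd <- adam_step(params[trainable], gr[trainable], state,
                         cfg$learning_rate)
        params[trainable] <- upd$params
        state <- upd$state
        inn$params <- params
        inn <- project_constraints(inn)
        params <- inn$params
      }
      history[ep] <- tot
    }
    attr(inn, "history") <- history
    inn
  })
}
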