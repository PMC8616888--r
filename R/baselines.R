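# Baseline uncertainty quantification methods: Monte Carlo dropout sample
# standard deviation (MCDrop) and direct variance estimation with a doubled
# mean/variance output head (ProbOut).

#' Monte Carlo dropout uncertainty
#'
#' Runs `T` stochastic forward passes with independently drawn dropout masks
#' and returns the component-wise sample standard deviation
#' `sqrt( (sum(out^2) - sum(out)^2 / T) / (T - 1) )`.
#'
#' @param net A [prediction_network()] with at least one dropout site.
#' @param z Input signal(s), as in [predict_network()].
#' @param T Number of stochastic passes (`>= 2`).
#' @param seed Optional seed for the dropout mask stream.
#' @param return_samples If `TRUE`, also return the individual passes
#'   (stacked along the last dimension) for diagnostics.
#' @return Nonnegative array of uncertainty scores (shape of the prediction),
#'   or a list with `u` and `samples` when `return_samples = TRUE`.
#' @export
mcdrop_uncertainty <- function(net, z, T = 64, seed = NULL,
                               return_samples = FALSE) {
  if (!inherits(net, "prediction_network")) {
    stop_contract("`net` must be a prediction_network")
  }
  if (length(net$dropout_sites) == 0) {
    stop_contract("MCDrop requires a network with dropout sites")
  }
  if (T < 2) stop_contract("`T` must be >= 2 (sample variance undefined)")
  T <- as.integer(T)
  x <- canonical_input(net, z)
  with_seed(seed, {
    s1 <- NULL
    s2 <- NULL
    samples <- if (return_samples) vector("list", T)
    for (t in seq_len(T)) {
      out <- net_forward_internal(net, x, dropout = TRUE)$out
      if (is.null(s1)) {
        s1 <- out
        s2 <- out^2
      } else {
        s1 <- s1 + out
        s2 <- s2 + out^2
      }
      if (return_samples) samples[[t]] <- out
    }
    u <- sqrt(pmax((s2 - s1^2 / T) / (T - 1), 0))
    if (net$kind == "conv1d") u <- canonical_output(u)
    if (return_samples) {
      list(u = u, samples = samples)
    } else {
      u
    }
  })
}

#' Direct variance estimation network
#'
#' Convenience constructor for the ProbOut architecture: the reconstruction
#' trunk with a doubled output head, channel 1 predicting the mean and
#' channel 2 the log-variance (exponentiated on read-out so the variance is
#' unconditionally positive).
#'
#' @inheritParams make_conv_net
#' @return A [prediction_network()] with two output channels.
#' @export
make_probout_net <- function(n_layers = 10, channels = 32, kernel_size = 5,
                             in_channels = 1, dropout_sites = c(3, 5, 7),
                             dropout_rate = 0.1, seed = NULL) {
  make_conv_net(n_layers = n_layers, channels = channels,
                kernel_size = kernel_size, in_channels = in_channels,
                out_channels = 2, dropout_sites = dropout_sites,
                dropout_rate = dropout_rate, seed = seed)
}

# Split the doubled output head into mean and log-variance matrices.
probout_heads <- function(out) {
  if (length(dim(out)) != 3 || dim(out)[1] != 2) {
    stop_contract("a ProbOut network must have exactly 2 output channels")
  }
  list(mean = matrix(out[1, , ], dim(out)[2], dim(out)[3]),
       logvar = matrix(out[2, , ], dim(out)[2], dim(out)[3]))
}

#' Evaluate a ProbOut network
#'
#' @param net A two-output-channel network from [make_probout_net()].
#' @param z Input signal(s).
#' @return List with `mean` and `var` (positive), each `n x batch`.
#' @export
probout_predict <- function(net, z) {
  x <- canonical_input(net, z)
  out <- net_forward_internal(net, x, dropout = FALSE)$out
  h <- probout_heads(out)
  list(mean = h$mean, var = exp(h$logvar))
}

#' Gaussian-likelihood-style loss for direct variance estimation
#'
#' `sum(((x - mean) / sqrt(var))^2) + sum(abs(log(var)))`, summed over the
#' batch.
#'
#' @param x Targets.
#' @param mean,var Predicted mean and (strictly positive) variance, same
#'   shape as `x`.
#' @return Scalar loss.
#' @export
probout_loss <- function(x, mean, var) {
  check_same_shape(x, mean, "x", "mean")
  check_same_shape(x, var, "x", "var")
  if (any(var <= 0)) stop_contract("`var` must be strictly positive")
  sum((x - mean)^2 / var) + sum(abs(log(var)))
}

#' ProbOut uncertainty score
#'
#' @param var Positive variance array.
#' @return `sqrt(var)` component-wise.
#' @export
probout_uncertainty <- function(var) {
  if (any(var <= 0)) stop_contract("`var` must be strictly positive")
  sqrt(var)
}

#' Train a ProbOut network
#'
#' Trains the doubled-head network from scratch (dropout active, Adam) by
#' minimising the [probout_loss()], with the variance parametrised as a
#' log-variance output channel. The per-epoch total loss is returned as the
#' `history` attribute.
#'
#' @param net A [make_probout_net()] network.
#' @param z,x Paired inputs and targets (`x` single-channel).
#' @param cfg A [training_config()].
#' @return The trained network.
#' @export
train_probout <- function(net, z, x, cfg = training_config()) {
  xc <- if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
  zc <- canonical_input(net, z)
  if (ncol(xc) != dim(zc)[3]) stop_contract("z and x batch sizes differ")
  with_seed(cfg$seed, {
    params <- lapply(net$layers, function(l) list(W = l$W, b = l$b))
    state <- adam_init(params)
    history <- numeric(cfg$epochs)
    n <- dim(zc)[3]
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      tot <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        bi <- idx[start:min(start + cfg$batch_size - 1, n)]
        zb <- zc[, , bi, drop = FALSE]
        xb <- xc[, bi, drop = FALSE]
        fw <- net_forward_internal(net, zb, dropout = TRUE, keep_cache = TRUE)
        mu <- fw$out[1, , , drop = FALSE]
        s <- fw$out[2, , , drop = FALSE]
        # numeric safeguard: bound the log-variance used inside exp()
        e <- exp(-pmin(pmax(s, -30), 30))
        r <- array(xb, dim = dim(mu)) - mu
        loss <- sum(r^2 * e) + sum(abs(s))
        if (!is.finite(loss)) {
          stop_contract("ProbOut training loss became non-finite at epoch %d", ep)
        }
        tot <- tot + loss
        d_out <- array(0, dim = dim(fw$out))
        d_out[1, , ] <- -2 * r * e
        d_out[2, , ] <- -r^2 * e + sign(s)
        bw <- net_backward_internal(net, fw$cache, d_out)
        upd <- adam_step(params, bw$grads, state, cfg$learning_rate)
        params <- upd$params
        state <- upd$state
        for (i in seq_along(net$layers)) {
          net$layers[[i]]$W <- params[[i]]$W
          net$layers[[i]]$b <- params[[i]]$b
        }
      }
      history[ep] <- tot
    }
    attr(net, "history") <- history
    net
  })
}
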