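# Feed-forward prediction networks (dense and 1D convolution layers with ReLU
# hidden activations), their forward/backward passes, and He initialisation.
# Activations are stored batch-last: dense layers work on (features x batch)
# matrices, convolution layers on (channels x length x batch) arrays.

#' Dense (fully connected) layer
#'
#' @param W Weight matrix, `out_features x in_features`.
#' @param b Bias vector of length `out_features`.
#' @param activation `"relu"` for hidden layers or `"identity"` for the
#'   output layer.
#' @return A layer object usable in [prediction_network()].
#' @export
dense_layer <- function(W, b, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  check_numeric_array(W, "W")
  check_numeric_array(b, "b")
  if (!is.matrix(W)) stop_contract("`W` must be a matrix")
  if (length(b) != nrow(W)) {
    stop_contract("`b` must have length nrow(W) = %d, got %d", nrow(W), length(b))
  }
  structure(
    list(type = "dense", W = W, b = as.numeric(b), activation = activation),
    class = "innuq_layer"
  )
}

#' 1D convolution layer
#'
#' Zero-padded ("same") cross-correlation with an odd-sized kernel, so the
#' signal length is preserved.
#'
#' @param W Kernel array, `out_channels x in_channels x kernel_size`
#'   (kernel size must be odd).
#' @param b Bias vector of length `out_channels`.
#' @inheritParams dense_layer
#' @return A layer object usable in [prediction_network()].
#' @export
conv1d_layer <- function(W, b, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  check_numeric_array(W, "W")
  check_numeric_array(b, "b")
  if (length(dim(W)) != 3) {
    stop_contract("`W` must be a 3D array (out_channels x in_channels x kernel)")
  }
  if (dim(W)[3] %% 2 == 0) stop_contract("kernel size must be odd")
  if (length(b) != dim(W)[1]) {
    stop_contract("`b` must have length dim(W)[1] = %d", dim(W)[1])
  }
  structure(
    list(type = "conv1d", W = W, b = as.numeric(b), activation = activation),
    class = "innuq_layer"
  )
}

layer_out_features <- function(layer) {
  if (layer$type == "dense") nrow(layer$W) else dim(layer$W)[1]
}

layer_in_features <- function(layer) {
  if (layer$type == "dense") ncol(layer$W) else dim(layer$W)[2]
}

#' Assemble a prediction network
#'
#' A feed-forward network of dense or 1D-convolution layers. All hidden
#' activations must be ReLU (the interval propagation rules rely on
#' nonnegative hidden activations); the final layer may be `"identity"`.
#' Dropout sites mark positions (after a layer's activation) where stochastic
#' masking is applied during training and by [mcdrop_uncertainty()]; with
#' dropout disabled the network is deterministic.
#'
#' @param layers List of layers from [dense_layer()] / [conv1d_layer()]
#'   (all of the same type).
#' @param dropout_sites Integer vector of layer indices after which dropout
#'   masks are applied.
#' @param dropout_rate Dropout probability in `[0, 1)`.
#' @return An object of class `prediction_network`.
#' @export
prediction_network <- function(layers, dropout_sites = integer(0),
                               dropout_rate = 0.1) {
  if (length(layers) == 0) stop_contract("`layers` must be nonempty")
  types <- vapply(layers, function(l) l$type, character(1))
  if (length(unique(types)) != 1) {
    stop_contract("all layers must share one type (dense or conv1d)")
  }
  n <- length(layers)
  for (i in seq_len(n - 1)) {
    if (layers[[i]]$activation != "relu") {
      stop_contract("hidden layer %d must use ReLU activation", i)
    }
    if (layer_out_features(layers[[i]]) != layer_in_features(layers[[i + 1]])) {
      stop_contract("layer %d output size does not match layer %d input size",
                    i, i + 1)
    }
  }
  dropout_sites <- as.integer(dropout_sites)
  if (length(dropout_sites) &&
      (any(dropout_sites < 1) || any(dropout_sites >= n))) {
    stop_contract("dropout sites must lie strictly inside the layer stack")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_contract("`dropout_rate` must be in [0, 1)")
  }
  structure(
    list(layers = layers, kind = types[1], dropout_sites = dropout_sites,
         dropout_rate = dropout_rate),
    class = "prediction_network"
  )
}

#' @export
print.prediction_network <- function(x, ...) {
  cat(sprintf("<prediction_network: %d %s layers", length(x$layers), x$kind))
  if (length(x$dropout_sites)) {
    cat(sprintf(", dropout (p=%g) after layers %s", x$dropout_rate,
                paste(x$dropout_sites, collapse = ", ")))
  }
  cat(">\n")
  invisible(x)
}

#' Random convolutional reconstruction network
#'
#' Builds the 1D convolutional architecture used by the deconvolution case
#' study: `n_layers` same-padded convolutions with ReLU activations (identity
#' on the last layer) and dropout sites interleaved in the middle of the
#' stack. Weights are He-initialised, biases start at zero.
#'
#' @param n_layers Number of convolution layers.
#' @param channels Hidden channel width.
#' @param kernel_size Odd kernel length.
#' @param in_channels,out_channels Input/output channel counts
#'   (`out_channels = 2` yields the doubled mean/variance head used by the
#'   direct variance estimation baseline).
#' @param dropout_sites Layer indices after which dropout is applied.
#' @param dropout_rate Dropout probability.
#' @param seed Optional integer seed for the weight draw.
#' @return A [prediction_network()].
#' @export
make_conv_net <- function(n_layers = 10, channels = 32, kernel_size = 5,
                          in_channels = 1, out_channels = 1,
                          dropout_sites = c(3, 5, 7), dropout_rate = 0.1,
                          seed = NULL) {
  with_seed(seed, {
    layers <- vector("list", n_layers)
    for (i in seq_len(n_layers)) {
      ci <- if (i == 1) in_channels else channels
      co <- if (i == n_layers) out_channels else channels
      fan_in <- ci * kernel_size
      W <- array(stats::rnorm(co * ci * kernel_size, sd = sqrt(2 / fan_in)),
                 dim = c(co, ci, kernel_size))
      act <- if (i == n_layers) "identity" else "relu"
      layers[[i]] <- conv1d_layer(W, rep(0, co), activation = act)
    }
    prediction_network(layers, dropout_sites = dropout_sites,
                       dropout_rate = dropout_rate)
  })
}

#' Random dense network
#'
#' Small fully connected ReLU network, mainly for tests and toy problems.
#'
#' @param sizes Integer vector of layer widths, input first, output last.
#' @inheritParams make_conv_net
#' @return A [prediction_network()].
#' @export
make_dense_net <- function(sizes, dropout_sites = integer(0),
                           dropout_rate = 0.1, seed = NULL) {
  if (length(sizes) < 2) stop_contract("`sizes` needs at least input and output")
  with_seed(seed, {
    n <- length(sizes) - 1
    layers <- vector("list", n)
    for (i in seq_len(n)) {
      W <- matrix(stats::rnorm(sizes[i + 1] * sizes[i], sd = sqrt(2 / sizes[i])),
                  sizes[i + 1], sizes[i])
      act <- if (i == n) "identity" else "relu"
      layers[[i]] <- dense_layer(W, rep(0, sizes[i + 1]), activation = act)
    }
    prediction_network(layers, dropout_sites = dropout_sites,
                       dropout_rate = dropout_rate)
  })
}

# ---- input/output canonicalisation ------------------------------------------

# Canonical activation for a network: dense -> (features x batch) matrix,
# conv1d -> (channels x length x batch) array. Plain vectors/matrices of
# signals are lifted to single-channel form.
canonical_input <- function(net, z) {
  check_numeric_array(z, "z")
  if (net$kind == "dense") {
    if (is.null(dim(z))) z <- matrix(z, ncol = 1)
    if (!is.matrix(z)) stop_contract("dense networks take vectors or matrices")
    if (nrow(z) != layer_in_features(net$layers[[1]])) {
      stop_contract("input has %d features, network expects %d",
                    nrow(z), layer_in_features(net$layers[[1]]))
    }
    z
  } else {
    ci <- layer_in_features(net$layers[[1]])
    if (is.null(dim(z))) {
      z <- array(z, dim = c(1, length(z), 1))
    } else if (is.matrix(z)) {
      z <- array(z, dim = c(1, nrow(z), ncol(z)))
    }
    if (length(dim(z)) != 3 || dim(z)[1] != ci) {
      stop_contract("conv1d networks take (length), (length x batch) or (%d x length x batch) inputs", ci)
    }
    z
  }
}

# Collapse a canonical output back to the shape family of the user input:
# single-channel conv outputs become (length x batch) matrices.
canonical_output <- function(a) {
  if (length(dim(a)) == 3 && dim(a)[1] == 1) {
    matrix(a, dim(a)[2], dim(a)[3])
  } else {
    a
  }
}

# ---- im2col helpers ----------------------------------------------------------
# The same-padded im2col/col2im layout transforms live in src/kernels.cpp
# (cpp_im2col1d / cpp_col2im1d); a convolution is then a single dense product
# of the flattened kernel with the column matrix.

im2col <- function(a, K) {
  d <- dim(a)
  cpp_im2col1d(a, d[1], d[2], d[3], K)
}

# Flatten layer weights to the affine matrix acting on im2col columns.
layer_W2 <- function(layer) {
  if (layer$type == "dense") {
    layer$W
  } else {
    d <- dim(layer$W)
    matrix(layer$W, d[1], d[2] * d[3])
  }
}

# ---- forward / backward ------------------------------------------------------

# Forward pass on canonical input. Returns list(out, cache); cache holds, per
# layer, the im2col matrix (or dense input), the pre-activation matrix, and
# dropout masks, as needed for the backward pass.
net_forward_internal <- function(net, x, dropout = FALSE, keep_cache = FALSE) {
  layers <- net$layers
  n <- length(layers)
  cache <- if (keep_cache) {
    list(cols = vector("list", n), pre = vector("list", n),
         masks = vector("list", n), dims = vector("list", n))
  }
  a <- x
  for (i in seq_len(n)) {
    layer <- layers[[i]]
    if (layer$type == "conv1d") {
      d <- dim(a)
      K <- dim(layer$W)[3]
      cols <- im2col(a, K)
      pre <- layer_W2(layer) %*% cols + layer$b
      if (keep_cache) {
        cache$cols[[i]] <- cols
        cache$dims[[i]] <- d
      }
      a <- apply_activation(pre, layer$activation)
      if (keep_cache) cache$pre[[i]] <- pre
      dim(a) <- c(dim(layer$W)[1], d[2], d[3])
    } else {
      pre <- layer$W %*% a + layer$b
      if (keep_cache) {
        cache$cols[[i]] <- a
        cache$pre[[i]] <- pre
      }
      a <- apply_activation(pre, layer$activation)
    }
    if (dropout && i %in% net$dropout_sites && net$dropout_rate > 0) {
      keep <- (stats::runif(length(a)) >= net$dropout_rate) * 1
      dim(keep) <- dim(a)
      a <- a * keep / (1 - net$dropout_rate)
      if (keep_cache) cache$masks[[i]] <- keep
    }
  }
  list(out = a, cache = cache)
}

# Backward pass from d_out (gradient w.r.t. the network output, canonical
# shape). Returns per-layer weight/bias gradients and the input gradient.
net_backward_internal <- function(net, cache, d_out) {
  layers <- net$layers
  n <- length(layers)
  grads <- vector("list", n)
  d_a <- d_out
  for (i in rev(seq_len(n))) {
    layer <- layers[[i]]
    if (!is.null(cache$masks[[i]])) {
      d_a <- d_a * cache$masks[[i]] / (1 - net$dropout_rate)
    }
    if (layer$type == "conv1d") {
      d <- cache$dims[[i]]
      d_pre <- grad_through_activation(d_a, cache$pre[[i]], layer$activation)
      dW2 <- tcrossprod(d_pre, cache$cols[[i]])
      db <- rowSums(d_pre)
      K <- dim(layer$W)[3]
      dcols <- crossprod(layer_W2(layer), d_pre)
      d_a <- cpp_col2im1d(dcols, dim(layer$W)[2], d[2], d[3], K)
      grads[[i]] <- list(W = array(dW2, dim = dim(layer$W)), b = db)
    } else {
      d_pre <- grad_through_activation(d_a, cache$pre[[i]], layer$activation)
      grads[[i]] <- list(W = tcrossprod(d_pre, cache$cols[[i]]),
                         b = rowSums(d_pre))
      d_a <- crossprod(layer$W, d_pre)
    }
  }
  list(grads = grads, d_input = d_a)
}

#' Evaluate a prediction network
#'
#' Deterministic forward pass (dropout disabled unless requested). For
#' single-channel convolutional networks, signals may be passed as a vector
#' or a `length x batch` matrix and are returned in the same shape family.
#'
#' @param net A [prediction_network()].
#' @param z Input signal(s): vector, `features x batch` matrix, or a
#'   `channels x length x batch` array for convolutional networks.
#' @param dropout If `TRUE`, sample dropout masks at the network's dropout
#'   sites (uses the current RNG stream).
#' @return The network output; matrix `n x batch` for single-channel outputs.
#' @export
predict_network <- function(net, z, dropout = FALSE) {
  x <- canonical_input(net, z)
  out <- net_forward_internal(net, x, dropout = dropout)$out
  if (net$kind == "conv1d") canonical_output(out) else out
}

#' Gradient of a scalar objective with respect to the network input
#'
#' Backpropagates `d_out` (the gradient of some scalar objective with respect
#' to the network output) through the network with dropout disabled. Used by
#' the box-constrained adversarial attack.
#'
#' @inheritParams predict_network
#' @param d_out Gradient at the output, same shape as the output.
#' @return List with `output` and `d_input` (same shape family as `z`).
#' @export
network_input_gradient <- function(net, z, d_out) {
  x <- canonical_input(net, z)
  fw <- net_forward_internal(net, x, dropout = FALSE, keep_cache = TRUE)
  d_can <- if (net$kind == "conv1d") {
    array(d_out, dim = dim(fw$out))
  } else {
    matrix(d_out, nrow(fw$out), ncol(fw$out))
  }
  bw <- net_backward_internal(net, fw$cache, d_can)
  d_in <- bw$d_input
  if (net$kind == "conv1d") d_in <- canonical_output(d_in)
  list(output = if (net$kind == "conv1d") canonical_output(fw$out) else fw$out,
       d_input = d_in)
}
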