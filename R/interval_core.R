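# Interval arithmetic core: interval boxes, the two layer propagation rules
# (point inputs and nonnegative interval inputs), post-hoc wrapping of a
# trained network in parameter intervals, and the sound interval forward pass.

#' Component-wise interval box
#'
#' A pair of equally shaped arrays with `lower <= upper` everywhere,
#' representing component-wise intervals over activations, weights or biases.
#'
#' @param lower,upper Numeric arrays of identical shape.
#' @return An object of class `interval_box` with fields `lower` and `upper`.
#' @export
interval_box <- function(lower, upper) {
  check_numeric_array(lower, "lower")
  check_numeric_array(upper, "upper")
  check_same_shape(lower, upper, "lower", "upper")
  if (any(lower > upper)) {
    stop_contract("interval_box requires lower <= upper component-wise")
  }
  structure(list(lower = lower, upper = upper), class = "interval_box")
}

#' @export
print.interval_box <- function(x, ...) {
  cat(sprintf("<interval_box: %s components, mean width %.4g>\n",
              paste(dim(x$lower) %||% length(x$lower), collapse = "x"),
              mean(x$upper - x$lower)))
  invisible(x)
}

#' Width of an interval box
#'
#' @param box An [interval_box()].
#' @return `upper - lower`, component-wise (nonnegative).
#' @export
interval_width <- function(box) {
  box$upper - box$lower
}

# ---- affine interval rules on column matrices --------------------------------
# All four rules act on flattened weight matrices (out x in_features) and
# column-major activation matrices (in_features x n_columns); biases recycle
# down columns.

affine_interval_point <- function(Wlo2, Whi2, blo, bhi, colsP, colsN) {
  list(
    lo = Wlo2 %*% colsP + Whi2 %*% colsN + blo,
    hi = Whi2 %*% colsP + Wlo2 %*% colsN + bhi
  )
}

affine_interval_nonneg <- function(Wlo2, Whi2, blo, bhi, colsLo, colsHi) {
  Whi_p <- pmax(Whi2, 0)
  Whi_n <- Whi2 - Whi_p
  Wlo_p <- pmax(Wlo2, 0)
  Wlo_n <- Wlo2 - Wlo_p
  list(
    lo = Wlo_p %*% colsLo + Wlo_n %*% colsHi + blo,
    hi = Whi_n %*% colsLo + Whi_p %*% colsHi + bhi
  )
}

# Canonicalise a weight interval box into flattened form plus layer metadata.
weight_box_info <- function(W_box) {
  if (!inherits(W_box, "interval_box")) {
    stop_contract("weights must be given as an interval_box")
  }
  d <- dim(W_box$lower)
  if (is.null(d) || length(d) == 2) {
    W_lo <- as.matrix(W_box$lower)
    W_hi <- as.matrix(W_box$upper)
    list(type = "dense", Wlo2 = W_lo, Whi2 = W_hi, out = nrow(W_lo),
         inn = ncol(W_lo))
  } else if (length(d) == 3) {
    list(type = "conv1d", Wlo2 = matrix(W_box$lower, d[1], d[2] * d[3]),
         Whi2 = matrix(W_box$upper, d[1], d[2] * d[3]),
         out = d[1], inn = d[2], K = d[3])
  } else {
    stop_contract("weight arrays must be 2D (dense) or 3D (conv1d)")
  }
}

canonical_plain <- function(info, z) {
  if (info$type == "dense") {
    if (is.null(dim(z))) z <- matrix(z, ncol = 1)
    if (nrow(z) != info$inn) {
      stop_contract("input has %d features, layer expects %d", nrow(z), info$inn)
    }
    z
  } else {
    if (is.null(dim(z))) z <- array(z, dim = c(1, length(z), 1))
    if (is.matrix(z)) z <- array(z, dim = c(1, nrow(z), ncol(z)))
    if (length(dim(z)) != 3 || dim(z)[1] != info$inn) {
      stop_contract("input channel count does not match layer (%d expected)",
                    info$inn)
    }
    z
  }
}

layer_cols <- function(info, a) {
  if (info$type == "dense") a else im2col(a, info$K)
}

restore_shape <- function(info, m, a_dims) {
  if (info$type == "dense") m else array(m, dim = c(info$out, a_dims[2], a_dims[3]))
}

#' Propagate a point input through one interval-valued layer
#'
#' Applies the exact interval-arithmetic rule for a single (possibly signed)
#' point input `z` through a layer whose weights and biases are intervals:
#' the upper pre-activation bound is
#' `W_hi max(z,0) + W_lo min(z,0) + b_hi` and the lower bound swaps the
#' weight bounds, after which the activation is applied to both bounds.
#'
#' @param W_box Weight [interval_box()]: matrices (dense) or
#'   `out x in x kernel` arrays (1D convolution).
#' @param b_box Bias [interval_box()] (vectors).
#' @param z Point input: vector, matrix, or canonical conv array.
#' @param activation `"relu"` or `"identity"`.
#' @return An [interval_box()] with the layer's output bounds.
#' @export
propagate_point_input <- function(W_box, b_box, z,
                                  activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  info <- weight_box_info(W_box)
  a <- canonical_plain(info, z)
  ap <- pmax(a, 0)
  an <- a - ap
  res <- affine_interval_point(info$Wlo2, info$Whi2, b_box$lower, b_box$upper,
                               layer_cols(info, ap), layer_cols(info, an))
  interval_box(
    restore_shape(info, apply_activation(res$lo, activation), dim(a)),
    restore_shape(info, apply_activation(res$hi, activation), dim(a))
  )
}

#' Propagate a nonnegative interval input through one interval-valued layer
#'
#' Applies the exact interval-arithmetic rule for a nonnegative interval
#' input (guaranteed after a ReLU layer): the upper bound is
#' `min(W_hi,0) z_lo + max(W_hi,0) z_hi + b_hi`, the lower bound
#' `max(W_lo,0) z_lo + min(W_lo,0) z_hi + b_lo`, with minima/maxima taken
#' component-wise, followed by the activation on both bounds.
#'
#' @inheritParams propagate_point_input
#' @param z_box Input [interval_box()] with `lower >= 0` everywhere.
#' @return An [interval_box()] with the layer's output bounds.
#' @export
propagate_nonneg_interval <- function(W_box, b_box, z_box,
                                      activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (!inherits(z_box, "interval_box")) {
    stop_contract("`z_box` must be an interval_box")
  }
  if (any(z_box$lower < 0)) {
    stop_contract("nonnegative-interval rule requires z_box$lower >= 0; use the point-input rule for signed inputs")
  }
  info <- weight_box_info(W_box)
  alo <- canonical_plain(info, z_box$lower)
  ahi <- canonical_plain(info, z_box$upper)
  res <- affine_interval_nonneg(info$Wlo2, info$Whi2, b_box$lower, b_box$upper,
                                layer_cols(info, alo), layer_cols(info, ahi))
  interval_box(
    restore_shape(info, apply_activation(res$lo, activation), dim(alo)),
    restore_shape(info, apply_activation(res$hi, activation), dim(alo))
  )
}

# ---- interval networks -------------------------------------------------------

#' Wrap a trained network in parameter intervals
#'
#' Constructs an interval network post hoc: every interval-equipped layer
#' receives weight intervals `[W - init_width |W| - eps0, W + init_width |W| + eps0]`
#' (biases analogously), so the box constraints `W_lo <= W <= W_hi` hold by
#' construction. Layers outside `interval_layers` carry point intervals equal
#' to the base parameters.
#'
#' @param base A trained [prediction_network()].
#' @param interval_layers Integer indices of layers that carry trainable
#'   intervals; `NULL` (default) equips all layers.
#' @param init_width Nonnegative relative initial half-width.
#' @param eps0 Tiny absolute half-width floor so interval-width gradients are
#'   nonzero at the start of training.
#' @param beta Optional tightness parameter to store with the network.
#' @return An object of class `interval_network`.
#' @export
wrap_network <- function(base, interval_layers = NULL, init_width = 0,
                         eps0 = 1e-6, beta = NA_real_) {
  if (!inherits(base, "prediction_network")) {
    stop_contract("`base` must be a prediction_network")
  }
  if (init_width < 0) stop_contract("`init_width` must be nonnegative")
  if (eps0 < 0) stop_contract("`eps0` must be nonnegative")
  n <- length(base$layers)
  if (is.null(interval_layers)) interval_layers <- seq_len(n)
  interval_layers <- sort(unique(as.integer(interval_layers)))
  if (length(interval_layers) == 0 || any(interval_layers < 1) ||
      any(interval_layers > n)) {
    stop_contract("`interval_layers` must be a nonempty subset of 1..%d", n)
  }
  params <- vector("list", n)
  for (i in seq_len(n)) {
    W <- base$layers[[i]]$W
    b <- base$layers[[i]]$b
    if (i %in% interval_layers) {
      dW <- init_width * abs(W) + eps0
      db <- init_width * abs(b) + eps0
    } else {
      dW <- 0
      db <- 0
    }
    params[[i]] <- list(W_lo = W - dW, W_hi = W + dW, b_lo = b - db,
                        b_hi = b + db)
  }
  structure(
    list(base = base, params = params, interval_layers = interval_layers,
         beta = beta),
    class = "interval_network"
  )
}

#' @export
print.interval_network <- function(x, ...) {
  w <- mean(unlist(lapply(x$params[x$interval_layers],
                          function(p) mean(p$W_hi - p$W_lo))))
  cat(sprintf(
    "<interval_network: %d layers (%d interval-equipped), beta=%s, mean weight width %.3g>\n",
    length(x$base$layers), length(x$interval_layers),
    format(x$beta), w))
  invisible(x)
}

# Check the box constraints W_lo <= W <= W_hi (and biases) exactly; these are
# what make the containment guarantee valid, so the forward pass refuses to
# run when they are violated.
validate_interval_network <- function(inn) {
  for (i in seq_along(inn$params)) {
    p <- inn$params[[i]]
    l <- inn$base$layers[[i]]
    if (any(p$W_lo > l$W) || any(p$W_hi < l$W) ||
        any(p$b_lo > l$b) || any(p$b_hi < l$b)) {
      stop_contract(
        "interval constraints violated at layer %d; the containment guarantee would be void", i)
    }
  }
  invisible(TRUE)
}

# Interval forward pass on canonical input. Layers before the first
# interval-equipped one carry point intervals, so the point input is
# propagated through them with the plain base forward; the first equipped
# layer uses the point-input rule (its input may be signed at layer 1,
# nonnegative after any ReLU) and subsequent layers the nonnegative-interval
# rule, all hidden activations being ReLU. Returns bounds as matrices
# (out x columns) per layer when keep_cache is TRUE.
inn_forward_internal <- function(inn, x, keep_cache = FALSE) {
  layers <- inn$base$layers
  n <- length(layers)
  first <- min(inn$interval_layers)
  cache <- if (keep_cache) {
    list(colsP = NULL, colsN = NULL, colsLo = vector("list", n),
         colsHi = vector("list", n), pre_lo = vector("list", n),
         pre_hi = vector("list", n), dims = vector("list", n), first = first)
  }
  a <- x
  for (i in seq_len(first - 1)) {
    layer <- layers[[i]]
    if (layer$type == "conv1d") {
      d <- dim(a)
      pre <- layer_W2(layer) %*% im2col(a, dim(layer$W)[3]) + layer$b
      a <- array(apply_activation(pre, layer$activation),
                 dim = c(dim(layer$W)[1], d[2], d[3]))
    } else {
      a <- apply_activation(layer$W %*% a + layer$b, layer$activation)
    }
  }
  alo <- NULL
  ahi <- NULL
  for (i in first:n) {
    layer <- layers[[i]]
    p <- inn$params[[i]]
    conv <- layer$type == "conv1d"
    if (conv) {
      K <- dim(layer$W)[3]
      info <- list(type = "conv1d", K = K)
    } else {
      info <- list(type = "dense")
    }
    Wlo2 <- if (conv) matrix(p$W_lo, dim(layer$W)[1], dim(layer$W)[2] * dim(layer$W)[3]) else p$W_lo
    Whi2 <- if (conv) matrix(p$W_hi, dim(layer$W)[1], dim(layer$W)[2] * dim(layer$W)[3]) else p$W_hi
    if (i == first) {
      ap <- pmax(a, 0)
      an <- a - ap
      colsP <- layer_cols(info, ap)
      colsN <- layer_cols(info, an)
      res <- affine_interval_point(Wlo2, Whi2, p$b_lo, p$b_hi, colsP, colsN)
      if (keep_cache) {
        cache$colsP <- colsP
        cache$colsN <- colsN
        cache$dims[[i]] <- dim(a) %||% c(length(a), 1L)
      }
    } else {
      colsLo <- layer_cols(info, alo)
      colsHi <- layer_cols(info, ahi)
      res <- affine_interval_nonneg(Wlo2, Whi2, p$b_lo, p$b_hi, colsLo, colsHi)
      if (keep_cache) {
        cache$colsLo[[i]] <- colsLo
        cache$colsHi[[i]] <- colsHi
        cache$dims[[i]] <- dim(alo) %||% c(length(alo), 1L)
      }
    }
    if (keep_cache) {
      cache$pre_lo[[i]] <- res$lo
      cache$pre_hi[[i]] <- res$hi
    }
    lo_a <- apply_activation(res$lo, layer$activation)
    hi_a <- apply_activation(res$hi, layer$activation)
    if (conv) {
      d_in <- if (i == first) dim(a) else dim(alo)
      lo_a <- array(lo_a, dim = c(dim(layer$W)[1], d_in[2], d_in[3]))
      hi_a <- array(hi_a, dim = c(dim(layer$W)[1], d_in[2], d_in[3]))
    }
    alo <- lo_a
    ahi <- hi_a
  }
  list(lo = alo, hi = ahi, cache = cache)
}

# Backward pass of the interval forward: gradients of a scalar loss with
# respect to the interval parameters of trainable layers, given d_lo/d_hi at
# the output (canonical shapes). The min/max weight splits are piecewise
# linear in the parameters; their subgradients select the active branch
# (ties resolved toward the nonnegative part).
inn_backward_internal <- function(inn, cache, d_lo, d_hi) {
  layers <- inn$base$layers
  n <- length(layers)
  first <- cache$first
  grads <- vector("list", n)
  trainable <- inn$interval_layers
  for (i in rev(first:n)) {
    layer <- layers[[i]]
    p <- inn$params[[i]]
    conv <- layer$type == "conv1d"
    dW <- if (conv) dim(layer$W) else NULL
    Wlo2 <- if (conv) matrix(p$W_lo, dW[1], dW[2] * dW[3]) else p$W_lo
    Whi2 <- if (conv) matrix(p$W_hi, dW[1], dW[2] * dW[3]) else p$W_hi
    d_pre_lo <- grad_through_activation(d_lo, cache$pre_lo[[i]],
                                        layer$activation)
    d_pre_hi <- grad_through_activation(d_hi, cache$pre_hi[[i]],
                                        layer$activation)
    if (i == first) {
      if (i %in% trainable) {
        dWhi2 <- tcrossprod(d_pre_hi, cache$colsP) +
          tcrossprod(d_pre_lo, cache$colsN)
        dWlo2 <- tcrossprod(d_pre_hi, cache$colsN) +
          tcrossprod(d_pre_lo, cache$colsP)
        grads[[i]] <- list(
          W_lo = if (conv) array(dWlo2, dim = dW) else dWlo2,
          W_hi = if (conv) array(dWhi2, dim = dW) else dWhi2,
          b_lo = rowSums(d_pre_lo), b_hi = rowSums(d_pre_hi))
      }
    } else {
      Whi_p <- pmax(Whi2, 0)
      Whi_n <- Whi2 - Whi_p
      Wlo_p <- pmax(Wlo2, 0)
      Wlo_n <- Wlo2 - Wlo_p
      if (i %in% trainable) {
        dWhi2 <- tcrossprod(d_pre_hi, cache$colsLo[[i]]) * (Whi2 < 0) +
          tcrossprod(d_pre_hi, cache$colsHi[[i]]) * (Whi2 >= 0)
        dWlo2 <- tcrossprod(d_pre_lo, cache$colsLo[[i]]) * (Wlo2 >= 0) +
          tcrossprod(d_pre_lo, cache$colsHi[[i]]) * (Wlo2 < 0)
        grads[[i]] <- list(
          W_lo = if (conv) array(dWlo2, dim = dW) else dWlo2,
          W_hi = if (conv) array(dWhi2, dim = dW) else dWhi2,
          b_lo = rowSums(d_pre_lo), b_hi = rowSums(d_pre_hi))
      }
      d_colsLo <- crossprod(Whi_n, d_pre_hi) + crossprod(Wlo_p, d_pre_lo)
      d_colsHi <- crossprod(Whi_p, d_pre_hi) + crossprod(Wlo_n, d_pre_lo)
      dims_prev <- cache$dims[[i]]
      if (conv) {
        d_lo <- cpp_col2im1d(d_colsLo, dW[2], dims_prev[2], dims_prev[3], dW[3])
        d_hi <- cpp_col2im1d(d_colsHi, dW[2], dims_prev[2], dims_prev[3], dW[3])
      } else {
        d_lo <- d_colsLo
        d_hi <- d_colsHi
      }
    }
  }
  grads
}

#' Interval forward pass with containment guarantee
#'
#' Propagates a point input through the interval network (point-input rule at
#' the first layer, nonnegative-interval rule afterwards) and evaluates the
#' base network deterministically. As long as the parameter box constraints
#' hold — they are checked and the function refuses to run otherwise — the
#' base prediction is guaranteed to lie inside `[lower, upper]`.
#'
#' @param inn An [wrap_network()] interval network.
#' @param z Input signal(s), as in [predict_network()].
#' @return List with `lower`, `upper`, and `prediction`, each in the shape
#'   family of the input.
#' @export
forward_interval <- function(inn, z) {
  if (!inherits(inn, "interval_network")) {
    stop_contract("`inn` must be an interval_network")
  }
  validate_interval_network(inn)
  x <- canonical_input(inn$base, z)
  res <- inn_forward_internal(inn, x)
  pred <- net_forward_internal(inn$base, x, dropout = FALSE)$out
  if (inn$base$kind == "conv1d") {
    list(lower = canonical_output(res$lo), upper = canonical_output(res$hi),
         prediction = canonical_output(pred))
  } else {
    list(lower = res$lo, upper = res$hi, prediction = pred)
  }
}
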