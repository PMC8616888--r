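# Independent oracles used across the interval tests.

# Exact extreme-value oracle for one interval-valued affine layer: the output
# bounds of activation(W z + b) over all (W, b, z) in their boxes are attained
# at corner points of the joint box (the map is affine in (W, b) for fixed z,
# affine in z for fixed (W, b), and the activation is monotone), so
# enumerating all corners yields the exact interval. Only feasible for tiny
# layers (1x1, 2x2).
corner_oracle <- function(W_lo, W_hi, b_lo, b_hi, z_lo, z_hi,
                          activation = "relu") {
  act <- function(v) if (activation == "relu") pmax(v, 0) else v
  nW <- length(W_lo)
  nb <- length(b_lo)
  nz <- length(z_lo)
  n_corners <- 2^(nW + nb + nz)
  out_lo <- rep(Inf, nrow(W_lo))
  out_hi <- rep(-Inf, nrow(W_lo))
  for (c in seq_len(n_corners) - 1) {
    bits <- as.integer(intToBits(c))[seq_len(nW + nb + nz)]
    W <- W_lo
    W[bits[seq_len(nW)] == 1] <- W_hi[bits[seq_len(nW)] == 1]
    b <- b_lo
    sel <- bits[nW + seq_len(nb)] == 1
    b[sel] <- b_hi[sel]
    z <- z_lo
    sel <- bits[nW + nb + seq_len(nz)] == 1
    z[sel] <- z_hi[sel]
    v <- act(W %*% z + b)
    out_lo <- pmin(out_lo, v)
    out_hi <- pmax(out_hi, v)
  }
  list(lo = out_lo, hi = out_hi)
}

# Draw a random parameter selection inside an interval network's boxes and
# return the corresponding plain network.
sample_network_in_intervals <- function(inn) {
  net <- inn$base
  for (i in seq_along(net$layers)) {
    p <- inn$params[[i]]
    uW <- stats::runif(length(p$W_lo))
    W <- p$W_lo + uW * (p$W_hi - p$W_lo)
    if (!is.null(dim(p$W_lo))) dim(W) <- dim(p$W_lo)
    ub <- stats::runif(length(p$b_lo))
    net$layers[[i]]$W <- W
    net$layers[[i]]$b <- p$b_lo + ub * (p$b_hi - p$b_lo)
  }
  net
}

# Small dense regression problem: smooth nonlinear map plus noise, used by
# the training-behaviour tests.
make_toy_problem <- function(n_samples = 200, d = 6, seed = 11,
                             noise_sd = 0.05) {
  set.seed(seed)
  z <- matrix(runif(d * n_samples, -1, 1), d, n_samples)
  x <- sin(2 * z) + 0.3 * z^2 +
    matrix(rnorm(d * n_samples, sd = noise_sd), d, n_samples)
  list(z = z, x = x)
}
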