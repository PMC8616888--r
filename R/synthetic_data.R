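# Synthetic 1D deconvolution benchmark: a DCT-diagonalised forward operator
# with polynomially decaying spectrum, piecewise-constant signals, Gaussian
# noise on measurements and/or signals, dataset assembly, and out-of-
# distribution artifact insertion.

#' Orthonormal Type-I discrete cosine transform matrix
#'
#' Symmetric orthonormal DCT-I basis: `D[j, k] = sqrt(2/(n-1)) c_j c_k
#' cos(pi (j-1)(k-1) / (n-1))` with `c_i = 1/sqrt(2)` at the endpoints, so
#' that `D %*% t(D)` is the identity.
#'
#' @param n Transform size (`>= 2`).
#' @return An `n x n` orthogonal matrix.
#' @export
dct1_matrix <- function(n) {
  if (n < 2) stop_contract("`n` must be >= 2")
  j <- seq_len(n) - 1
  D <- sqrt(2 / (n - 1)) * cos(pi * outer(j, j) / (n - 1))
  c_end <- rep(1, n)
  c_end[c(1, n)] <- 1 / sqrt(2)
  D * outer(c_end, c_end)
}

#' Forward operator with polynomially decaying spectrum
#'
#' Builds `A = t(D) S D` where `D` is the orthonormal DCT-I and `S` is
#' diagonal with `s_j = ((n - j) / (n - 1))^nu` for `j = 1..n`, so the
#' spectrum decays from `s_1 = 1` to `s_n = 0` with exponent `nu`. `A` is
#' symmetric with eigenvalues in `[0, 1]` (a contraction), and larger `nu`
#' suppresses high-frequency content more strongly, making the deconvolution
#' problem more ill-posed.
#'
#' @param n Signal dimension (`>= 2`).
#' @param nu Nonnegative decay exponent.
#' @return An `n x n` matrix with attribute `spectrum` (the `s_j`).
#' @export
make_forward_operator <- function(n, nu) {
  if (n < 2) stop_contract("`n` must be >= 2")
  if (nu < 0) stop_contract("`nu` must be nonnegative")
  D <- dct1_matrix(n)
  s <- ((n - seq_len(n)) / (n - 1))^nu
  A <- crossprod(D, s * D)
  attr(A, "spectrum") <- s
  A
}

#' Inverse problem description
#'
#' Bundles the forward operator, the model-based inversion, and the noise
#' configuration of the benchmark. For the 1D deconvolution case study the
#' model-based inversion is the identity, so the network input equals the
#' measurement; `a_dagger` can be overridden with any function for other
#' setups.
#'
#' @param n Signal dimension.
#' @param nu Spectral decay exponent of the forward operator.
#' @param noise_mode One of `"none"`, `"measurement"` (noise on `y` only) or
#'   `"measurement_and_signal"` (independent noise on the signal before the
#'   forward operator and on the measurement).
#' @param sigma Nonnegative Gaussian noise standard deviation.
#' @param a_dagger Model-based inversion function `y -> z`; `NULL` means the
#'   identity.
#' @return An object of class `inverse_problem`.
#' @export
inverse_problem <- function(n = 512, nu = 8,
                            noise_mode = c("none", "measurement",
                                           "measurement_and_signal"),
                            sigma = 0, a_dagger = NULL) {
  noise_mode <- match.arg(noise_mode)
  if (sigma < 0) stop_contract("`sigma` must be nonnegative")
  A <- make_forward_operator(n, nu)
  structure(
    list(n = as.integer(n), m = as.integer(n), A = A, nu = nu,
         noise_mode = noise_mode, sigma = sigma, a_dagger = a_dagger),
    class = "inverse_problem"
  )
}

#' @export
print.inverse_problem <- function(x, ...) {
  cat(sprintf("<inverse_problem: n=m=%d, nu=%g, noise=%s, sigma=%g>\n",
              x$n, x$nu, x$noise_mode, x$sigma))
  invisible(x)
}

#' Sample a piecewise-constant signal
#'
#' Draws a jump count uniformly from `jump_count_range`, jump positions
#' uniformly without replacement among the `n - 1` interior boundaries, and
#' independent plateau heights uniformly from `height_range`; the result is
#' clipped to `[0, 1]`.
#'
#' @param n Signal length.
#' @param jump_count_range Length-2 integer range (inclusive) for the number
#'   of jumps.
#' @param height_range Length-2 range for plateau heights.
#' @param seed Optional seed.
#' @return Numeric vector of length `n` with values in `[0, 1]`.
#' @export
sample_signal <- function(n, jump_count_range = c(4, 12),
                          height_range = c(0, 1), seed = NULL) {
  if (length(jump_count_range) == 1) {
    jump_count_range <- rep(jump_count_range, 2)
  }
  if (jump_count_range[2] > n - 1) {
    stop_contract("cannot place more than n - 1 = %d jumps", n - 1)
  }
  with_seed(seed, {
    k <- jump_count_range[1] +
      sample.int(jump_count_range[2] - jump_count_range[1] + 1L, 1) - 1L
    bounds <- if (k > 0) sort(sample.int(n - 1, k)) else integer(0)
    heights <- stats::runif(k + 1, height_range[1], height_range[2])
    x <- rep(heights, times = diff(c(0, bounds, n)))
    pmin(pmax(x, 0), 1)
  })
}

#' Simulate measurements and model-based inversions
#'
#' Applies the forward operator and the configured noise model:
#' `"measurement"` gives `y = A x + eta`, `"measurement_and_signal"` gives
#' `y = A (x + eta1) + eta2` with independent draws
#' `eta, eta1, eta2 ~ N(0, sigma^2 Id)`, and `"none"` gives `y = A x`. The
#' network input is `z = A_dagger(y)` (identity by default).
#'
#' @param problem An [inverse_problem()].
#' @param x Signal vector or `n x batch` matrix.
#' @param seed Optional seed for the noise draws.
#' @return List with `y` (measurements) and `z` (network inputs), matrices
#'   shaped like `x`.
#' @export
simulate_measurements <- function(problem, x, seed = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (nrow(x) != problem$n) {
    stop_contract("`x` must have %d rows", problem$n)
  }
  with_seed(seed, {
    sigma <- problem$sigma
    y <- switch(problem$noise_mode,
      none = problem$A %*% x,
      measurement = problem$A %*% x +
        matrix(stats::rnorm(length(x), sd = sigma), nrow(x), ncol(x)),
      measurement_and_signal = {
        eta1 <- matrix(stats::rnorm(length(x), sd = sigma), nrow(x), ncol(x))
        eta2 <- matrix(stats::rnorm(length(x), sd = sigma), nrow(x), ncol(x))
        problem$A %*% (x + eta1) + eta2
      }
    )
    z <- if (is.null(problem$a_dagger)) y else problem$a_dagger(y)
    list(y = y, z = z)
  })
}

#' Insert an out-of-distribution artifact
#'
#' Adds `amplitude * mask` to the signal (clipped back to `[0, 1]`). With
#' `mask = NULL`, a contiguous block of `block_length` components is placed
#' uniformly at random — the 1D analogue of inserting a fixed silhouette at a
#' random image position. Measurements for the perturbed signal are then
#' simulated with [simulate_measurements()] exactly as for clean signals.
#'
#' @param x Signal vector.
#' @param mask Binary (0/1) vector of the same length as `x`, or `NULL` to
#'   place a random block.
#' @param amplitude Artifact height added inside the mask.
#' @param block_length Block size used when `mask` is `NULL`.
#' @param seed Optional seed for the random placement.
#' @return List with `x_ood` (perturbed signal) and `mask`.
#' @export
insert_artifact <- function(x, mask = NULL, amplitude = 0.5,
                            block_length = 50, seed = NULL) {
  n <- length(x)
  with_seed(seed, {
    if (is.null(mask)) {
      if (block_length > n) stop_contract("`block_length` exceeds signal length")
      start <- sample.int(n - block_length + 1, 1)
      mask <- rep(0, n)
      mask[start:(start + block_length - 1)] <- 1
    }
    if (length(mask) != n) stop_contract("`mask` must match the signal length")
    if (!all(mask %in% c(0, 1))) stop_contract("`mask` must be binary")
    list(x_ood = pmin(pmax(x + amplitude * mask, 0), 1), mask = mask)
  })
}

#' Generate a paired dataset with train/validation/test splits
#'
#' Draws `n_total` piecewise-constant signals, simulates their measurements
#' and model-based inversions under the problem's noise configuration, and
#' assigns disjoint split labels in generation order.
#'
#' @param problem An [inverse_problem()].
#' @param n_total Total number of sample pairs.
#' @param split_sizes Named or unnamed integer vector
#'   `(train, validation, test)` summing to `n_total`.
#' @param jump_count_range,height_range Passed to [sample_signal()].
#' @param seed Optional seed making the whole dataset reproducible.
#' @return An object of class `sample_set`: list with `signals`, `y`, `z`
#'   (`n x n_total` matrices), `split` (factor), `problem`, and `seed`.
#' @export
make_dataset <- function(problem, n_total = 2000,
                         split_sizes = c(train = 1600, validation = 200,
                                         test = 200),
                         jump_count_range = c(4, 12), height_range = c(0, 1),
                         seed = NULL) {
  if (sum(split_sizes) != n_total) {
    stop_contract("split sizes must sum to n_total = %d", n_total)
  }
  with_seed(seed, {
    signals <- matrix(0, problem$n, n_total)
    for (i in seq_len(n_total)) {
      signals[, i] <- sample_signal(problem$n, jump_count_range, height_range)
    }
    meas <- simulate_measurements(problem, signals)
    split <- factor(rep(c("train", "validation", "test"), times = split_sizes),
                    levels = c("train", "validation", "test"))
    structure(
      list(signals = signals, y = meas$y, z = meas$z, split = split,
           problem = problem, seed = seed,
           jump_count_range = jump_count_range, height_range = height_range),
      class = "sample_set"
    )
  })
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set: n=%d, %s samples (%s)>\n", nrow(x$signals),
              ncol(x$signals),
              paste(table(x$split), collapse = "/")))
  invisible(x)
}

#' Extract one split of a dataset
#'
#' @param ds A [make_dataset()] sample set.
#' @param split `"train"`, `"validation"` or `"test"`.
#' @return List with `z`, `x` (targets), and `y` matrices for the split.
#' @export
dataset_split <- function(ds, split = c("train", "validation", "test")) {
  split <- match.arg(split)
  idx <- ds$split == split
  list(z = ds$z[, idx, drop = FALSE], x = ds$signals[, idx, drop = FALSE],
       y = ds$y[, idx, drop = FALSE])
}
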