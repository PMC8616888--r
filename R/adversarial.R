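# Adversarial perturbation of network inputs by box-constrained quasi-Newton
# optimisation against the prediction network.

#' Attack configuration
#'
#' @param region_size Length of the contiguous target region (the 1D analogue
#'   of a square patch).
#' @param depth_factor Multiple of the reconstruction mean subtracted inside
#'   the region.
#' @param box Length-2 valid input range.
#' @param max_iterations Iteration cap for the bounded quasi-Newton solver.
#' @param tolerance Gradient tolerance (`pgtol`) of the solver.
#' @param seed Optional seed for random region placement.
#' @return A list of class `attack_config`.
#' @export
attack_config <- function(region_size = 50, depth_factor = 1.5,
                          box = c(0, 1), max_iterations = 200,
                          tolerance = 1e-8, seed = NULL) {
  if (depth_factor <= 0) stop_contract("`depth_factor` must be positive")
  if (box[1] >= box[2]) stop_contract("`box` lower bound must be below upper")
  structure(
    list(region_size = as.integer(region_size), depth_factor = depth_factor,
         box = box, max_iterations = as.integer(max_iterations),
         tolerance = tolerance, seed = seed),
    class = "attack_config"
  )
}

#' Build an adversarial target reconstruction
#'
#' Copies the reconstruction and subtracts `depth_factor` times its mean
#' value inside the given region, creating a clearly visible artificial
#' depression that the attack will try to realise.
#'
#' @param x_rec Reconstruction vector.
#' @param region Integer indices of the target region (nonempty).
#' @param depth_factor Multiple of `mean(x_rec)` to subtract.
#' @return The adversarial target vector.
#' @export
make_adversarial_target <- function(x_rec, region, depth_factor = 1.5) {
  if (length(region) == 0) stop_contract("`region` must be nonempty")
  region <- as.integer(region)
  if (any(region < 1) || any(region > length(x_rec))) {
    stop_contract("`region` indices out of bounds")
  }
  x_tar <- x_rec
  x_tar[region] <- x_tar[region] - depth_factor * mean(x_rec)
  x_tar
}

#' Sample a contiguous attack region
#'
#' @param n Signal length.
#' @param region_size Region length.
#' @param seed Optional seed.
#' @return Integer vector of region indices.
#' @export
sample_attack_region <- function(n, region_size = 50, seed = NULL) {
  if (region_size > n) stop_contract("`region_size` exceeds signal length")
  with_seed(seed, {
    start <- sample.int(n - region_size + 1, 1)
    seq(start, start + region_size - 1)
  })
}

#' Box-constrained adversarial perturbation of a network input
#'
#' Minimises `|| Phi(z_adv) - x_adv_tar ||_2^2` over `z_adv` inside the box,
#' starting from the clean input `z`, using bounded L-BFGS with analytic
#' gradients obtained by backpropagation. The returned point is feasible and
#' its objective never exceeds the starting objective (the start point is
#' returned, with a warning, should the solver fail to improve on it).
#'
#' @param net The prediction network under attack.
#' @param z Clean input vector (within the box).
#' @param x_adv_tar Adversarial target, same length as the network output.
#' @param cfg An [attack_config()].
#' @return List with `z_adv`, `objective` (final value), `start_objective`,
#'   and `converged`.
#' @export
adversarial_perturb <- function(net, z, x_adv_tar, cfg = attack_config()) {
  z <- as.numeric(z)
  if (any(z < cfg$box[1] - 1e-12) || any(z > cfg$box[2] + 1e-12)) {
    stop_contract("starting input must lie inside the box")
  }
  tar <- as.numeric(x_adv_tar)
  fn <- function(p) {
    out <- as.numeric(predict_network(net, p))
    sum((out - tar)^2)
  }
  gr <- function(p) {
    out <- predict_network(net, p)
    d_out <- 2 * (as.numeric(out) - tar)
    as.numeric(network_input_gradient(net, p, d_out)$d_input)
  }
  f0 <- fn(z)
  res <- tryCatch(
    stats::optim(z, fn, gr, method = "L-BFGS-B",
                 lower = cfg$box[1], upper = cfg$box[2],
                 control = list(maxit = cfg$max_iterations,
                                pgtol = cfg$tolerance)),
    error = function(e) NULL
  )
  if (is.null(res) || res$value > f0) {
    warning("adversarial optimisation failed to improve; returning the start point")
    return(list(z_adv = z, objective = f0, start_objective = f0,
                converged = FALSE))
  }
  z_adv <- pmin(pmax(res$par, cfg$box[1]), cfg$box[2])
  list(z_adv = z_adv, objective = res$value, start_objective = f0,
       converged = res$convergence == 0)
}
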