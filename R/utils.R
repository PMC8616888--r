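#' @keywords internal
#' @useDynLib innuq, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_contract <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_numeric_array <- function(x, name) {
  if (!is.numeric(x)) stop_contract("`%s` must be numeric", name)
  if (anyNA(x)) stop_contract("`%s` contains NA/NaN", name)
  invisible(x)
}

same_shape <- function(a, b) {
  identical(dim(a) %||% length(a), dim(b) %||% length(b))
}

check_same_shape <- function(a, b, name_a, name_b) {
  if (!same_shape(a, b)) {
    stop_contract("`%s` and `%s` must have identical shapes", name_a, name_b)
  }
  invisible(TRUE)
}

# Run `expr` with a temporarily seeded RNG when `seed` is given; the caller's
# RNG state is restored afterwards so seeded helpers do not perturb the
# global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

apply_activation <- function(x, activation) {
  switch(activation,
    relu = cpp_relu(x),
    identity = x,
    stop_contract("unknown activation '%s'", activation)
  )
}

# Gradient of `loss` w.r.t. a pre-activation: `d` is the gradient at the
# activation output (any shape of equal length); the result carries the shape
# of `pre`.
grad_through_activation <- function(d, pre, activation) {
  switch(activation,
    relu = cpp_relu_grad(d, pre),
    identity = structure(as.numeric(d), dim = dim(pre)),
    stop_contract("unknown activation '%s'", activation)
  )
}
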