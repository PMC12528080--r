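#' Activation functions
#'
#' Elementwise nonlinearities used across the network. `pf_activation()`
#' returns the function, `pf_activation_grad()` its derivative expressed
#' in terms of the pre-activation input.
#'
#' @param name one of `"tanh"`, `"relu"`, `"elu"`, `"swish"`,
#'   `"identity"`.
#' @return a vectorized function.
#' @export
pf_activation <- function(name) {
  switch(name,
    tanh = tanh,
    relu = function(u) { u[u < 0] <- 0; u },
    elu = function(u) { neg <- u < 0; u[neg] <- exp(u[neg]) - 1; u },
    swish = function(u) u / (1 + exp(-u)),
    identity = identity,
    abort(paste0("unknown activation: ", name)))
}

#' @rdname pf_activation
#' @export
pf_activation_grad <- function(name) {
  switch(name,
    tanh = function(u) 1 - tanh(u)^2,
    relu = function(u) { g <- u; g[] <- as.numeric(u > 0); g },
    elu = function(u) { neg <- u < 0; u[neg] <- exp(u[neg]); u[!neg] <- 1; u },
    swish = function(u) { s <- 1 / (1 + exp(-u)); s + u * s * (1 - s) },
    identity = function(u) { u[] <- 1; u },
    abort(paste0("unknown activation: ", name)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(u) 1 / (1 + exp(-u))
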