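#' Two-layer fused projection of the pathway latent
#'
#' `z_fused = phi(W2 phi(W1 z + b1) + b2)` maps the concatenated pathway
#' embeddings (length `P * d_h`) into a compact `d_z`-dimensional latent.
#'
#' @param z pathway latent vector.
#' @param head list with `W1` (`d_z x P d_h`), `b1`, `W2` (`d_z x d_z`),
#'   `b2`, `activation` (`"elu"` default, or `"swish"`).
#' @return vector of length `d_z`.
#' @export
fuse_projection <- function(z, head) {
  if (length(z) != ncol(head$W1)) abort("dimension mismatch")
  phi <- pf_activation(head$activation %||% "elu")
  drop(phi(head$W2 %*% phi(head$W1 %*% z + head$b1) + head$b2))
}

#' Diagonal-Gaussian latent encoder
#'
#' Linear heads on `z_fused` produce the mean and the log-variance of a
#' diagonal Gaussian; the log-variance is clamped to `[-10, 10]` so
#' `sigma = exp(logvar / 2)` is always strictly positive and finite.
#'
#' @param z_fused fused latent vector.
#' @param head list with `W_mu`, `b_mu`, `W_lv`, `b_lv`.
#' @return list with `mu`, `sigma`, `logvar`.
#' @export
encode_gaussian <- function(z_fused, head) {
  mu <- drop(head$W_mu %*% z_fused + head$b_mu)
  lv <- pmin(pmax(drop(head$W_lv %*% z_fused + head$b_lv), -10), 10)
  list(mu = mu, sigma = exp(lv / 2), logvar = lv)
}

#' Reparameterized Gaussian sample
#'
#' `z_tilde = mu + sigma * eps` with `eps ~ N(0, I)`, expressing the
#' stochastic latent as a differentiable transform of noise so gradients
#' pass through `(mu, sigma)`.
#'
#' @param mu,sigma Gaussian parameters.
#' @param eps standard-normal draw of the same length (injectable for
#'   tests; drawn internally when `NULL`).
#' @return latent sample `z_tilde`.
#' @export
reparameterize <- function(mu, sigma, eps = NULL) {
  if (is.null(eps)) eps <- rnorm(length(mu))
  mu + sigma * eps
}

#' Softmax class probabilities from the latent
#'
#' `y_hat = softmax(W_out z_tilde + b_out)`; components are positive and
#' sum to one.
#'
#' @param z_tilde latent vector.
#' @param classifier list with `W_out` (`C x d_z`), `b_out`.
#' @return probability vector of length C.
#' @export
plp_predict <- function(z_tilde, classifier) {
  softmax_vec(drop(classifier$W_out %*% z_tilde + classifier$b_out))
}

softmax_vec <- function(u) {
  e <- exp(u - max(u))
  e / sum(e)
}

softmax_cols <- function(U) {
  U <- sweep(U, 2, apply(U, 2, max))
  E <- exp(U)
  sweep(E, 2, colSums(E), `/`)
}
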