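#' Encode one modality block into the shared latent space
#'
#' `h = phi(W x_tilde + b)`: an affine projection of the masked feature
#' block followed by a modality-specific nonlinearity, mapping every
#' modality into a common `d_h`-dimensional space.
#'
#' @param x_block masked feature block (length `d_m`).
#' @param params_m list with `W` (`d_h x d_m`), `b` (`d_h`),
#'   `activation` name.
#' @return latent vector of length `d_h`.
#' @export
encode_modality <- function(x_block, params_m) {
  if (length(x_block) != ncol(params_m$W)) abort("dimension mismatch")
  phi <- pf_activation(params_m$activation %||% "tanh")
  drop(phi(params_m$W %*% x_block + params_m$b))
}

#' Which modalities of a sample are present
#'
#' A modality counts as present iff at least one of its mask entries is 1;
#' a fully masked block is an absent modality and is excluded from the
#' cross-modal attention summation.
#'
#' @param mask binary mask vector (length d).
#' @param blocks modality block index list.
#' @return logical vector of length M, named by modality.
#' @export
modality_presence <- function(mask, blocks) {
  vapply(blocks, function(idx) any(mask[idx] == 1), logical(1))
}

#' Cross-modal scaled-dot-product attention
#'
#' For each present modality m, scalar scores
#' `s_n = h^(m)' T_mn h^(n) / sqrt(d_h)` are computed against every other
#' present modality n, turned into weights by a softmax over those n, and
#' the attended vector is the weight-averaged `a^(m) = sum_n w_n h^(n)`.
#' Absent modalities are omitted from the summation; a modality with no
#' present partner falls back to `a^(m) = h^(m)`.
#'
#' @param h_list list of M latent vectors (length `d_h` each).
#' @param presence logical vector of present modalities.
#' @param T_params M x M list of `d_h x d_h` interaction matrices
#'   (`T_params[[m]][[n]]`; diagonal entries unused).
#' @param d_h latent dimension (scaling constant).
#' @return list with `a` (list of attended vectors) and `weights`
#'   (M x M matrix, `weights[m, n]` = attention of query m on key n; NA
#'   where undefined).
#' @export
cross_modal_attention <- function(h_list, presence, T_params, d_h) {
  M <- length(h_list)
  a <- vector("list", M)
  W <- matrix(NA_real_, M, M)
  for (m in seq_len(M)) {
    if (!presence[m]) { a[[m]] <- h_list[[m]]; next }
    others <- setdiff(which(presence), m)
    if (!length(others)) { a[[m]] <- h_list[[m]]; next }
    s <- vapply(others, function(n) {
      drop(crossprod(h_list[[m]], T_params[[m]][[n]] %*% h_list[[n]])) / sqrt(d_h)
    }, numeric(1))
    w <- exp(s - max(s)); w <- w / sum(w)
    W[m, others] <- w
    am <- 0
    for (j in seq_along(others)) am <- am + w[j] * h_list[[others[j]]]
    a[[m]] <- am
  }
  list(a = a, weights = W)
}

#' Gated residual fusion of a modality vector with its attended context
#'
#' `h' = h + g * a` with gate `g = sigmoid(W_g [h; a] + b_g)`: the
#' residual keeps the modality-specific signal intact while the gate
#' learns how much cross-modal context to blend in. With a zero gate the
#' output is exactly `h`.
#'
#' @param h modality latent vector.
#' @param a attended vector from [cross_modal_attention()].
#' @param gate_params list with `W` (`d_h x 2 d_h`) and `b` (`d_h`), or a
#'   fixed numeric gate vector `g` for diagnostics.
#' @return fused vector `h'`.
#' @export
gated_residual_fuse <- function(h, a, gate_params) {
  g <- if (is.numeric(gate_params)) gate_params
       else drop(sigmoid(gate_params$W %*% c(h, a) + gate_params$b))
  h + g * a
}

#' Pairwise cross-modal interaction score
#'
#' Diagnostic bilinear score `sigma(h_m' T_mn h_n)` between two modality
#' vectors; not part of the trained forward pass, exposed for exploratory
#' analysis of inter-modality alignment.
#'
#' @param h_m,h_n latent vectors.
#' @param T_mn interaction matrix.
#' @param activation `"tanh"` (default) or `"relu"`.
#' @return scalar interaction score.
#' @export
pairwise_interaction <- function(h_m, h_n, T_mn, activation = "tanh") {
  if (length(h_m) != nrow(T_mn) || length(h_n) != ncol(T_mn))
    abort("dimension mismatch")
  phi <- pf_activation(match.arg(activation, c("tanh", "relu")))
  phi(drop(crossprod(h_m, T_mn %*% h_n)))
}

#' Implicit low-rank multi-way interaction term
#'
#' Rank-R surrogate for the full M-way outer product of modality
#' embeddings, which is never materialized: term r contributes the
#' product of inner products `prod_m <h^(m), w_r^(m)>`. Off by default in
#' the model (`rank = 0`).
#'
#' @param h_list modality latent vectors.
#' @param factors list of R lists of factor vectors (per modality).
#' @return numeric vector of length R.
#' @export
lowrank_interaction <- function(h_list, factors) {
  vapply(factors, function(fr) {
    prod(vapply(seq_along(h_list),
                function(m) sum(h_list[[m]] * fr[[m]]), numeric(1)))
  }, numeric(1))
}
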