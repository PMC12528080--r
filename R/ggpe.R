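#' Build the initial per-feature node matrix
#'
#' Row j of the d x d_h node matrix combines the feature's own masked
#' signal with its modality's fused context:
#' `H0[j, ] = x_tilde[j] * w_j + h'_(mod(j))`, where `w_j` is a learned
#' per-feature embedding and `h'` the gated fusion output of the
#' feature's modality. A fully masked feature contributes its modality
#' context alone.
#'
#' @param x_tilde masked feature vector (length d).
#' @param blocks modality block index list.
#' @param fused list of fused modality vectors `h'` (length M).
#' @param W_node d x d_h per-feature embedding matrix.
#' @return d x d_h matrix.
#' @export
build_node_matrix <- function(x_tilde, blocks, fused, W_node) {
  H0 <- x_tilde * W_node
  for (m in seq_along(blocks)) {
    idx <- blocks[[m]]
    H0[idx, ] <- H0[idx, , drop = FALSE] +
      matrix(fused[[m]], length(idx), length(fused[[m]]), byrow = TRUE)
  }
  H0
}

#' One graph-convolution layer
#'
#' `H_next = sigma(A_hat H W)`: neighborhood aggregation through the
#' self-loop symmetric-normalized adjacency, a shared linear map, and an
#' elementwise nonlinearity.
#'
#' @param H d x d_h input node matrix.
#' @param A_hat normalized adjacency from [normalized_adjacency()].
#' @param W d_h x d_h layer weights.
#' @param activation activation name (default `"elu"`).
#' @return d x d_h output matrix.
#' @export
gcn_layer <- function(H, A_hat, W, activation = "elu") {
  if (ncol(H) != nrow(W)) abort("dimension mismatch")
  phi <- pf_activation(activation)
  as.matrix(phi(A_hat %*% (H %*% W)))
}

#' Pathway-mean pooling of node embeddings
#'
#' The pathway embedding is the arithmetic mean of the final-layer rows
#' of its member features: `p^(k) = mean_{j in P_k} H[j, ]`.
#'
#' @param H_final d x d_h node matrix after the last GCN layer.
#' @param members integer indices of the pathway's member features.
#' @return vector of length d_h.
#' @export
pathway_pool <- function(H_final, members) {
  if (!length(members)) abort("empty pathway (excluded upstream by min_size)")
  colMeans(H_final[members, , drop = FALSE])
}

#' Assemble the pathway-level latent vector
#'
#' Concatenates the pathway embeddings in collection order into one
#' vector of length `P * d_h`.
#'
#' @param pathway_vectors list of P vectors (length d_h each).
#' @return vector of length `P * d_h`.
#' @export
assemble_latent <- function(pathway_vectors) {
  unlist(pathway_vectors, use.names = FALSE)
}

#' Per-sample pathway embeddings
#'
#' Runs the deterministic forward pass and returns the pooled pathway
#' embeddings `p^(k)` for each requested sample as a long tibble,
#' suitable for inspection or export.
#'
#' @param model a [pf_model()] or [pf_fit()].
#' @param cohort the cohort to embed.
#' @param indices sample indices (default all).
#' @return tibble with `sample_id`, `pathway`, `dim`, `value`.
#' @export
pathway_embeddings <- function(model, cohort, indices = NULL) {
  if (inherits(model, "pf_fit")) model <- model$model
  if (is.null(indices)) indices <- seq_along(cohort$sample_ids)
  cache <- pf_forward(model, (cohort$x * cohort$mask)[indices, , drop = FALSE],
                      cohort$mask[indices, , drop = FALSE],
                      deterministic = TRUE)
  dimnames(cache$Parr) <- list(model$pathways$names,
                               cohort$sample_ids[indices],
                               paste0("dim", seq_len(model$dims$d_h)))
  as_tibble(as.data.frame.table(cache$Parr, responseName = "value",
                                stringsAsFactors = FALSE)) |>
    stats::setNames(c("pathway", "sample_id", "dim", "value")) |>
    dplyr::select("sample_id", "pathway", "dim", "value")
}

#' Write pathway embeddings as TSV
#' @param embeddings tibble from [pathway_embeddings()].
#' @param path output file.
#' @export
write_pathway_embeddings <- function(embeddings, path) {
  utils::write.table(as.data.frame(embeddings), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
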