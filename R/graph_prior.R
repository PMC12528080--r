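#' Combinatorial graph Laplacian
#'
#' `L = D - A` with unit edge weights over `d` nodes; symmetric with zero
#' row sums, positive semi-definite for undirected graphs.
#'
#' @param edges tibble with `from_idx`, `to_idx` (as from
#'   [read_edge_list()]) or a two-column integer matrix.
#' @param d number of nodes.
#' @return dense d x d matrix.
#' @export
build_laplacian <- function(edges, d) {
  A <- adjacency_matrix(edges, d)
  diag(Matrix::rowSums(A)) - as.matrix(A)
}

adjacency_matrix <- function(edges, d) {
  ei <- edge_index(edges)
  if (!nrow(ei)) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                             x = numeric(), dims = c(d, d)))
  Matrix::sparseMatrix(i = c(ei[, 1], ei[, 2]), j = c(ei[, 2], ei[, 1]),
                       x = 1, dims = c(d, d))
}

edge_index <- function(edges) {
  if (is.matrix(edges)) return(edges)
  cbind(edges$from_idx, edges$to_idx)
}

#' Heat diffusion kernel on a graph
#'
#' `K = exp(-beta * L)`, computed exactly via the symmetric
#' eigendecomposition `K = U exp(-beta Lambda) U'`. Since `L 1 = 0`, every
#' row of `K` sums to 1, so diffusion conserves total signal; `beta`
#' controls the diffusion strength (`beta = 0` gives the identity,
#' `beta -> Inf` the per-component stationary average).
#'
#' @param L graph Laplacian (symmetric PSD).
#' @param beta diffusion strength, `>= 0`.
#' @param max_dim guard on dense eigendecomposition size (default 2000).
#' @return dense symmetric kernel matrix.
#' @export
diffusion_kernel <- function(L, beta, max_dim = 2000) {
  if (beta < 0) abort("beta must be >= 0")
  d <- nrow(L)
  if (d > max_dim) abort(sprintf("dense diffusion kernel limited to d <= %d", max_dim))
  eig <- eigen(L, symmetric = TRUE)
  K <- eig$vectors %*% (exp(-beta * eig$values) * t(eig$vectors))
  (K + t(K)) / 2
}

#' Diffuse a masked feature vector over the graph
#'
#' `x_prop = K x_tilde`; because `K` rows sum to 1 the total signal
#' `sum(x_prop)` equals `sum(x_tilde)`.
#'
#' @param K diffusion kernel from [diffusion_kernel()].
#' @param x_tilde masked feature vector of length `nrow(K)`.
#' @return propagated vector.
#' @export
propagate <- function(K, x_tilde) {
  if (length(x_tilde) != ncol(K)) abort("dimension mismatch")
  drop(K %*% x_tilde)
}

#' Self-loop symmetric-normalized adjacency
#'
#' `A_hat = Dt^{-1/2} (A + I) Dt^{-1/2}` with `Dt` the degree matrix of
#' `A + I`; this is the propagation operator of the graph-convolution
#' layers. An isolated node keeps a unit self-entry.
#'
#' @inheritParams build_laplacian
#' @return sparse symmetric d x d matrix (`Matrix::dsCMatrix`-compatible).
#' @export
normalized_adjacency <- function(edges, d) {
  A <- adjacency_matrix(edges, d) + Matrix::Diagonal(d)
  dinv <- 1 / sqrt(Matrix::rowSums(A))
  Ah <- Matrix::Diagonal(d, dinv) %*% A %*% Matrix::Diagonal(d, dinv)
  methods::as(Ah, "generalMatrix")   # stable class for products downstream
}

#' Biological graph prior
#'
#' Bundles the Laplacian, the normalized self-loop adjacency used by the
#' GCN stack, and (lazily) the diffusion kernel of a feature-interaction
#' graph.
#'
#' @param edges edge tibble from [read_edge_list()] (or 2-col index matrix).
#' @param d number of features (graph nodes).
#' @param beta diffusion strength (default 1).
#' @param compute_kernel compute `K = exp(-beta L)` eagerly (default FALSE;
#'   [prior_kernel()] computes and caches it on demand).
#' @return object of class `pf_graph_prior` with `edges`, `d`, `L`,
#'   `A_hat`, `beta`, `K` (possibly NULL).
#' @export
graph_prior <- function(edges, d, beta = 1, compute_kernel = FALSE) {
  L <- build_laplacian(edges, d)
  pr <- structure(list(edges = edge_index(edges), d = d, beta = beta,
                       L = L, A_hat = normalized_adjacency(edges, d),
                       K = NULL),
                  class = "pf_graph_prior")
  if (compute_kernel) pr$K <- diffusion_kernel(L, beta)
  pr
}

#' Diffusion kernel of a graph prior (cached)
#' @param prior a [graph_prior()].
#' @return the kernel matrix `exp(-beta L)`.
#' @export
prior_kernel <- function(prior) {
  if (is.null(prior$K)) prior$K <- diffusion_kernel(prior$L, prior$beta)
  prior$K
}

#' @export
print.pf_graph_prior <- function(x, ...) {
  cat(sprintf("<pf_graph_prior> %d nodes, %d edges, beta = %g, kernel %s\n",
              x$d, nrow(x$edges), x$beta,
              if (is.null(x$K)) "not computed" else "cached"))
  invisible(x)
}

#' Export the prior's matrices as TSV for inspection
#' @param prior a [graph_prior()].
#' @param dir output directory.
#' @param kernel also export the diffusion kernel (default FALSE).
#' @export
write_graph_prior <- function(prior, dir, kernel = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mat <- function(m, path) {
    utils::write.table(as.matrix(m), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_mat(prior$L, file.path(dir, "laplacian.tsv"))
  write_mat(prior$A_hat, file.path(dir, "normalized_adjacency.tsv"))
  if (kernel) write_mat(prior_kernel(prior), file.path(dir, "diffusion_kernel.tsv"))
  invisible(dir)
}
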