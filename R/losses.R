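#' Composite-loss weights
#'
#' Weights of the semi-supervised composite objective
#' `L = L_pred + l1 L_weak + l2 L_context + l3 L_intra + l4 L_inter +
#' l5 L_entropy + l6 L_consist`, plus the cosine margin `delta` of the
#' inter-group hinge and the feature-dropout probability `p` of the
#' consistency perturbation.
#'
#' @param lambda numeric vector of the six nonnegative component weights.
#' @param delta cosine margin in `[-1, 1]` (default 0.3).
#' @param p dropout probability in `[0, 1]` (default 0.2): each feature
#'   is zeroed with probability `p`, i.e. kept with probability `1 - p`.
#' @return list of class `pf_loss_weights`.
#' @export
loss_weights <- function(lambda = c(0.5, 0.1, 0.1, 0.1, 0.01, 0.1),
                         delta = 0.3, p = 0.2) {
  if (length(lambda) != 6 || any(!is.finite(lambda)) || any(lambda < 0))
    abort("lambda must be six finite nonnegative weights")
  if (delta < -1 || delta > 1) abort("delta must lie in [-1, 1]")
  if (p < 0 || p > 1) abort("p must lie in [0, 1]")
  structure(list(lambda = lambda, delta = delta, p = p),
            class = "pf_loss_weights")
}

#' Supervised cross-entropy loss
#'
#' `-sum_i log p(y_i | y_hat_i)` over labeled samples; probabilities are
#' floored at 1e-12 before the log.
#'
#' @param predictions n x C matrix of probability rows.
#' @param labels integer labels in 1..C, `NA` = unlabeled (skipped).
#' @return nonnegative scalar.
#' @export
loss_pred <- function(predictions, labels) {
  keep <- which(!is.na(labels))
  if (!length(keep)) {
    warn("no labeled samples: L_pred = 0")
    return(0)
  }
  p <- predictions[cbind(keep, labels[keep])]
  -sum(log(pmax(p, 1e-12)))
}

#' Pseudo-label alignment loss
#'
#' `sum_i KL(y_tilde_i || y_hat_i)` over the weakly labeled set, with the
#' `0 log 0 = 0` convention. The divergence direction is from the soft
#' pseudo-label to the model prediction.
#'
#' @param pseudo_labels n' x C matrix of soft target rows (sum to 1).
#' @param predictions matching matrix of prediction rows.
#' @return nonnegative scalar.
#' @export
loss_weak <- function(pseudo_labels, predictions) {
  if (!nrow(pseudo_labels)) return(0)
  if (any(abs(rowSums(pseudo_labels) - 1) > 1e-6) ||
      any(abs(rowSums(predictions) - 1) > 1e-6))
    abort("loss_weak inputs must be probability rows")
  terms <- pseudo_labels * (log(pmax(pseudo_labels, 1e-300)) -
                            log(pmax(predictions, 1e-300)))
  terms[pseudo_labels == 0] <- 0
  sum(terms)
}

#' Entropy-minimisation loss
#'
#' `-sum_i sum_k y_hat_ik log y_hat_ik` over the weakly supervised set;
#' pushes predictions toward confident (low-entropy) distributions.
#'
#' @param predictions n' x C matrix of probability rows.
#' @return scalar in `[0, n' log C]`.
#' @export
loss_entropy <- function(predictions) {
  if (!nrow(predictions)) return(0)
  terms <- predictions * log(pmax(predictions, 1e-300))
  terms[predictions == 0] <- 0
  -sum(terms)
}

#' Pathway context projection
#'
#' `c = C x_tilde`: a soft aggregation of masked feature evidence into
#' per-pathway activation levels via the binary (or weighted) membership
#' matrix.
#'
#' @param x_tilde masked feature vector (length d) or n x d matrix.
#' @param C_matrix P x d membership matrix.
#' @return length-P vector (or P x n matrix for matrix input).
#' @export
context_projection <- function(x_tilde, C_matrix) {
  if (is.matrix(x_tilde)) {
    if (ncol(x_tilde) != ncol(C_matrix)) abort("dimension mismatch")
    return(C_matrix %*% t(x_tilde))
  }
  if (length(x_tilde) != ncol(C_matrix)) abort("dimension mismatch")
  drop(C_matrix %*% x_tilde)
}

#' Pathway-context alignment loss
#'
#' `sum_i || z_fused_i - W_c c_i ||^2`: penalizes divergence of the fused
#' latent from a learnable linear image of the pathway activations,
#' nudging the latent space toward biologically interpretable
#' configurations.
#'
#' @param z_fused d_z x n matrix of fused latents (columns = samples).
#' @param c_batch P x n matrix of context projections.
#' @param W_c d_z x P learnable alignment map.
#' @return nonnegative scalar.
#' @export
loss_context <- function(z_fused, c_batch, W_c) {
  r <- z_fused - W_c %*% c_batch
  sum(r^2)
}

#' Feature-wise dropout perturbation
#'
#' Zeroes each feature independently with probability `p` (keep
#' probability `1 - p`), emulating incomplete assays for the consistency
#' regularizer.
#'
#' @param x numeric vector or matrix.
#' @param p dropout probability in `[0, 1]`.
#' @return perturbed copy of `x` (same shape).
#' @export
feature_dropout <- function(x, p) {
  if (p < 0 || p > 1) abort("p must lie in [0, 1]")
  keep <- runif(length(x)) >= p
  x * keep
}

#' Dropout-consistency loss
#'
#' `sum_i || f(x_i) - f(x_i^drop) ||^2` between predictions on the
#' original and the feature-dropped inputs; symmetric in its arguments.
#'
#' @param pred_original,pred_dropped matching probability matrices.
#' @return nonnegative scalar.
#' @export
loss_consist <- function(pred_original, pred_dropped) {
  sum((pred_original - pred_dropped)^2)
}

#' Group centroids in latent space
#'
#' Mean latent vector per stratum; empty groups are skipped with a
#' warning.
#'
#' @param latents d_z x n matrix (columns = samples).
#' @param groups character/factor vector of strata (length n).
#' @return d_z x G matrix of centroids, columns named by group.
#' @export
group_centroids <- function(latents, groups) {
  gs <- unique(groups[!is.na(groups)])
  cent <- vapply(gs, function(g) {
    idx <- which(groups == g)
    rowMeans(latents[, idx, drop = FALSE])
  }, numeric(nrow(latents)))
  if (!is.matrix(cent)) cent <- matrix(cent, nrow(latents))
  colnames(cent) <- gs
  cent
}

#' Intra-group compactness loss
#'
#' `sum_g sum_{i in g} || z_i - zbar_g ||^2`: squared distances of member
#' latents to their group centroid.
#'
#' @inheritParams group_centroids
#' @param centroids optional precomputed [group_centroids()].
#' @return nonnegative scalar.
#' @export
loss_intra <- function(latents, groups, centroids = NULL) {
  if (is.null(centroids)) centroids <- group_centroids(latents, groups)
  tot <- 0
  for (g in colnames(centroids)) {
    idx <- which(groups == g)
    tot <- tot + sum((latents[, idx, drop = FALSE] - centroids[, g])^2)
  }
  tot
}

#' Inter-group angular separation loss
#'
#' Hinge on the cosine similarity of every unordered pair of distinct
#' group centroids: `sum_{g < g'} max(0, cos(zbar_g, zbar_g') - delta)`.
#' A zero-norm centroid has its cosine defined as 0 (with a warning).
#'
#' @param centroids d_z x G centroid matrix.
#' @param delta cosine margin.
#' @return nonnegative scalar.
#' @export
loss_inter <- function(centroids, delta) {
  G <- ncol(centroids)
  if (G < 2) return(0)
  nrm <- sqrt(colSums(centroids^2))
  if (any(nrm == 0)) warn("zero-norm centroid: cosine defined as 0")
  tot <- 0
  for (g in seq_len(G - 1)) for (h in seq((g + 1), G)) {
    cs <- if (nrm[g] == 0 || nrm[h] == 0) 0
          else sum(centroids[, g] * centroids[, h]) / (nrm[g] * nrm[h])
    tot <- tot + max(0, cs - delta)
  }
  tot
}

#' Weighted composite loss breakdown
#'
#' Combines the seven components into
#' `L_total = L_pred + l1 L_weak + l2 L_context + l3 L_intra +
#' l4 L_inter + l5 L_entropy + l6 L_consist`, keeping each unweighted
#' component in the returned breakdown.
#'
#' @param components named list/vector with `pred`, `weak`, `context`,
#'   `intra`, `inter`, `entropy`, `consist`.
#' @param weights a [loss_weights()].
#' @return tibble of class `pf_loss_breakdown` with one row holding the
#'   seven components and `total`.
#' @export
total_loss <- function(components, weights) {
  if (!inherits(weights, "pf_loss_weights")) abort("weights must come from loss_weights()")
  cm <- as.list(components)
  lam <- weights$lambda
  total <- cm$pred + lam[1] * cm$weak + lam[2] * cm$context +
    lam[3] * cm$intra + lam[4] * cm$inter + lam[5] * cm$entropy +
    lam[6] * cm$consist
  out <- tibble(pred = cm$pred, weak = cm$weak, context = cm$context,
                intra = cm$intra, inter = cm$inter, entropy = cm$entropy,
                consist = cm$consist, total = total)
  class(out) <- c("pf_loss_breakdown", class(out))
  out
}
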