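#' Gradient-based pathway attribution
#'
#' Sensitivity of the predicted class probability to each entry of the
#' pathway embeddings: `S[k, j] = d yhat_target / d p^(k)_j`, evaluated
#' by the analytic chain rule through the classifier, the Gaussian mean
#' head and the two-layer fused projection, in deterministic mode
#' (`z_tilde = mu`). When several samples are given, the per-sample maps
#' are averaged.
#'
#' @param model a [pf_model()] or [pf_fit()].
#' @param cohort the cohort to attribute on.
#' @param indices sample indices (default all).
#' @param target_class integer class index in `1..C` (default: each
#'   sample's predicted class).
#' @param raw_features also return the per-feature gradient vector
#'   `d yhat_target / d x` averaged over samples (signed).
#' @return object of class `pf_attribution`: list with `S` (P x d_h
#'   matrix, rows named by pathway), `per_pathway` (tibble ranking
#'   pathways by `score`, the mean over member features of the mean
#'   per-sample input-times-gradient contribution
#'   `x_j * d yhat_target / d x_j`, with the embedding-level aggregate
#'   `sum_j |S[k, j]|` kept as `embed_score`), `target_class`, and
#'   optionally `feature_gradient` (length-d named vector).
#'
#' @details The P x d_h map `S` quantifies sensitivity to the pathway
#'   *embeddings*; because the fused modality context contributes to
#'   every feature's node state, these embedding-level sensitivities are
#'   shared across pathways and do not localize pathway identity. The
#'   ranking therefore uses the full raw-feature chain-rule gradient
#'   (classifier through GCN, fusion and encoders down to the masked
#'   inputs) multiplied elementwise by the masked input — the
#'   first-order contribution of each observed feature to the target
#'   probability — aggregated within each pathway's member set.
#' @export
pf_attribute <- function(model, cohort, indices = NULL, target_class = NULL,
                         raw_features = FALSE) {
  if (inherits(model, "pf_fit")) model <- model$model
  if (is.null(indices)) indices <- seq_along(cohort$sample_ids)
  X <- (cohort$x * cohort$mask)[indices, , drop = FALSE]
  mask <- cohort$mask[indices, , drop = FALSE]
  cache <- pf_forward(model, X, mask, deterministic = TRUE)
  n <- cache$n; C <- model$dims$C
  if (!is.null(target_class) && (target_class < 1 || target_class > C))
    abort("target_class out of range")
  tgt <- if (is.null(target_class)) max.col(t(cache$yhat), ties.method = "first")
         else rep(target_class, n)

  # d yhat_tgt / d logits = yhat_tgt * (e_tgt - yhat)
  yt <- cache$yhat[cbind(tgt, seq_len(n))]
  dLog <- -cache$yhat * rep(yt, each = C)
  dLog[cbind(tgt, seq_len(n))] <- dLog[cbind(tgt, seq_len(n))] + yt

  p <- model$params
  fgrad <- pf_activation_grad(model$config$fuse_activation)
  dzt <- crossprod(p$clf$W_out, dLog)
  dmu <- dzt                                   # deterministic: zt = mu
  dzf <- crossprod(p$head$W_mu, dmu)
  dU2 <- dzf * fgrad(cache$U2)
  dF1 <- crossprod(p$fuse$W2, dU2)
  dU1 <- dF1 * fgrad(cache$U1)
  dZ <- crossprod(p$fuse$W1, dU1)              # (P*d_h) x n

  d_h <- model$dims$d_h; P <- model$dims$P
  Sarr <- array(dZ, c(d_h, P, n))
  S <- t(apply(Sarr, c(1, 2), mean))           # P x d_h
  dimnames(S) <- list(model$pathways$names, paste0("dim", seq_len(d_h)))

  dX <- attribution_feature_gradient(model, cache, dZ) * mask
  # first-order contribution of each observed feature to the target
  # probability: gradient times masked input, averaged over samples
  feat_score <- colMeans(dX * X)
  agg <- vapply(model$pathways$pathways, function(mem)
    mean(feat_score[mem]), numeric(1))
  per <- tibble(pathway = model$pathways$names, score = unname(agg),
                embed_score = rowSums(abs(S))) |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::mutate(rank = dplyr::row_number())

  out <- list(S = S, per_pathway = per,
              target_class = if (is.null(target_class)) NA_integer_
                             else target_class,
              n_samples = n)
  if (raw_features) {
    fg <- colMeans(dX)                         # d x_tilde / d x = mask
    names(fg) <- model$feature_ids
    out$feature_gradient <- fg
  }
  structure(out, class = "pf_attribution")
}

# continue the chain rule from dZ (pathway-latent gradient) down to the
# raw input features; returns n x d matrix of input gradients
attribution_feature_gradient <- function(model, cache, dZ) {
  p <- model$params; dims <- model$dims; cfg <- model$config
  n <- cache$n; d <- dims$d; d_h <- dims$d_h; M <- dims$M
  dParr <- aperm(array(dZ, c(d_h, dims$P, n)), c(2, 3, 1))
  dim(dParr) <- c(dims$P, n * d_h)
  dH <- as.matrix(crossprod(model$pool, dParr))          # d x (n*d_h)
  for (l in rev(seq_len(dims$L))) {
    dPre <- dH * act_grad_fast(cfg$gcn_activation, cache$Hs[[l + 1]],
                               cache$Pre[[l]])
    dG <- (model$prior$A_hat %*% dPre)@x
    dim(dG) <- c(d * n, d_h)
    dH <- dG %*% t(p$gcn[[l]])
    dim(dH) <- c(d, n * d_h)
  }
  # node matrix: rows are x_tilde[j] * w_j + context
  dHmat <- dH
  dim(dHmat) <- c(d * n, d_h)
  dXt <- matrix(rowSums(dHmat * p$node$W[rep(seq_len(d), n), , drop = FALSE]),
                d, n)
  BH <- model$bmat %*% dH
  dHp <- vector("list", M)
  for (m in seq_len(M)) {
    v <- BH[m, ]
    dim(v) <- c(n, d_h)
    dHp[[m]] <- t(v)
  }
  dHm <- vector("list", M); dA <- vector("list", M)
  for (m in seq_len(M)) {
    if (cfg$gate) {
      dA[[m]] <- dHp[[m]] * cache$GG[[m]]
      dPreg <- (dHp[[m]] * cache$A[[m]]) * cache$GG[[m]] * (1 - cache$GG[[m]])
      dU <- crossprod(p$gate[[m]]$W, dPreg)
      dHm[[m]] <- dHp[[m]] + dU[seq_len(d_h), , drop = FALSE]
      dA[[m]] <- dA[[m]] + dU[d_h + seq_len(d_h), , drop = FALSE]
    } else {
      dHm[[m]] <- dHp[[m]]; dA[[m]] <- dHp[[m]]
    }
  }
  sq <- sqrt(d_h)
  for (m in seq_len(M)) {
    ac <- cache$attcols[[m]]
    if (any(!ac))
      dHm[[m]][, !ac] <- dHm[[m]][, !ac, drop = FALSE] + dA[[m]][, !ac, drop = FALSE]
    if (!any(ac)) next
    W <- cache$Wt[[m]]
    dW <- matrix(0, M, n)
    for (k in seq_len(M)) {
      if (k == m) next
      dW[k, ac] <- colSums((dA[[m]] * cache$H[[k]])[, ac, drop = FALSE])
      wk <- W[k, ]; wk[!ac] <- 0
      dHm[[k]] <- dHm[[k]] + dA[[m]] * rep(wk, each = d_h)
    }
    dS <- W * sweep(dW, 2, colSums(W * dW))
    dS[, !ac] <- 0
    for (k in seq_len(M)) {
      if (k == m) next
      coef <- dS[k, ] / sq
      if (!any(coef != 0)) next
      dHm[[m]] <- dHm[[m]] + cache$TH[[m]][[k]] * rep(coef, each = d_h)
      dHm[[k]] <- dHm[[k]] + crossprod(p$Tmn[[m]][[k]], cache$H[[m]]) * rep(coef, each = d_h)
    }
  }
  mod_names <- names(dims$blocks)
  enc_acts <- enc_activation_of(cfg, mod_names)
  for (m in seq_len(M)) {
    dPre <- dHm[[m]] * pf_activation_grad(enc_acts[m])(cache$U_enc[[m]])
    dXt[dims$blocks[[m]], ] <- dXt[dims$blocks[[m]], , drop = FALSE] +
      crossprod(p$enc[[m]]$W, dPre)
  }
  dX <- t(dXt)
  if (cfg$diffuse_input) dX <- dX %*% model$kernel
  dX
}

#' @export
print.pf_attribution <- function(x, ...) {
  cat(sprintf("<pf_attribution> %d pathways x %d dims, averaged over %d sample(s)\n",
              nrow(x$S), ncol(x$S), x$n_samples))
  print(head(x$per_pathway, 5))
  invisible(x)
}

#' Export an attribution map and its pathway ranking
#'
#' Writes the P x d_h sensitivity matrix and the per-pathway ranking
#' (feature-gradient `score` plus the embedding-level `embed_score`)
#' as TSV files.
#'
#' @param attribution a [pf_attribute()] result.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_attribution <- function(attribution, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- file.path(dir, "attribution_matrix.tsv")
  rp <- file.path(dir, "pathway_ranking.tsv")
  utils::write.table(attribution$S, sp, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(as.data.frame(attribution$per_pathway), rp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(matrix = sp, ranking = rp))
}
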