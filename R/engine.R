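# Vectorized forward and backward passes.
#
# All per-sample quantities are carried in matrices with one column per
# sample (modality latents: d_h x n) or in 3-d arrays with canonical
# layout (d, n, d_h) for node states, so every heavy step is a single
# BLAS or sparse product over the whole batch. The per-sample operations
# exported from the fusion/embedding/prediction modules define the
# semantics; tests pin the engine to them.

# Activation derivatives computed from cached *outputs* where the
# function allows it (elu' = min(out + 1, 1), tanh' = 1 - out^2,
# relu' = [out > 0]), avoiding a second exp/tanh evaluation; swish falls
# back to the pre-activation form.
act_grad_fast <- function(name, out, pre) {
  switch(name,
    elu = { g <- out + 1; g[g > 1] <- 1; g },
    tanh = 1 - out^2,
    relu = { g <- out; g[] <- as.numeric(out > 0); g },
    pf_activation_grad(name)(pre))
}

#' Batch forward pass
#'
#' Runs the full network on a batch: modality encoders, cross-modal
#' attention with missing-modality exclusion, gated residual fusion,
#' per-feature node assembly, the GCN stack over the graph prior,
#' pathway-mean pooling, the two-layer fused projection, the
#' diagonal-Gaussian head, reparameterization (or the deterministic
#' `z_tilde = mu` in evaluation mode) and the softmax classifier.
#'
#' @param model a [pf_model()].
#' @param X n x d matrix of masked feature values (zeros at unobserved
#'   positions).
#' @param mask n x d observation mask.
#' @param eps optional `d_z x n` matrix of standard-normal draws; when
#'   `NULL` and `deterministic = FALSE` they are drawn internally.
#' @param deterministic use `z_tilde = mu` (evaluation/attribution mode).
#' @return a cache list; `cache$yhat` holds the C x n probability
#'   columns, `cache$Z` the pathway latents, `cache$Zf`, `cache$mu`,
#'   `cache$zt` the head states.
#' @export
pf_forward <- function(model, X, mask, eps = NULL, deterministic = is.null(eps)) {
  p <- model$params; cfg <- model$config; dims <- model$dims
  n <- nrow(X); d <- dims$d; d_h <- dims$d_h; d_z <- dims$d_z; M <- dims$M
  stopifnot(ncol(X) == d, n >= 1)
  X <- X * mask                                   # enforce x-tilde convention
  if (cfg$diffuse_input) X <- X %*% model$kernel  # K symmetric
  Xt <- t(X)                                      # d x n
  blocks <- dims$blocks
  pres <- matrix(FALSE, M, n)
  for (m in seq_len(M)) pres[m, ] <- rowSums(mask[, blocks[[m]], drop = FALSE] != 0) > 0
  mod_names <- names(blocks)
  enc_acts <- enc_activation_of(cfg, mod_names)

  # --- modality encoders -------------------------------------------------
  U_enc <- H <- vector("list", M)
  for (m in seq_len(M)) {
    U_enc[[m]] <- p$enc[[m]]$W %*% Xt[blocks[[m]], , drop = FALSE] + p$enc[[m]]$b
    H[[m]] <- pf_activation(enc_acts[m])(U_enc[[m]])
  }

  # --- cross-modal attention --------------------------------------------
  TH <- vector("list", M)        # TH[[m]][[k]] = T_mk %*% H_k
  S <- Wt <- vector("list", M)   # scores / weights, M x n each
  A <- vector("list", M)         # attended vectors
  attcols <- vector("list", M)
  sq <- sqrt(d_h)
  for (m in seq_len(M)) {
    S[[m]] <- matrix(-Inf, M, n)
    TH[[m]] <- vector("list", M)
    for (k in seq_len(M)) {
      if (k == m) next
      TH[[m]][[k]] <- p$Tmn[[m]][[k]] %*% H[[k]]
      s <- colSums(H[[m]] * TH[[m]][[k]]) / sq
      ok <- pres[m, ] & pres[k, ]
      S[[m]][k, ok] <- s[ok]
    }
    mx <- suppressWarnings(apply(S[[m]], 2, max))
    ac <- is.finite(mx)
    attcols[[m]] <- ac
    W <- matrix(0, M, n)
    if (any(ac)) {
      E <- exp(sweep(S[[m]][, ac, drop = FALSE], 2, mx[ac]))
      E[!is.finite(E)] <- 0
      W[, ac] <- sweep(E, 2, colSums(E), `/`)
    }
    Wt[[m]] <- W
    Am <- matrix(0, d_h, n)
    for (k in seq_len(M)) {
      if (k == m) next
      Am <- Am + H[[k]] * rep(W[k, ], each = d_h)
    }
    if (any(!ac)) Am[, !ac] <- H[[m]][, !ac, drop = FALSE]  # self-fallback
    A[[m]] <- Am
  }

  # --- gated residual fusion --------------------------------------------
  GU <- GG <- Hp <- vector("list", M)
  for (m in seq_len(M)) {
    if (cfg$gate) {
      GU[[m]] <- rbind(H[[m]], A[[m]])
      GG[[m]] <- sigmoid(p$gate[[m]]$W %*% GU[[m]] + p$gate[[m]]$b)
      Hp[[m]] <- H[[m]] + GG[[m]] * A[[m]]
    } else {
      Hp[[m]] <- H[[m]] + A[[m]]
    }
  }

  # --- per-feature node matrix --------------------------------------------
  # node states live in d x (n*d_h) matrices: the column-major layout of
  # (j, i, k) makes the switch to (d*n) x d_h a free dim<-, so the layer
  # map (right product with W) and neighborhood aggregation (left product
  # with A_hat) both run without reshape copies
  H0 <- Xt[, rep(seq_len(n), times = d_h), drop = FALSE] *
    p$node$W[, rep(seq_len(d_h), each = n), drop = FALSE]
  HpW <- matrix(0, M, n * d_h)                   # HpW[m, (k-1)n+i] = Hp_m[k, i]
  for (m in seq_len(M)) HpW[m, ] <- as.vector(t(Hp[[m]]))
  H0 <- H0 + crossprod(model$bmat, HpW)

  # --- GCN stack ---------------------------------------------------------
  A_hat <- model$prior$A_hat
  gphi <- pf_activation(cfg$gcn_activation)
  keep_pre <- !cfg$gcn_activation %in% c("elu", "tanh", "relu")
  Hs <- vector("list", dims$L + 1); Pre <- vector("list", dims$L)
  Hs[[1]] <- H0
  for (l in seq_len(dims$L)) {
    G <- Hs[[l]]
    dim(G) <- c(d * n, d_h)
    G <- G %*% p$gcn[[l]]
    dim(G) <- c(d, n * d_h)
    Sl <- (A_hat %*% G)@x
    dim(Sl) <- c(d, n * d_h)
    if (keep_pre) Pre[[l]] <- Sl
    Hs[[l + 1]] <- gphi(Sl)
  }
  HL <- Hs[[dims$L + 1]]

  # --- pathway pooling and latent assembly ------------------------------
  P <- dims$P
  Parr <- as.matrix(model$pool %*% HL)
  dim(Parr) <- c(P, n, d_h)
  Z <- matrix(aperm(Parr, c(3, 1, 2)), P * d_h, n)

  # --- variational head and classifier ----------------------------------
  fphi <- pf_activation(cfg$fuse_activation)
  U1 <- p$fuse$W1 %*% Z + p$fuse$b1
  F1 <- fphi(U1)
  U2 <- p$fuse$W2 %*% F1 + p$fuse$b2
  Zf <- fphi(U2)
  mu <- p$head$W_mu %*% Zf + p$head$b_mu
  lv_raw <- p$head$W_lv %*% Zf + p$head$b_lv
  lv <- pmin(pmax(lv_raw, -10), 10)
  clamped <- lv_raw < -10 | lv_raw > 10
  sig <- exp(lv / 2)
  if (deterministic) {
    zt <- mu; eps <- NULL
  } else {
    if (is.null(eps)) eps <- matrix(rnorm(d_z * n), d_z, n)
    zt <- mu + sig * eps
  }
  logits <- p$clf$W_out %*% zt + p$clf$b_out
  yhat <- softmax_cols(logits)

  list(n = n, X = X, Xt = Xt, mask = mask, pres = pres,
       U_enc = U_enc, H = H, TH = TH, S = S, Wt = Wt, A = A,
       attcols = attcols, GU = GU, GG = GG, Hp = Hp,
       Hs = Hs, Pre = Pre, HL = HL, Parr = Parr, Z = Z,
       U1 = U1, F1 = F1, U2 = U2, Zf = Zf,
       mu = mu, lv = lv, clamped = clamped, sig = sig, eps = eps,
       zt = zt, logits = logits, yhat = yhat,
       deterministic = deterministic)
}

#' Batch backward pass
#'
#' Backpropagates an upstream gradient through the cached forward pass,
#' accumulating gradients for every parameter. Upstream gradients can be
#' injected at the logits (classification-type losses), at the latent
#' `z_tilde` (group-geometry losses) and at the fused latent `z_fused`
#' (context alignment).
#'
#' @param model a [pf_model()].
#' @param cache forward cache from [pf_forward()].
#' @param dLogits C x n gradient at the logits (post-softmax losses must
#'   already be mapped through the softmax Jacobian).
#' @param dZt d_z x n gradient at `z_tilde` (or NULL).
#' @param dZf d_z x n gradient at `z_fused` (or NULL).
#' @return gradient structure matching `model$params`.
#' @export
pf_backward <- function(model, cache, dLogits, dZt = NULL, dZf = NULL) {
  p <- model$params; cfg <- model$config; dims <- model$dims
  n <- cache$n; d <- dims$d; d_h <- dims$d_h; M <- dims$M
  g <- param_zeros_like(p)
  fact <- cfg$fuse_activation; gact <- cfg$gcn_activation

  # classifier
  g$clf$W_out <- dLogits %*% t(cache$zt)
  g$clf$b_out <- rowSums(dLogits)
  dzt <- crossprod(p$clf$W_out, dLogits)
  if (!is.null(dZt)) dzt <- dzt + dZt

  # reparameterization
  if (cache$deterministic) {
    dmu <- dzt
    dlv <- matrix(0, dims$d_z, n)
  } else {
    dmu <- dzt
    dsig <- dzt * cache$eps
    dlv <- dsig * cache$sig / 2
    dlv[cache$clamped] <- 0
  }
  g$head$W_mu <- dmu %*% t(cache$Zf)
  g$head$b_mu <- rowSums(dmu)
  g$head$W_lv <- dlv %*% t(cache$Zf)
  g$head$b_lv <- rowSums(dlv)
  dzf <- crossprod(p$head$W_mu, dmu) + crossprod(p$head$W_lv, dlv)
  if (!is.null(dZf)) dzf <- dzf + dZf

  # fused projection
  dU2 <- dzf * act_grad_fast(fact, cache$Zf, cache$U2)
  g$fuse$W2 <- dU2 %*% t(cache$F1)
  g$fuse$b2 <- rowSums(dU2)
  dF1 <- crossprod(p$fuse$W2, dU2)
  dU1 <- dF1 * act_grad_fast(fact, cache$F1, cache$U1)
  g$fuse$W1 <- dU1 %*% t(cache$Z)
  g$fuse$b1 <- rowSums(dU1)
  dZ <- crossprod(p$fuse$W1, dU1)

  # pooling
  dParr <- aperm(array(dZ, c(d_h, dims$P, n)), c(2, 3, 1))
  dim(dParr) <- c(dims$P, n * d_h)
  dH <- as.matrix(crossprod(model$pool, dParr))          # d x (n*d_h)

  # GCN stack (reverse)
  A_hat <- model$prior$A_hat
  for (l in rev(seq_len(dims$L))) {
    dPre <- dH * act_grad_fast(gact, cache$Hs[[l + 1]], cache$Pre[[l]])
    dG <- (A_hat %*% dPre)@x                             # A_hat symmetric
    dim(dG) <- c(d * n, d_h)
    Hmat <- cache$Hs[[l]]
    dim(Hmat) <- c(d * n, d_h)
    g$gcn[[l]] <- crossprod(Hmat, dG)
    dH <- dG %*% t(p$gcn[[l]])
    dim(dH) <- c(d, n * d_h)
  }

  # node matrix: dH is d x (n*d_h); rows were x_tilde_j w_j + context
  E <- dH * as.vector(cache$Xt)                          # recycles over k
  rsel <- Matrix::sparseMatrix(i = seq_len(n * d_h),
                               j = rep(seq_len(d_h), each = n), x = 1,
                               dims = c(n * d_h, d_h))
  g$node$W <- as.matrix(E %*% rsel)
  BH <- model$bmat %*% dH                                # M x (n*d_h)
  dHp <- vector("list", M)
  for (m in seq_len(M)) {
    v <- BH[m, ]
    dim(v) <- c(n, d_h)
    dHp[[m]] <- t(v)                                     # d_h x n
  }

  # gated residual fusion
  dHm <- vector("list", M); dA <- vector("list", M)
  for (m in seq_len(M)) {
    if (cfg$gate) {
      dG_ <- dHp[[m]] * cache$A[[m]]
      dA[[m]] <- dHp[[m]] * cache$GG[[m]]
      dPreg <- dG_ * cache$GG[[m]] * (1 - cache$GG[[m]])
      g$gate[[m]]$W <- dPreg %*% t(cache$GU[[m]])
      g$gate[[m]]$b <- rowSums(dPreg)
      dU <- crossprod(p$gate[[m]]$W, dPreg)
      dHm[[m]] <- dHp[[m]] + dU[seq_len(d_h), , drop = FALSE]
      dA[[m]] <- dA[[m]] + dU[d_h + seq_len(d_h), , drop = FALSE]
    } else {
      dHm[[m]] <- dHp[[m]]
      dA[[m]] <- dHp[[m]]
    }
  }

  # cross-modal attention
  sq <- sqrt(d_h)
  for (m in seq_len(M)) {
    ac <- cache$attcols[[m]]
    if (any(!ac)) {              # self-fallback columns
      dHm[[m]][, !ac] <- dHm[[m]][, !ac, drop = FALSE] + dA[[m]][, !ac, drop = FALSE]
    }
    if (!any(ac)) next
    W <- cache$Wt[[m]]
    dW <- matrix(0, M, n)
    for (k in seq_len(M)) {
      if (k == m) next
      dW[k, ac] <- colSums((dA[[m]] * cache$H[[k]])[, ac, drop = FALSE])
      wk <- W[k, ]; wk[!ac] <- 0
      dHm[[k]] <- dHm[[k]] + dA[[m]] * rep(wk, each = d_h)
    }
    inner <- colSums(W * dW)
    dS <- W * sweep(dW, 2, inner)
    dS[, !ac] <- 0
    for (k in seq_len(M)) {
      if (k == m) next
      coef <- dS[k, ] / sq
      if (!any(coef != 0)) next
      dHm[[m]] <- dHm[[m]] + cache$TH[[m]][[k]] * rep(coef, each = d_h)
      dHm[[k]] <- dHm[[k]] + crossprod(p$Tmn[[m]][[k]], cache$H[[m]]) * rep(coef, each = d_h)
      g$Tmn[[m]][[k]] <- g$Tmn[[m]][[k]] +
        (cache$H[[m]] * rep(coef, each = d_h)) %*% t(cache$H[[k]])
    }
  }

  # modality encoders
  mod_names <- names(dims$blocks)
  enc_acts <- enc_activation_of(cfg, mod_names)
  for (m in seq_len(M)) {
    dPre <- dHm[[m]] * act_grad_fast(enc_acts[m], cache$H[[m]], cache$U_enc[[m]])
    g$enc[[m]]$W <- dPre %*% t(cache$Xt[dims$blocks[[m]], , drop = FALSE])
    g$enc[[m]]$b <- rowSums(dPre)
  }
  g
}
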