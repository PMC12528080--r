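#' Training configuration
#'
#' Optimization defaults follow the decoupled-weight-decay adaptive
#' optimizer with an initial learning rate of 1e-4, linear decay with
#' warm-up over the first 10% of steps, gradient clipping at global norm
#' 1.0, and early stopping on validation accuracy with a patience of five
#' epochs. Splits are stratified by class.
#'
#' @param learning_rate initial learning rate.
#' @param warmup_frac fraction of total steps used for linear warm-up.
#' @param schedule `"linear"` decay (to 0) or `"constant"`.
#' @param clip_norm maximum global gradient norm.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum number of epochs.
#' @param patience early-stopping patience (epochs, `>= 1`).
#' @param split train/val/test fractions (sum to 1).
#' @param weights a [loss_weights()].
#' @param entropy_on which samples the entropy term ranges over:
#'   `"pseudo"` (the weakly supervised set, default) or `"all"`.
#' @param seed master seed; per-component streams (split, shuffling,
#'   latent noise, dropout, initialization) are derived from it.
#' @return list of class `pf_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, warmup_frac = 0.1,
                         schedule = c("linear", "constant"),
                         clip_norm = 1.0, weight_decay = 0.01,
                         batch_size = 64, max_epochs = 80, patience = 5,
                         split = c(train = 0.7, val = 0.15, test = 0.15),
                         weights = loss_weights(),
                         entropy_on = c("pseudo", "all"),
                         seed = 1) {
  if (abs(sum(split) - 1) > 1e-9) abort("split fractions must sum to 1")
  if (patience < 1) abort("patience must be >= 1")
  structure(list(learning_rate = learning_rate, warmup_frac = warmup_frac,
                 schedule = match.arg(schedule), clip_norm = clip_norm,
                 weight_decay = weight_decay, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 split = split, weights = weights,
                 entropy_on = match.arg(entropy_on), seed = seed),
            class = "pf_train_config")
}

#' Stratified train/validation/test split
#'
#' Shuffles within each class and allocates fractions per class, so every
#' class is represented in every partition; unlabeled samples go to the
#' training partition (they contribute only unsupervised terms).
#'
#' @param y integer labels (NA = unlabeled).
#' @param split named fractions summing to 1.
#' @param seed RNG seed.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(y, split = c(train = 0.7, val = 0.15, test = 0.15),
                             seed = 1) {
  set.seed(seed)
  parts <- list(train = integer(), val = integer(), test = integer())
  for (c_ in sort(unique(y[!is.na(y)]))) {
    idx <- sample(which(y == c_))
    n_c <- length(idx)
    n_tr <- round(split[[1]] * n_c)
    n_va <- round(split[[2]] * n_c)
    if (n_tr < 1) abort(sprintf("class %d absent from the training split", c_))
    parts$train <- c(parts$train, idx[seq_len(n_tr)])
    parts$val <- c(parts$val, idx[n_tr + seq_len(min(n_va, n_c - n_tr))])
    parts$test <- c(parts$test, idx[setdiff(seq_len(n_c), seq_len(n_tr + n_va))])
  }
  parts$train <- sort(c(parts$train, which(is.na(y))))
  parts$val <- sort(parts$val); parts$test <- sort(parts$test)
  parts
}

# composite loss and its parameter gradient on one mini-batch; when a
# dropout mask is given, the clean and perturbed passes share one
# double-width forward/backward call (columns 1..n clean, n+1..2n dropped)
loss_step <- function(model, Xb, maskb, yb, pseudob, groupb, weights,
                      entropy_on = "pseudo", eps = NULL, drop_keep = NULL) {
  lam <- weights$lambda
  n <- nrow(Xb); C <- model$dims$C; d_z <- model$dims$d_z
  two_pass <- !is.null(drop_keep)
  if (two_pass) {
    cache <- pf_forward(model, rbind(Xb, Xb * drop_keep), rbind(maskb, maskb),
                        eps = if (is.null(eps)) NULL else cbind(eps, eps),
                        deterministic = is.null(eps))
  } else {
    cache <- pf_forward(model, Xb, maskb, eps = eps,
                        deterministic = is.null(eps))
  }
  i1 <- seq_len(n)
  yhat1 <- cache$yhat[, i1, drop = FALSE]                # C x n (clean pass)
  yhat2 <- if (two_pass) cache$yhat[, n + i1, drop = FALSE]
  zt1 <- cache$zt[, i1, drop = FALSE]
  Zf1 <- cache$Zf[, i1, drop = FALSE]
  Yrows <- t(yhat1)

  has_pseudo <- !is.null(pseudob) && any(!is.na(pseudob[, 1]))
  ps_idx <- if (has_pseudo) which(!is.na(pseudob[, 1])) else integer()
  ent_idx <- if (entropy_on == "all") seq_len(n) else ps_idx

  comp <- list(pred = loss_pred(Yrows, yb),
               weak = if (length(ps_idx))
                 loss_weak(pseudob[ps_idx, , drop = FALSE],
                           Yrows[ps_idx, , drop = FALSE]) else 0,
               entropy = if (length(ent_idx))
                 loss_entropy(Yrows[ent_idx, , drop = FALSE]) else 0,
               context = 0, intra = 0, inter = 0, consist = 0)

  # context alignment on the clean pass
  Cc <- model$pathways$C_matrix %*% t(Xb * maskb)        # P x n
  rctx <- Zf1 - model$params$ctx$W_c %*% Cc
  comp$context <- sum(rctx^2)

  # group geometry on the stochastic latents of the clean pass
  gi <- which(!is.na(groupb))
  cent <- NULL
  if (length(gi)) {
    cent <- group_centroids(zt1[, gi, drop = FALSE], groupb[gi])
    comp$intra <- loss_intra(zt1[, gi, drop = FALSE], groupb[gi], cent)
    comp$inter <- loss_inter(cent, weights$delta)
  }

  if (two_pass) comp$consist <- loss_consist(t(yhat1), t(yhat2))

  breakdown <- total_loss(comp, weights)

  # ---- gradients --------------------------------------------------------
  dLog1 <- matrix(0, C, n)
  lab <- which(!is.na(yb))
  if (length(lab)) {
    oneh <- matrix(0, C, length(lab))
    oneh[cbind(yb[lab], seq_along(lab))] <- 1
    dLog1[, lab] <- dLog1[, lab] + (yhat1[, lab, drop = FALSE] - oneh)
  }
  if (length(ps_idx) && lam[1] > 0) {
    dLog1[, ps_idx] <- dLog1[, ps_idx] +
      lam[1] * (yhat1[, ps_idx, drop = FALSE] - t(pseudob[ps_idx, , drop = FALSE]))
  }
  if (length(ent_idx) && lam[5] > 0) {
    yh <- yhat1[, ent_idx, drop = FALSE]
    dY <- -(log(pmax(yh, 1e-300)) + 1)
    dLog1[, ent_idx] <- dLog1[, ent_idx] +
      lam[5] * yh * sweep(dY, 2, colSums(yh * dY))
  }
  dLog2 <- NULL
  if (two_pass && lam[6] > 0) {
    D <- 2 * (yhat1 - yhat2)
    dLog1 <- dLog1 + lam[6] * yhat1 * sweep(D, 2, colSums(yhat1 * D))
    dLog2 <- lam[6] * yhat2 * sweep(-D, 2, colSums(yhat2 * (-D)))
  }

  dZt <- matrix(0, d_z, n)
  if (length(gi) && (lam[3] > 0 || lam[4] > 0)) {
    if (lam[3] > 0) {
      for (g in colnames(cent)) {
        ii <- gi[groupb[gi] == g]
        dZt[, ii] <- dZt[, ii] +
          lam[3] * 2 * (zt1[, ii, drop = FALSE] - cent[, g])
      }
    }
    if (lam[4] > 0 && ncol(cent) >= 2) {
      nrm <- sqrt(colSums(cent^2))
      dCent <- cent * 0
      G <- ncol(cent)
      for (a in seq_len(G - 1)) for (b in seq((a + 1), G)) {
        if (nrm[a] == 0 || nrm[b] == 0) next
        cs <- sum(cent[, a] * cent[, b]) / (nrm[a] * nrm[b])
        if (cs <= weights$delta) next
        dCent[, a] <- dCent[, a] +
          cent[, b] / (nrm[a] * nrm[b]) - cs * cent[, a] / nrm[a]^2
        dCent[, b] <- dCent[, b] +
          cent[, a] / (nrm[a] * nrm[b]) - cs * cent[, b] / nrm[b]^2
      }
      for (g in colnames(cent)) {
        ii <- gi[groupb[gi] == g]
        dZt[, ii] <- dZt[, ii] + lam[4] * dCent[, g] / length(ii)
      }
    }
  }

  dZf <- lam[2] * 2 * rctx
  if (two_pass) {
    zero <- matrix(0, nrow(dZt), n)
    if (is.null(dLog2)) dLog2 <- matrix(0, C, n)
    grads <- pf_backward(model, cache, cbind(dLog1, dLog2),
                         dZt = cbind(dZt, zero),
                         dZf = cbind(dZf, matrix(0, d_z, n)))
  } else {
    grads <- pf_backward(model, cache, dLog1, dZt = dZt, dZf = dZf)
  }
  grads$ctx$W_c <- grads$ctx$W_c - lam[2] * 2 * (rctx %*% t(Cc))

  list(breakdown = breakdown, grads = grads, yhat = yhat1)
}

clip_gradients <- function(grads, max_norm) {
  nrm <- param_global_norm(grads)
  if (is.finite(max_norm) && nrm > max_norm) {
    grads <- param_map(function(a) a * (max_norm / nrm), grads)
  }
  grads
}

adamw_init <- function(params) {
  list(m = param_zeros_like(params), v = param_zeros_like(params), t = 0)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- param_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- param_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  params <- param_map(function(p, m, v) {
    p - lr * ((m / c1) / (sqrt(v / c2) + eps) + weight_decay * p)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

lr_at <- function(step, total_steps, cfg) {
  warm <- max(1, ceiling(cfg$warmup_frac * total_steps))
  if (step <= warm) return(cfg$learning_rate * step / warm)
  if (cfg$schedule == "constant") return(cfg$learning_rate)
  cfg$learning_rate * max(0, (total_steps - step) / max(1, total_steps - warm))
}

derive_stream_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(2^31 - 10, 4)
  list(init = s[1], split = s[2], order = s[3], noise = s[4])
}

#' Train the pathway-fusion classifier
#'
#' Minimizes the weighted composite objective by mini-batch gradient
#' descent (decoupled-weight-decay adaptive optimizer, linear warm-up and
#' decay, gradient clipping), with a stratified train/val/test split,
#' per-epoch loss and validation logging, and early stopping on
#' validation accuracy. One latent noise draw is taken per sample per
#' step; evaluation is deterministic. Fully reproducible from
#' `tc$seed`.
#'
#' @param cohort a labeled, normalized [multiomic_cohort()].
#' @param prior a [graph_prior()] on its features.
#' @param pathways a [pathway_collection()] on its features.
#' @param config a [model_config()].
#' @param tc a [train_config()].
#' @param verbose print per-epoch progress.
#' @return object of class `pf_fit` with elements `model` (best
#'   validation parameters), `history` (per-epoch tibble), `split`,
#'   `best_epoch`, `config`, `train_config`.
#' @export
pf_train <- function(cohort, prior, pathways, config = model_config(),
                     tc = train_config(), verbose = FALSE) {
  seeds <- derive_stream_seeds(tc$seed)
  split <- stratified_split(cohort$y, tc$split, seed = seeds$split)
  model <- pf_model(cohort, prior, pathways, config, seed = seeds$init)
  state <- adamw_init(model$params)

  tr <- split$train
  n_tr <- length(tr)
  steps_per_epoch <- max(1, ceiling(n_tr / tc$batch_size))
  total_steps <- tc$max_epochs * steps_per_epoch

  Xall <- cohort$x * cohort$mask
  hist <- vector("list", tc$max_epochs)
  best_acc <- -Inf; best_sel_ce <- Inf; min_ce <- Inf
  best_epoch <- 0L; last_improve <- 0L; best_params <- model$params
  step <- 0L
  for (epoch in seq_len(tc$max_epochs)) {
    set.seed(seeds$order + epoch)
    ord <- sample(tr)
    ep <- c(pred = 0, weak = 0, context = 0, intra = 0, inter = 0,
            entropy = 0, consist = 0, total = 0)
    for (b in seq_len(steps_per_epoch)) {
      idx <- ord[((b - 1) * tc$batch_size + 1):min(b * tc$batch_size, n_tr)]
      step <- step + 1L
      set.seed(seeds$noise + step)
      eps <- matrix(rnorm(model$dims$d_z * length(idx)),
                    model$dims$d_z, length(idx))
      drop_keep <- NULL
      if (tc$weights$lambda[6] > 0) {
        drop_keep <- matrix(runif(length(idx) * model$dims$d) >= tc$weights$p,
                            length(idx), model$dims$d) * 1
      }
      st <- loss_step(model, Xall[idx, , drop = FALSE],
                      cohort$mask[idx, , drop = FALSE],
                      cohort$y[idx],
                      if (is.null(cohort$pseudo)) NULL
                      else cohort$pseudo[idx, , drop = FALSE],
                      cohort$group[idx], tc$weights,
                      entropy_on = tc$entropy_on,
                      eps = eps, drop_keep = drop_keep)
      grads <- clip_gradients(st$grads, tc$clip_norm)
      upd <- adamw_step(model$params, grads, state,
                        lr = lr_at(step, total_steps, tc),
                        weight_decay = tc$weight_decay)
      model$params <- upd$params; state <- upd$state
      ep <- ep + unlist(st$breakdown[1, ])
    }
    val_pred <- pf_predict(model, cohort, split$val)
    vy <- cohort$y[split$val]
    val_acc <- mean(max.col(val_pred, ties.method = "first") == vy)
    val_ce <- -mean(log(pmax(val_pred[cbind(seq_along(vy), vy)], 1e-12)))
    hist[[epoch]] <- tibble(epoch = epoch, !!!as.list(ep),
                            val_accuracy = val_acc, val_ce = val_ce)
    if (verbose)
      message(sprintf("epoch %3d  loss %.3f  val acc %.3f  val ce %.3f",
                      epoch, ep[["total"]], val_acc, val_ce))
    # accuracy is a step function of the predictions and can stall or dip
    # while the model is still clearly learning; the patience window
    # therefore resets on a new accuracy high OR a new cross-entropy low,
    # while the returned parameters always come from the best-accuracy
    # epoch (ties broken by lower validation cross-entropy)
    acc_high <- val_acc > best_acc
    ce_low <- val_ce < min_ce
    if (acc_high || (val_acc == best_acc && val_ce < best_sel_ce)) {
      best_acc <- val_acc; best_sel_ce <- val_ce
      best_epoch <- epoch; best_params <- model$params
    }
    if (acc_high || ce_low) last_improve <- epoch
    min_ce <- min(min_ce, val_ce)
    if (epoch - last_improve >= tc$patience) break
  }
  model$params <- best_params
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 split = split, best_epoch = best_epoch,
                 best_val_accuracy = best_acc,
                 config = config, train_config = tc,
                 sample_ids = cohort$sample_ids),
            class = "pf_fit")
}

#' @export
print.pf_fit <- function(x, ...) {
  cat(sprintf("<pf_fit> %d epochs (best %d, val acc %.3f), %d/%d/%d split\n",
              max(x$history$epoch), x$best_epoch, x$best_val_accuracy,
              length(x$split$train), length(x$split$val), length(x$split$test)))
  invisible(x)
}

#' Deterministic class probabilities
#'
#' Forward pass in evaluation mode (`z_tilde = mu`), so predictions are
#' reproducible bit-identically for fixed parameters.
#'
#' @param object a [pf_model()] or [pf_fit()].
#' @param cohort the cohort to score.
#' @param indices optional sample indices (default all).
#' @param ... unused.
#' @return n x C matrix of probabilities, rows named by sample id.
#' @export
pf_predict <- function(object, cohort, indices = NULL, ...) {
  model <- if (inherits(object, "pf_fit")) object$model else object
  if (is.null(indices)) indices <- seq_along(cohort$sample_ids)
  cache <- pf_forward(model,
                      (cohort$x * cohort$mask)[indices, , drop = FALSE],
                      cohort$mask[indices, , drop = FALSE],
                      deterministic = TRUE)
  pr <- t(cache$yhat)
  dimnames(pr) <- list(cohort$sample_ids[indices], model$class_names)
  pr
}
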