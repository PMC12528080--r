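# small but real end-to-end fits used by several tests
small_fit <- function(seed = 1, n = 60, max_epochs = 4, ...) {
  sim <- tiny_sim(n = n, seed = 5)
  co <- zscore_by_modality(sim$cohort)
  tc <- train_config(seed = seed, max_epochs = max_epochs, batch_size = 16, ...)
  list(fit = pf_train(co, sim$prior, sim$pathways,
                      model_config(d_h = 6, d_z = 4), tc),
       cohort = co, sim = sim)
}

test_that("stratified splits keep every class in every partition", {
  y <- rep(1:3, times = c(40, 30, 20))
  sp <- stratified_split(y, seed = 2)
  for (part in sp) expect_setequal(unique(y[part]), 1:3)
  expect_equal(sort(unname(unlist(sp))), seq_along(y))
  expect_equal(length(sp$train) / length(y), 0.7, tolerance = 0.05)
  expect_error(stratified_split(c(1, rep(2, 50)),
                                c(train = 0.2, val = 0.4, test = 0.4), 1),
               "absent from the training split")
})

test_that("the supervised loss decreases on successive steps of a separable toy", {
  sim <- tiny_sim(n = 30, seed = 6, rho = 0, rho_mod = 0)
  co <- zscore_by_modality(sim$cohort)
  tc <- train_config(seed = 3, max_epochs = 3, batch_size = 30,
                     weights = loss_weights(lambda = rep(0, 6)),
                     split = c(train = 0.8, val = 0.1, test = 0.1))
  fit <- pf_train(co, sim$prior, sim$pathways, model_config(d_h = 6, d_z = 4), tc)
  expect_equal(fit$history$total, fit$history$pred)
  expect_lt(fit$history$pred[3], fit$history$pred[1])
})

test_that("training is reproducible from its seed", {
  a <- small_fit(seed = 11)
  b <- small_fit(seed = 11)
  expect_identical(a$fit$history, b$fit$history)
  expect_identical(a$fit$model$params, b$fit$model$params)
  c_ <- small_fit(seed = 12)
  expect_false(identical(a$fit$history$total, c_$fit$history$total))
})

test_that("early stopping halts within patience epochs of the last improvement", {
  res <- small_fit(seed = 4, max_epochs = 30, patience = 3)
  h <- res$fit$history
  acc_high <- h$val_accuracy > dplyr::lag(cummax(h$val_accuracy), default = -Inf)
  ce_low <- h$val_ce < dplyr::lag(cummin(h$val_ce), default = Inf)
  last_improve <- max(h$epoch[acc_high | ce_low])
  expect_lte(max(h$epoch), last_improve + 3)
  expect_equal(res$fit$best_val_accuracy, max(h$val_accuracy))
  expect_gte(res$fit$best_epoch, which.max(h$val_accuracy))
})

test_that("clipped gradients never exceed the configured global norm", {
  st <- tiny_setup(n = 12)
  co <- st$cohort
  X <- co$x * co$mask
  set.seed(51)
  eps <- matrix(rnorm(st$config$d_z * nrow(X)), st$config$d_z, nrow(X))
  stp <- pathfusion:::loss_step(st$model, X, co$mask, co$y, co$pseudo,
                                co$group, loss_weights(), eps = eps,
                                drop_keep = (matrix(runif(length(X)),
                                                    nrow(X)) >= 0.2) * 1)
  expect_gt(pathfusion:::param_global_norm(stp$grads), 1)  # clipping is active
  clipped <- pathfusion:::clip_gradients(stp$grads, 1.0)
  expect_lte(pathfusion:::param_global_norm(clipped), 1 + 1e-6)
  # direction preserved
  expect_equal(unlist(clipped) / max(abs(unlist(clipped))),
               unlist(stp$grads) / max(abs(unlist(stp$grads))),
               tolerance = 1e-9)
})

test_that("the learning-rate schedule warms up linearly then decays to zero", {
  tc <- train_config(learning_rate = 1e-3, warmup_frac = 0.1)
  total <- 100
  lrs <- vapply(1:total, pathfusion:::lr_at, numeric(1),
                total_steps = total, cfg = tc)
  expect_equal(lrs[10], 1e-3)                 # end of warm-up
  expect_equal(lrs[5], 5e-4)
  expect_lt(lrs[99], 2e-5)
  expect_true(all(diff(lrs[10:100]) <= 0))
})

test_that("checkpoints round-trip predictions bit-identically", {
  res <- small_fit(seed = 7)
  path <- withr::local_tempfile(fileext = ".rds")
  pf_save(res$fit, path)
  back <- pf_load(path)
  expect_identical(pf_predict(back, res$cohort), pf_predict(res$fit, res$cohort))
  expect_error(pf_load(withr::local_tempfile(fileext = ".rds")), "not found")
})

test_that("evaluation metrics behave at the reference points", {
  n <- 40
  y <- rep(1:2, each = n / 2)
  perfect <- cbind(as.numeric(y == 1), as.numeric(y == 2))
  expect_equal(auc_rank(y == 1, perfect[, 1]), 1)
  expect_equal(auc_rank(y == 1, rep(0.5, n)), 0.5)       # constant predictor
  set.seed(52)
  scores <- runif(1e4)
  truth <- sample(c(TRUE, FALSE), 1e4, replace = TRUE)
  expect_lt(abs(auc_rank(truth, scores) - 0.5), 0.02)
  if (requireNamespace("pROC", quietly = TRUE)) {
    a_ref <- as.numeric(pROC::auc(pROC::roc(truth[1:500], scores[1:500],
                                            quiet = TRUE,
                                            direction = "<", levels = c(FALSE, TRUE))))
    expect_equal(auc_rank(truth[1:500], scores[1:500]), a_ref, tolerance = 1e-12)
  }
})

test_that("pf_evaluate reports exact metrics for a trained fit", {
  res <- small_fit(seed = 8)
  ev <- pf_evaluate(res$fit, res$cohort)
  expect_true(all(unlist(ev[, 1:4]) >= 0 & unlist(ev[, 1:4]) <= 1, na.rm = TRUE))
  expect_equal(ev$n, length(res$fit$split$test))
  # single-class subset: AUC undefined, reported as NA
  idx1 <- which(res$cohort$y == 1)[1:4]
  ev1 <- pf_evaluate(res$fit, res$cohort, indices = idx1)
  expect_true(is.na(ev1$macro_auc))
  multi <- pf_evaluate_seeds(list(res$fit, res$fit), res$cohort)
  expect_equal(nrow(multi$per_seed), 2)
  expect_equal(multi$summary$sd[multi$summary$metric == "accuracy"], 0)
})

test_that("tidiers and plots expose the fit in broom/ggplot idiom", {
  res <- small_fit(seed = 9)
  td <- tidy(res$fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$component),
                  c("pred", "weak", "context", "intra", "inter", "entropy",
                    "consist", "total"))
  gl <- glance(res$fit)
  expect_equal(nrow(gl), 1)
  expect_s3_class(autoplot(res$fit), "ggplot")
  att <- pf_attribute(res$fit, res$cohort)
  expect_s3_class(autoplot(att), "ggplot")
  expect_s3_class(tidy(att), "tbl_df")
  expect_s3_class(as_tibble(res$cohort), "tbl_df")
})
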