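test_that("batch forward reproduces the per-sample operation chain", {
  st <- tiny_setup(n = 10, rho = 0.3, rho_mod = 0.3)
  m <- st$model; co <- st$cohort
  cache <- pf_forward(m, co$x * co$mask, co$mask, deterministic = TRUE)
  p <- m$params
  d_h <- m$dims$d_h
  mod_names <- names(m$blocks)
  for (i in c(1, 4, 7)) {
    smp <- cohort_sample(co, i)
    pres <- modality_presence(smp$mask, m$blocks)
    expect_equal(unname(pres), unname(cache$pres[, i]))
    h <- lapply(seq_along(m$blocks), function(mm)
      encode_modality(smp$x_tilde[m$blocks[[mm]]],
                      list(W = p$enc[[mm]]$W, b = p$enc[[mm]]$b,
                           activation = "tanh")))
    for (mm in seq_along(h))
      expect_equal(h[[mm]], unname(cache$H[[mm]][, i]), tolerance = 1e-12)
    att <- cross_modal_attention(h, pres, p$Tmn, d_h)
    fused <- lapply(seq_along(h), function(mm)
      gated_residual_fuse(h[[mm]], att$a[[mm]],
                          list(W = p$gate[[mm]]$W, b = p$gate[[mm]]$b)))
    for (mm in seq_along(h))
      expect_equal(fused[[mm]], unname(cache$Hp[[mm]][, i]), tolerance = 1e-12)
    H0 <- build_node_matrix(smp$x_tilde, m$blocks, fused, p$node$W)
    H0cache <- as3d(cache$Hs[[1]], m$dims$d, 10, d_h)
    expect_equal(unname(H0), unname(H0cache[, i, ]), tolerance = 1e-12)
    Hl <- H0
    for (l in seq_len(m$dims$L))
      Hl <- gcn_layer(Hl, m$prior$A_hat, p$gcn[[l]], "elu")
    HLcache <- as3d(cache$HL, m$dims$d, 10, d_h)
    expect_equal(unname(Hl), unname(HLcache[, i, ]), tolerance = 1e-10)
    pooled <- lapply(m$pathways$pathways, function(mem) pathway_pool(Hl, mem))
    z <- assemble_latent(pooled)
    expect_equal(z, unname(cache$Z[, i]), tolerance = 1e-10)
    zf <- fuse_projection(z, c(p$fuse, activation = "elu"))
    expect_equal(zf, unname(cache$Zf[, i]), tolerance = 1e-10)
    enc <- encode_gaussian(zf, p$head)
    expect_equal(enc$mu, unname(cache$mu[, i]), tolerance = 1e-10)
    yhat <- plp_predict(enc$mu, p$clf)       # deterministic: z_tilde = mu
    expect_equal(yhat, unname(cache$yhat[, i]), tolerance = 1e-10)
  }
})

test_that("composite-loss gradients match central finite differences", {
  st <- tiny_setup(n = 16, rho = 0.2, rho_mod = 0.1)
  m <- st$model; co <- st$cohort
  X <- co$x * co$mask
  w <- loss_weights()
  set.seed(41)
  eps <- matrix(rnorm(m$dims$d_z * nrow(X)), m$dims$d_z, nrow(X))
  keep <- matrix(runif(length(X)) >= w$p, nrow(X), ncol(X)) * 1
  stp <- pathfusion:::loss_step(m, X, co$mask, co$y, co$pseudo, co$group, w,
                                eps = eps, drop_keep = keep)
  flat <- unlist(m$params)
  gflat <- unlist(stp$grads)
  idx <- sort(sample(length(flat), 60))
  lossfun <- function(v) {
    m2 <- m
    m2$params <- utils::relist(v, skeleton = unclass(m$params))
    pathfusion:::loss_step(m2, X, co$mask, co$y, co$pseudo, co$group, w,
                           eps = eps, drop_keep = keep)$breakdown$total
  }
  num <- vapply(idx, function(i) {
    vp <- flat; vp[i] <- vp[i] + 1e-5
    vm <- flat; vm[i] <- vm[i] - 1e-5
    (lossfun(vp) - lossfun(vm)) / 2e-5
  }, numeric(1))
  expect_lt(max(abs(num - gflat[idx]) / pmax(1, abs(num))), 1e-4)
})

test_that("values at masked positions never influence any output", {
  st <- tiny_setup(n = 8, rho = 0.4, rho_mod = 0.2)
  m <- st$model; co <- st$cohort
  X1 <- co$x
  set.seed(42)
  X2 <- X1 + (1 - co$mask) * matrix(rnorm(length(X1), sd = 50), nrow(X1))
  c1 <- pf_forward(m, X1, co$mask, deterministic = TRUE)
  c2 <- pf_forward(m, X2, co$mask, deterministic = TRUE)
  expect_identical(c1$yhat, c2$yhat)
  expect_identical(c1$Z, c2$Z)
  a1 <- pf_attribute(m, co)
  co2 <- co; co2$x <- X2 * co$mask            # container requires stored zeros
  a2 <- pf_attribute(m, co2)
  expect_identical(a1$S, a2$S)
})

test_that("forward passes are deterministic given parameters and noise", {
  st <- tiny_setup(n = 6)
  m <- st$model; co <- st$cohort
  X <- co$x * co$mask
  eps <- matrix(0.5, m$dims$d_z, nrow(X))
  c1 <- pf_forward(m, X, co$mask, eps = eps)
  c2 <- pf_forward(m, X, co$mask, eps = eps)
  expect_identical(c1$yhat, c2$yhat)
  expect_identical(c1$zt, c1$mu + c1$sig * eps)
})

test_that("input diffusion pre-smoothing is wired through the kernel", {
  st <- tiny_setup(n = 5)
  cfgd <- model_config(d_h = st$config$d_h, d_z = st$config$d_z,
                       diffuse_input = TRUE, beta = 0.5)
  prior <- graph_prior(st$sim$prior$edges, length(st$cohort$feature_ids),
                       beta = 0.5)
  md <- pf_model(st$cohort, prior, st$sim$pathways, cfgd, seed = 3)
  co <- st$cohort
  cache <- pf_forward(md, co$x * co$mask, co$mask, deterministic = TRUE)
  Xs <- (co$x * co$mask) %*% prior_kernel(prior)
  expect_equal(cache$Xt, t(Xs), tolerance = 1e-12)
})
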