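rand_prob_rows <- function(n, C) {
  m <- matrix(rexp(n * C), n, C)
  m / rowSums(m)
}

test_that("cross-entropy vanishes on perfect predictions and sums per sample", {
  perfect <- diag(3)[c(1, 2, 3), ]
  expect_equal(loss_pred(perfect, 1:3), 0)
  expect_equal(loss_pred(matrix(0.25, 1, 4), 2), log(4))
  expect_equal(loss_pred(matrix(0.5, 2, 2), c(1, 2)), 2 * log(2))
  expect_warning(v <- loss_pred(matrix(0.5, 2, 2), c(NA, NA)), "no labeled")
  expect_equal(v, 0)
})

test_that("pseudo-label KL is zero at equality and nonnegative", {
  p <- rand_prob_rows(5, 3)
  expect_equal(loss_weak(p, p), 0)
  expect_equal(loss_weak(matrix(c(1, 0), 1, 2), matrix(0.5, 1, 2)), log(2))
  set.seed(31)
  for (i in 1:100) {
    a <- rand_prob_rows(100, 4); b <- rand_prob_rows(100, 4)
    expect_gte(loss_weak(a, b), 0)
  }
  expect_error(loss_weak(matrix(c(2, 0), 1, 2), matrix(0.5, 1, 2)),
               "probability")
})

test_that("entropy lies in [0, log C] with endpoints attained", {
  expect_equal(loss_entropy(matrix(c(1, 0, 0), 1, 3)), 0)
  expect_equal(loss_entropy(matrix(1 / 2, 1, 2)), log(2))
  expect_equal(round(loss_entropy(matrix(c(0.9, 0.1), 1, 2)), 5), 0.32508)
  set.seed(32)
  for (i in 1:50) {
    C <- sample(2:5, 1)
    h <- loss_entropy(rand_prob_rows(1, C))
    expect_gte(h, 0); expect_lte(h, log(C) + 1e-12)
  }
})

test_that("context projection aggregates masked evidence into pathways", {
  Cm <- rbind(c(1, 1, 0), c(0, 1, 1))
  expect_equal(context_projection(c(1, 2, 3), Cm), c(3, 5))
  expect_equal(context_projection(c(0, 0, 0), Cm), c(0, 0))
  expect_equal(context_projection(c(1, 2, 3), matrix(1, 1, 3)), 6)
  expect_error(context_projection(1:4, Cm), "mismatch")
})

test_that("context alignment is a quadratic residual penalty", {
  z <- matrix(c(1, 0), 2, 1); cc <- matrix(0, 3, 1)
  Wc <- matrix(0, 2, 3)
  expect_equal(loss_context(z, cc, Wc), 1)
  zc <- matrix(c(1, 2), 2, 1); cc1 <- matrix(1, 3, 1)
  Wfit <- cbind(c(1, 2), c(0, 0), c(0, 0))
  expect_equal(loss_context(zc, cc1, Wfit), 0)
  expect_equal(loss_context(2 * z, cc, Wc), 4 * loss_context(z, cc, Wc))
})

test_that("feature dropout keeps each entry with probability 1 - p", {
  x <- rnorm(10)
  expect_identical(feature_dropout(x, 0), x)
  expect_identical(feature_dropout(x, 1), x * 0)
  set.seed(33)
  big <- rep(1, 1e5)
  kept <- mean(feature_dropout(big, 0.3))
  expect_lt(abs(kept - 0.7), 0.01)
  expect_error(feature_dropout(x, 1.5), "p must")
})

test_that("consistency loss is a symmetric squared distance", {
  a <- matrix(c(1, 0), 1, 2); b <- matrix(c(0, 1), 1, 2)
  expect_equal(loss_consist(a, a), 0)
  expect_equal(loss_consist(a, b), 2)
  expect_equal(loss_consist(a, b), loss_consist(b, a))
})

test_that("group centroids and intra-group compactness match brute force", {
  z <- cbind(c(1, 1), c(3, 3), c(10, 0))
  g <- c("a", "a", "b")
  cent <- group_centroids(z, g)
  expect_equal(cent[, "a"], c(2, 2))
  expect_equal(cent[, "b"], c(10, 0))                    # singleton
  expect_equal(loss_intra(z, g), 4)                      # 2 + 2 + 0
  set.seed(34)
  zz <- matrix(rnorm(3 * 20), 3)
  gg <- sample(letters[1:4], 20, replace = TRUE)
  brute <- 0
  for (u in unique(gg)) {
    idx <- which(gg == u)
    cb <- rowMeans(zz[, idx, drop = FALSE])
    for (i in idx) brute <- brute + sum((zz[, i] - cb)^2)
    # scatter identity: sum of squared deviations = (|g|-1) * trace(cov)
    if (length(idx) > 1)
      expect_equal(sum((zz[, idx] - cb)^2),
                   (length(idx) - 1) * sum(diag(cov(t(zz[, idx, drop = FALSE])))),
                   tolerance = 1e-9)
  }
  expect_equal(loss_intra(zz, gg), brute, tolerance = 1e-9)
})

test_that("inter-group hinge penalizes cosine above the margin", {
  orth <- cbind(c(1, 0), c(0, 1))
  colnames(orth) <- c("a", "b")
  expect_equal(loss_inter(orth, 0), 0)
  same <- cbind(c(1, 0), c(1, 0)); colnames(same) <- c("a", "b")
  expect_equal(loss_inter(same, 0.3), 0.7)
  expect_equal(loss_inter(same, 1), 0)
  expect_warning(v <- loss_inter(cbind(a = c(0, 0), b = c(1, 0)), 0),
                 "zero-norm")
  expect_equal(v, 0)
  # pair count: all-identical unit centroids give G(G-1)/2 hinges of 1 - delta
  G <- 5
  cm <- matrix(1, 2, G, dimnames = list(NULL, letters[1:G])) / sqrt(2)
  expect_equal(loss_inter(cm, 0), G * (G - 1) / 2)
})

test_that("the composite total is the printed weighted sum, affine in each weight", {
  comp <- list(pred = 1, weak = 1, context = 1, intra = 1, inter = 1,
               entropy = 1, consist = 1)
  w <- loss_weights(lambda = c(0.5, 0.1, 0.1, 0.1, 0.01, 0.1))
  expect_equal(total_loss(comp, w)$total, 1.91)
  w0 <- loss_weights(lambda = rep(0, 6))
  expect_equal(total_loss(comp, w0)$total, comp$pred)
  comp2 <- list(pred = 1, weak = 2, context = 0, intra = 0, inter = 0,
                entropy = 0, consist = 0)
  expect_equal(total_loss(comp2, loss_weights(c(1, 0, 0, 0, 0, 0)))$total, 3)
  # affine in each lambda with slope equal to the component value
  set.seed(35)
  compr <- as.list(setNames(runif(7, 0.5, 2),
                            c("pred", "weak", "context", "intra", "inter",
                              "entropy", "consist")))
  base <- runif(6)
  for (j in 1:6) {
    lam1 <- base; lam2 <- base; lam2[j] <- lam2[j] + 0.25
    t1 <- total_loss(compr, loss_weights(lam1))$total
    t2 <- total_loss(compr, loss_weights(lam2))$total
    slope <- (t2 - t1) / 0.25
    cname <- c("weak", "context", "intra", "inter", "entropy", "consist")[j]
    expect_equal(slope, compr[[cname]], tolerance = 1e-9)
  }
  expect_error(loss_weights(lambda = c(-1, 0, 0, 0, 0, 0)), "nonnegative")
})

test_that("every loss component is nonnegative on random valid inputs", {
  set.seed(36)
  for (i in 1:200) {
    n <- sample(2:6, 1); C <- sample(2:4, 1); dz <- 3
    pr <- rand_prob_rows(n, C)
    ps <- rand_prob_rows(n, C)
    y <- sample(C, n, replace = TRUE)
    z <- matrix(rnorm(dz * n), dz)
    g <- sample(c("a", "b"), n, replace = TRUE)
    expect_gte(loss_pred(pr, y), 0)
    expect_gte(loss_weak(ps, pr), 0)
    expect_gte(loss_entropy(pr), 0)
    expect_gte(loss_intra(z, g), 0)
    expect_gte(suppressWarnings(loss_inter(group_centroids(z, g),
                                           runif(1, -1, 1))), 0)
    expect_gte(loss_consist(pr, rand_prob_rows(n, C)), 0)
  }
})

test_that("each enabled component alone produces a nonzero parameter gradient", {
  st <- tiny_setup(n = 12)
  co <- st$cohort
  X <- co$x * co$mask
  set.seed(37)
  eps <- matrix(rnorm(st$config$d_z * nrow(X)), st$config$d_z, nrow(X))
  keep <- matrix(runif(length(X)) >= 0.3, nrow(X), ncol(X)) * 1
  run <- function(lam) {
    w <- loss_weights(lambda = lam, p = 0.3)
    pathfusion:::loss_step(st$model, X, co$mask, co$y, co$pseudo,
                           co$group, w, eps = eps, drop_keep = keep)
  }
  base <- run(rep(0, 6))                    # L_pred alone
  expect_gt(pathfusion:::param_global_norm(base$grads), 0)
  for (j in 1:6) {
    lam <- rep(0, 6); lam[j] <- 1
    stj <- run(lam)
    delta <- pathfusion:::param_map(`-`, stj$grads, base$grads)
    expect_gt(pathfusion:::param_global_norm(delta), 0)
  }
})
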