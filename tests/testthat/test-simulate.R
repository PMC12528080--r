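test_that("simulated priors have the configured pathway/graph structure", {
  cfg <- simulation_config(n_pathways = 2, features_per_pathway = 3,
                           n_classes = 2, causal_per_class = 1,
                           overlap_fraction = 0, q_in = 1, q_out = 0, seed = 9)
  pr <- simulate_prior(cfg)
  expect_length(pr$feature_ids, 2 * 3)                   # disjoint union
  expect_equal(nrow(pr$edges), 2 * choose(3, 2))         # complete within
  pr2 <- simulate_prior(cfg)
  expect_identical(pr, pr2)                              # determinism
  cfg_ov <- simulation_config(n_pathways = 4, features_per_pathway = 4,
                              n_classes = 2, causal_per_class = 1,
                              overlap_fraction = 0.5, seed = 9)
  pr_ov <- simulate_prior(cfg_ov)
  expect_length(pr_ov$feature_ids, 4 * 4 - 3 * 2)
  expect_length(intersect(pr_ov$pathways$pathways[[1]],
                          pr_ov$pathways$pathways[[2]]), 2)
  expect_error(simulate_prior(simulation_config(features_per_pathway = 2)),
               "min_size")
})

test_that("cohorts carry the planted class signal and missingness rates", {
  cfg0 <- simulation_config(n_samples = 2000, n_pathways = 6,
                            features_per_pathway = 4, effect_size = 0,
                            rho = 0, rho_mod = 0, seed = 10)
  sim0 <- simulate_cohort(cfg0, simulate_prior(cfg0))
  expect_true(all(sim0$cohort$mask == 1))
  # no effect: per-feature class-mean t statistics stay at chance level
  y <- sim0$cohort$y
  tstats <- apply(sim0$cohort$x, 2, function(v)
    t.test(v[y == 1], v[y != 1])$statistic)
  expect_lt(mean(abs(tstats) > qt(0.999, df = 100)), 0.05)

  cfgm <- simulation_config(n_samples = 100, n_pathways = 25,
                            features_per_pathway = 10, n_classes = 5,
                            causal_per_class = 2,
                            rho = 0.3, rho_mod = 0, seed = 11)
  simm <- simulate_cohort(cfgm, simulate_prior(cfgm))
  d <- length(simm$cohort$feature_ids)
  expect_gte(d, 250)
  expect_lt(abs(mean(simm$cohort$mask) - 0.7), 0.015)
  expect_identical(simm$cohort$x, simm$cohort$x * simm$cohort$mask)
})

test_that("modality knockout blanks whole blocks", {
  cfg <- simulation_config(n_samples = 400, rho = 0, rho_mod = 0.2, seed = 12)
  sim <- simulate_cohort(cfg, simulate_prior(cfg))
  co <- sim$cohort
  frac_absent <- mean(vapply(seq_along(co$sample_ids), function(i) {
    mean(!modality_presence(co$mask[i, ], co$blocks))
  }, numeric(1)))
  expect_lt(abs(frac_absent - 0.2), 0.05)
  # blocks are blanked atomically: a knocked-out block has an all-zero mask
  for (i in 1:50) {
    for (b in co$blocks) {
      s <- sum(co$mask[i, b])
      expect_true(s == 0 || s == length(b))
    }
  }
})

test_that("pseudo-labels are tempered softmax seeds with uniform corruption", {
  set.seed(13)
  pl <- simulate_pseudo_labels(c(1, 2), 2, tau = 1, eta = 0)
  expect_equal(pl[1, ], c(0.73106, 0.26894), tolerance = 1e-5)
  expect_equal(rowSums(pl), c(1, 1))
  pl_cold <- simulate_pseudo_labels(rep(1, 5), 3, tau = 0.01, eta = 0)
  expect_true(all(pl_cold[, 1] > 0.999))                 # temperature limit
  set.seed(14)
  y <- sample(2, 1e4, replace = TRUE)
  pl_flip <- simulate_pseudo_labels(y, 2, tau = 0.5, eta = 1)
  match_rate <- mean((pl_flip[, 1] > 0.5) == (y == 1))
  expect_lt(abs(match_rate - 0.5), 0.02)                 # uniform reseeding
  expect_error(simulate_pseudo_labels(1, 2, tau = 0), "tau")
})

test_that("planted signal is recoverable by per-feature t-tests", {
  cfg <- simulation_config(seed = 15)                    # n=600, delta=2, 20% MCAR
  sim <- simulate_cohort(cfg, pr <- simulate_prior(cfg))
  co <- sim$cohort
  feats_of_class <- lapply(co$class_names, function(cl)
    unique(unlist(pr$pathways$pathways[match(sim$truth$causal_pathways[[cl]],
                                             pr$pathways$names)])))
  flagged <- logical(0)
  for (c_ in seq_along(co$class_names)) {
    for (j in feats_of_class[[c_]]) {
      obs <- co$mask[, j] == 1
      v <- co$x[obs, j]; grp <- co$y[obs] == c_
      flagged <- c(flagged, t.test(v[grp], v[!grp])$p.value < 0.001)
    }
  }
  expect_gt(mean(flagged), 0.9)
})

test_that("simulation output files are byte-identical under a fixed seed", {
  cfg <- simulation_config(n_samples = 30, n_pathways = 6,
                           features_per_pathway = 4, seed = 16)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_multiomic(cfg), d1)
  write_simulation(simulate_multiomic(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("label permutation regenerates the weak-supervision channel", {
  cfg <- simulation_config(n_samples = 40, n_pathways = 6,
                           features_per_pathway = 4, eta = 0, tau = 0.5,
                           seed = 17)
  sim <- simulate_multiomic(cfg)
  perm <- permute_labels(sim$cohort, cfg, seed = 1)
  expect_setequal(perm$y, sim$cohort$y)
  expect_false(identical(perm$y, sim$cohort$y))
  # pseudo-labels follow the permuted classes, not the original ones
  agree <- mean(max.col(perm$pseudo) == perm$y)
  expect_equal(agree, 1)                                 # eta = 0
})

test_that("graph-correlated noise mode draws smoother cohorts deterministically", {
  cfg <- simulation_config(n_samples = 200, n_pathways = 4,
                           features_per_pathway = 5, n_classes = 2,
                           causal_per_class = 1, q_in = 1, q_out = 0,
                           effect_size = 0, rho = 0, rho_mod = 0,
                           noise_mode = "graph", seed = 18)
  pr <- simulate_prior(cfg)
  s1 <- simulate_cohort(cfg, pr)
  s2 <- simulate_cohort(cfg, pr)
  expect_identical(s1$cohort$x, s2$cohort$x)
  # within-pathway features (connected) correlate more than cross-pathway
  x <- s1$cohort$x
  within <- cor(x[, pr$pathways$pathways[[1]][1]],
                x[, pr$pathways$pathways[[1]][2]])
  across <- cor(x[, pr$pathways$pathways[[1]][1]],
                x[, pr$pathways$pathways[[2]][1]])
  expect_gt(within, across + 0.1)
})
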