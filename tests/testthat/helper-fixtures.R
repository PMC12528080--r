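# Shared fixtures: tiny simulated studies, tiny models, and numeric
# differentiation / series oracles used across test files.

tiny_sim <- function(n = 24, C = 3, M = 3, P = 6, s = 4, seed = 7, ...) {
  simulate_multiomic(simulation_config(
    n_samples = n, n_classes = C, n_modalities = M, n_pathways = P,
    features_per_pathway = s, seed = seed, ...))
}

tiny_setup <- function(n = 24, d_h = 5, d_z = 4, seed = 7, model_seed = 3, ...) {
  sim <- tiny_sim(n = n, seed = seed, ...)
  cohort <- zscore_by_modality(sim$cohort)
  cfg <- model_config(d_h = d_h, d_z = d_z, gcn_layers = 2)
  model <- pf_model(cohort, sim$prior, sim$pathways, cfg, seed = model_seed)
  list(sim = sim, cohort = cohort, config = cfg, model = model)
}

# central finite differences of scalar f at x
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# truncated Taylor series of the matrix exponential exp(-beta * L)
expm_taylor <- function(L, beta, terms = 40) {
  d <- nrow(L)
  acc <- diag(d); term <- diag(d)
  for (k in seq_len(terms)) {
    term <- term %*% (-beta * L) / k
    acc <- acc + term
  }
  acc
}

# random undirected edge set over d nodes (index matrix)
random_edges <- function(d, p = 0.4) {
  pairs <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  pairs[keep, , drop = FALSE]
}

# perturb one parameter tensor entry and return the rebuilt model
with_param <- function(model, path, idx, value) {
  model$params[[path[1]]][[path[2]]][idx] <- value
  model
}

expect_prob_cols <- function(m, tol = 1e-9) {
  expect_true(all(m > 0))
  expect_true(all(abs(colSums(m) - 1) < tol))
}

# node-state matrices are d x (n*d_h); view as the (d, n, d_h) array
as3d <- function(m, d, n, d_h) array(m, c(d, n, d_h))
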