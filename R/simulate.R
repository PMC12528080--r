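#' Synthetic-cohort simulation settings
#'
#' Defines the generative conditions for a multi-omic cohort with
#' planted class-specific pathway activations: pathway/graph structure,
#' class effect size, noise, MCAR and modality-level missingness,
#' subgroup strata and temperature-noised soft pseudo-labels. Every
#' draw is reproducible from `seed`.
#'
#' @param n_samples cohort size.
#' @param n_classes number of classes C (balanced).
#' @param n_modalities number of omic modalities M (features assigned
#'   round-robin).
#' @param n_pathways number of pathways P.
#' @param features_per_pathway pathway size s.
#' @param overlap_fraction fraction of each pathway's features shared
#'   with the previous pathway (0 = disjoint).
#' @param q_in within-pathway edge probability.
#' @param q_out cross-pathway edge probability.
#' @param effect_size class effect delta, in noise-SD units, added to
#'   the features of a class's causal pathways.
#' @param noise_sd additive Gaussian noise SD.
#' @param rho element-wise MCAR missingness rate.
#' @param rho_mod whole-modality knockout rate per sample.
#' @param groups_per_class subgroup strata nested within each class.
#' @param causal_per_class causal pathways planted per class (disjoint
#'   across classes).
#' @param tau pseudo-label softmax temperature.
#' @param eta pseudo-label corruption rate: with probability `eta` the
#'   seed class is replaced by a uniform draw over all C classes.
#' @param noise_mode `"independent"` Gaussian noise, or `"graph"` for
#'   noise with covariance proportional to the diffusion kernel of the
#'   simulated graph.
#' @param seed master seed, recorded in every output.
#' @return list of class `pf_sim_config`.
#' @export
simulation_config <- function(n_samples = 600, n_classes = 3,
                              n_modalities = 3, n_pathways = 12,
                              features_per_pathway = 10,
                              overlap_fraction = 0,
                              q_in = 0.3, q_out = 0.01,
                              effect_size = 2, noise_sd = 1,
                              rho = 0.2, rho_mod = 0.05,
                              groups_per_class = 2, causal_per_class = 2,
                              tau = 0.5, eta = 0.1,
                              noise_mode = c("independent", "graph"),
                              seed = 1) {
  probs <- c(overlap_fraction, q_in, q_out, rho, rho_mod, eta)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (effect_size < 0) abort("effect_size must be >= 0")
  if (tau <= 0) abort("tau must be > 0")
  if (causal_per_class * n_classes > n_pathways)
    abort("causal pathways exceed available pathways")
  structure(list(n_samples = n_samples, n_classes = n_classes,
                 n_modalities = n_modalities, n_pathways = n_pathways,
                 features_per_pathway = features_per_pathway,
                 overlap_fraction = overlap_fraction,
                 q_in = q_in, q_out = q_out,
                 effect_size = effect_size, noise_sd = noise_sd,
                 rho = rho, rho_mod = rho_mod,
                 groups_per_class = groups_per_class,
                 causal_per_class = causal_per_class,
                 tau = tau, eta = eta,
                 noise_mode = match.arg(noise_mode), seed = seed),
            class = "pf_sim_config")
}

sim_stream_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(2^31 - 10, 6)
  list(prior = s[1], signal = s[2], noise = s[3], mask = s[4],
       pseudo = s[5], group = s[6])
}

#' Simulate the pathway/graph prior
#'
#' Builds P pathways of s features each (with the configured overlap
#' between consecutive pathways), assigns features round-robin to M
#' modalities, and draws undirected edges Bernoulli(`q_in`) within
#' pathways and Bernoulli(`q_out`) across. Fully reproducible from the
#' config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `feature_ids`, `modality_of`, `pathways`
#'   (a [pathway_collection()]), `edges` (tibble as from
#'   [read_edge_list()]).
#' @export
simulate_prior <- function(config) {
  s <- config$features_per_pathway
  P <- config$n_pathways
  if (s < 3) abort("features_per_pathway must be >= 3 (pathway min_size)")
  n_shared <- floor(config$overlap_fraction * s)
  d <- P * s - (P - 1) * n_shared
  feature_ids <- sprintf("f%04d", seq_len(d))
  members <- vector("list", P)
  start <- 1
  for (k in seq_len(P)) {
    if (k == 1) {
      members[[k]] <- seq(start, start + s - 1)
      start <- start + s
    } else {
      shared <- utils::tail(members[[k - 1]], n_shared)
      fresh <- seq(start, start + (s - n_shared) - 1)
      members[[k]] <- c(shared, fresh)
      start <- start + (s - n_shared)
    }
  }
  names(members) <- sprintf("pw%02d", seq_len(P))
  modality_of <- setNames(paste0("mod", ((seq_len(d) - 1) %% config$n_modalities) + 1),
                          feature_ids)
  seeds <- sim_stream_seeds(config$seed)
  set.seed(seeds$prior)
  same_pw <- matrix(FALSE, d, d)
  for (k in seq_len(P)) same_pw[members[[k]], members[[k]]] <- TRUE
  pairs <- which(upper.tri(same_pw), arr.ind = TRUE)
  p_edge <- ifelse(same_pw[pairs], config$q_in, config$q_out)
  keep <- runif(nrow(pairs)) < p_edge
  edges <- tibble(from = feature_ids[pairs[keep, 1]],
                  to = feature_ids[pairs[keep, 2]],
                  from_idx = pairs[keep, 1], to_idx = pairs[keep, 2])
  pw <- pathway_collection(lapply(members, function(i) feature_ids[i]),
                           feature_ids, min_size = 3)
  list(feature_ids = feature_ids, modality_of = modality_of,
       pathways = pw, edges = edges)
}

#' Simulate a labeled multi-omic cohort over a prior
#'
#' Samples are drawn balanced across classes; a sample of class c has
#' mean `effect_size` on the features of its causal pathways and 0
#' elsewhere, plus Gaussian noise; masks are applied MCAR at rate `rho`
#' plus whole-modality knockout at rate `rho_mod`; subgroup strata are
#' assigned within class; soft pseudo-labels are generated from the true
#' labels by [simulate_pseudo_labels()].
#'
#' @param config a [simulation_config()].
#' @param prior output of [simulate_prior()].
#' @return list with `cohort` (a [multiomic_cohort()]) and `truth`
#'   (causal pathway names per class, per-sample class/group, the applied
#'   mask, and the seed).
#' @export
simulate_cohort <- function(config, prior) {
  seeds <- sim_stream_seeds(config$seed)
  n <- config$n_samples; C <- config$n_classes
  d <- length(prior$feature_ids)
  P <- length(prior$pathways$pathways)

  set.seed(seeds$signal)
  causal_idx <- sample.int(P, C * config$causal_per_class)
  causal <- split(causal_idx, rep(seq_len(C), each = config$causal_per_class))
  names(causal) <- paste0("class", seq_len(C))
  y <- rep(seq_len(C), length.out = n)
  mean_mat <- matrix(0, C, d)
  for (c_ in seq_len(C)) {
    feats <- unique(unlist(prior$pathways$pathways[causal[[c_]]]))
    mean_mat[c_, feats] <- config$effect_size
  }

  set.seed(seeds$noise)
  if (config$noise_mode == "graph") {
    L <- build_laplacian(prior$edges, d)
    K <- diffusion_kernel(L, beta = 1)
    eig <- eigen(K, symmetric = TRUE)
    rt <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
    noise <- matrix(rnorm(n * d), n, d) %*% rt * config$noise_sd
  } else {
    noise <- matrix(rnorm(n * d, sd = config$noise_sd), n, d)
  }
  x <- mean_mat[y, , drop = FALSE] + noise

  set.seed(seeds$mask)
  mask <- matrix(runif(n * d) >= config$rho, n, d) * 1
  blocks <- split(seq_len(d),
                  factor(prior$modality_of[prior$feature_ids],
                         levels = unique(unname(prior$modality_of))))
  knock <- matrix(runif(n * length(blocks)) < config$rho_mod, n, length(blocks))
  for (m in seq_along(blocks)) mask[knock[, m], blocks[[m]]] <- 0
  x[mask == 0] <- 0

  set.seed(seeds$group)
  group <- paste0("class", y, "_g",
                  sample.int(config$groups_per_class, n, replace = TRUE))

  set.seed(seeds$pseudo)
  pseudo <- simulate_pseudo_labels(y, C, config$tau, config$eta)

  dimnames(x) <- dimnames(mask) <- list(sprintf("S%04d", seq_len(n)),
                                        prior$feature_ids)
  cohort <- multiomic_cohort(x, mask, prior$modality_of,
                             class_names = paste0("class", seq_len(C)),
                             y = y, group = group, pseudo = pseudo)
  truth <- list(causal_pathways = lapply(causal, function(i) prior$pathways$names[i]),
                y = y, group = group, mask = mask, seed = config$seed,
                config = unclass(config))
  list(cohort = cohort, truth = truth)
}

#' Temperature-noised soft pseudo-labels
#'
#' With probability `eta` a sample's seed class is replaced by a uniform
#' draw over all C classes; the soft label is the softmax of the seed
#' one-hot vector divided by temperature `tau`. Rows sum to 1.
#'
#' @param labels integer true classes.
#' @param C number of classes.
#' @param tau temperature (> 0).
#' @param eta corruption rate in `[0, 1]`.
#' @return n x C matrix of soft labels.
#' @export
simulate_pseudo_labels <- function(labels, C, tau = 0.5, eta = 0.1) {
  if (tau <= 0) abort("tau must be > 0")
  if (eta < 0 || eta > 1) abort("eta must lie in [0, 1]")
  n <- length(labels)
  seedcls <- labels
  flip <- runif(n) < eta
  seedcls[flip] <- sample.int(C, sum(flip), replace = TRUE)
  soft <- matrix(0, n, C)
  soft[cbind(seq_len(n), seedcls)] <- 1 / tau
  t(softmax_cols(t(soft)))
}

#' Simulate a complete study (prior + cohort + truth)
#'
#' @param config a [simulation_config()].
#' @return list with `cohort`, `prior` (a [graph_prior()]), `pathways`,
#'   `edges`, `truth`.
#' @export
simulate_multiomic <- function(config = simulation_config()) {
  pr <- simulate_prior(config)
  sim <- simulate_cohort(config, pr)
  list(cohort = sim$cohort,
       prior = graph_prior(pr$edges, length(pr$feature_ids)),
       pathways = pr$pathways, edges = pr$edges, truth = sim$truth)
}

#' Write a simulated study as the standard file set
#'
#' Emits `features.tsv`, `modality_map.tsv`, `metadata.tsv`,
#' `pathways.gmt`, `edges.tsv` and `ground_truth.json`, byte-identical
#' for a fixed config.
#'
#' @param sim output of [simulate_multiomic()].
#' @param dir output directory.
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_cohort(sim$cohort, dir)
  gmt <- file.path(dir, "pathways.gmt")
  write_gmt(sim$pathways, gmt)
  ed <- file.path(dir, "edges.tsv")
  write_edge_list(sim$edges, ed)
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sim$truth[c("causal_pathways", "y", "group", "seed",
                                   "config")],
                       gt, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, gmt = gmt, edges = ed, ground_truth = gt))
}

#' Permute labels (negative control)
#'
#' Randomly permutes the class labels and regenerates groups and
#' pseudo-labels from the permuted labels, so no label information leaks
#' into the permuted run through the weak-supervision channel.
#'
#' @param cohort a labeled [multiomic_cohort()].
#' @param config the [simulation_config()] used to build the cohort
#'   (for `tau`, `eta`, `groups_per_class`).
#' @param seed permutation seed.
#' @return the cohort with permuted `y` and regenerated `group`,
#'   `pseudo`.
#' @export
permute_labels <- function(cohort, config, seed = 1) {
  set.seed(seed)
  n <- length(cohort$y)
  y <- sample(cohort$y)
  group <- paste0("class", y, "_g",
                  sample.int(config$groups_per_class, n, replace = TRUE))
  pseudo <- simulate_pseudo_labels(y, length(cohort$class_names),
                                   config$tau, config$eta)
  multiomic_cohort(cohort$x, cohort$mask, cohort$modality_of,
                   sample_ids = cohort$sample_ids,
                   class_names = cohort$class_names,
                   y = y, group = group, pseudo = pseudo)
}
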