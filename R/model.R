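#' Model architecture configuration
#'
#' Hyperparameters of the pathway-guided fusion network. Defaults:
#' shared latent width `d_h = 32`, compact latent `d_z = 16`, two GCN
#' layers with ELU, tanh modality encoders, ELU fused projection,
#' diffusion strength `beta = 1`, gated residual fusion on, optional
#' input diffusion (pre-smoothing of masked features by `exp(-beta L)`)
#' off, implicit low-rank multi-way interaction off (`rank = 0`).
#'
#' @param d_h shared modality/node latent dimension.
#' @param d_z compact latent dimension of the variational head.
#' @param gcn_layers number of graph-convolution layers (`>= 0`).
#' @param gcn_activation activation of the GCN layers.
#' @param enc_activation modality-encoder activation (one name for all
#'   modalities or a named vector per modality).
#' @param fuse_activation activation of the two-layer fused projection
#'   (`"elu"` or `"swish"`).
#' @param beta graph diffusion strength.
#' @param gate use the learned gate in residual fusion (plain residual
#'   `h + a` when `FALSE`).
#' @param diffuse_input pre-smooth masked inputs with the diffusion
#'   kernel before encoding (off by default).
#' @param rank rank of the implicit multi-way interaction diagnostic
#'   (0 = off).
#' @return list of class `pf_model_config`.
#' @export
model_config <- function(d_h = 32, d_z = 16, gcn_layers = 2,
                         gcn_activation = "elu", enc_activation = "tanh",
                         fuse_activation = "elu", beta = 1,
                         gate = TRUE, diffuse_input = FALSE, rank = 0) {
  stopifnot(d_h >= 1, d_z >= 1, gcn_layers >= 0, beta >= 0, rank >= 0)
  fuse_activation <- match.arg(fuse_activation, c("elu", "swish"))
  structure(list(d_h = d_h, d_z = d_z, gcn_layers = gcn_layers,
                 gcn_activation = gcn_activation,
                 enc_activation = enc_activation,
                 fuse_activation = fuse_activation,
                 beta = beta, gate = gate,
                 diffuse_input = diffuse_input, rank = rank),
            class = "pf_model_config")
}

model_dims <- function(cohort, pathways, config) {
  dm <- cohort_dims(cohort)
  list(d = dm$d, M = dm$M, blocks = cohort$blocks,
       block_sizes = dm$block_sizes, P = length(pathways$pathways),
       C = dm$C, d_h = config$d_h, d_z = config$d_z,
       L = config$gcn_layers)
}

glorot <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

enc_activation_of <- function(config, mod_names) {
  acts <- config$enc_activation
  if (length(acts) == 1 && is.null(names(acts)))
    acts <- setNames(rep(acts, length(mod_names)), mod_names)
  acts[mod_names]
}

#' Initialize model parameters
#'
#' Draws all learnable parameters (modality encoders, interaction
#' matrices, gates, per-feature node embeddings, GCN stack, fused
#' projection, Gaussian heads, classifier, context-alignment map) with
#' Glorot-scaled normal weights and zero biases, reproducibly from
#' `seed`.
#'
#' @param dims dimension list from the cohort/pathways (internal) or a
#'   list with `d`, `M`, `block_sizes`, `P`, `C`, `d_h`, `d_z`, `L`.
#' @param config a [model_config()].
#' @param seed integer seed for the initialization RNG stream.
#' @return nested parameter list of class `pf_params`.
#' @export
init_params <- function(dims, config, seed = 1) {
  set.seed(seed)
  M <- dims$M; d_h <- dims$d_h; d_z <- dims$d_z
  mod_names <- names(dims$blocks) %||% paste0("mod", seq_len(M))
  enc <- lapply(seq_len(M), function(m) {
    list(W = glorot(d_h, dims$block_sizes[m]), b = numeric(d_h))
  })
  names(enc) <- mod_names
  Tmn <- lapply(seq_len(M), function(m) {
    lapply(seq_len(M), function(n) if (m == n) NULL else glorot(d_h, d_h))
  })
  gate <- lapply(seq_len(M), function(m) {
    list(W = glorot(d_h, 2 * d_h), b = numeric(d_h))
  })
  gcn <- lapply(seq_len(dims$L), function(l) glorot(d_h, d_h))
  p <- list(
    enc = enc,
    Tmn = Tmn,
    gate = gate,
    node = list(W = matrix(rnorm(dims$d * d_h, sd = 1 / sqrt(d_h)), dims$d, d_h)),
    gcn = gcn,
    fuse = list(W1 = glorot(d_z, dims$P * d_h), b1 = numeric(d_z),
                W2 = glorot(d_z, d_z), b2 = numeric(d_z)),
    # log-variance bias starts at -4 (sigma ~ 0.14): the stochastic
    # latent begins close to its mean and variance is learned upward
    # only where warranted, instead of drowning the early signal
    head = list(W_mu = glorot(d_z, d_z), b_mu = numeric(d_z),
                W_lv = glorot(d_z, d_z), b_lv = rep(-4, d_z)),
    clf = list(W_out = glorot(dims$C, d_z), b_out = numeric(dims$C)),
    ctx = list(W_c = glorot(d_z, dims$P))
  )
  structure(p, class = "pf_params")
}

# recursive map over nested numeric parameter structures
param_map <- function(f, ...) {
  args <- list(...)
  a <- args[[1]]
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) {
      if (is.null(a[[i]])) return(NULL)
      do.call(param_map, c(list(f), lapply(args, `[[`, i)))
    })
    names(out) <- names(a)
    attributes(out) <- attributes(a)
    return(out)
  }
  do.call(f, args)
}

param_zeros_like <- function(p) param_map(function(a) { a[] <- 0; a }, p)

param_unlist <- function(p) unlist(p, use.names = FALSE)

param_global_norm <- function(g) sqrt(sum(param_unlist(g)^2))

#' Assemble a pathway-fusion model
#'
#' Bundles parameters, architecture configuration, the graph prior, the
#' pathway collection and the cohort's feature bookkeeping into a single
#' object the forward pass, trainer, evaluator and attribution all
#' consume.
#'
#' @param cohort a [multiomic_cohort()] defining features/blocks/classes.
#' @param prior a [graph_prior()] over the cohort's features.
#' @param pathways a [pathway_collection()].
#' @param config a [model_config()].
#' @param seed initialization seed.
#' @param params optional pre-built parameters (checkpoint restore).
#' @return object of class `pf_model`.
#' @export
pf_model <- function(cohort, prior, pathways, config = model_config(),
                     seed = 1, params = NULL) {
  if (prior$d != length(cohort$feature_ids))
    abort("graph prior and cohort disagree on d")
  if (!identical(pathways$feature_ids, cohort$feature_ids))
    abort("pathway collection built over a different feature universe")
  dims <- model_dims(cohort, pathways, config)
  if (dims$C < 2) abort("model needs at least two classes")
  if (is.null(params)) params <- init_params(dims, config, seed = seed)
  bmat <- matrix(0, dims$M, dims$d)              # modality indicator rows
  for (m in seq_len(dims$M)) bmat[m, dims$blocks[[m]]] <- 1
  structure(list(params = params, config = config, dims = dims,
                 prior = prior, pathways = pathways,
                 pool = pathway_pool_matrix(pathways),
                 bmat = bmat,
                 feature_ids = cohort$feature_ids,
                 blocks = cohort$blocks,
                 class_names = cohort$class_names,
                 kernel = if (config$diffuse_input) prior_kernel(prior) else NULL),
            class = "pf_model")
}

#' @export
print.pf_model <- function(x, ...) {
  cat(sprintf(paste0("<pf_model> d=%d features, M=%d modalities, P=%d pathways,",
                     " C=%d classes\n  d_h=%d, d_z=%d, %d GCN layer(s), %d parameters\n"),
              x$dims$d, x$dims$M, x$dims$P, x$dims$C,
              x$dims$d_h, x$dims$d_z, x$dims$L,
              length(param_unlist(x$params))))
  invisible(x)
}
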