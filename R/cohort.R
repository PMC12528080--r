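#' Multi-omic cohort container
#'
#' Bundles a sample-by-feature value matrix, its observation mask, the
#' partition of features into modality blocks, and per-sample metadata
#' (class label, subgroup stratum, soft pseudo-label) into a single
#' validated object. Values at unobserved positions are stored as zero,
#' so `x` is already the masked vector \eqn{\tilde{x} = m \odot x} used by
#' every downstream computation; the raw (pre-mask) values are never
#' needed by the model.
#'
#' @param x numeric matrix, samples in rows, features in columns. Entries
#'   at masked positions must be 0.
#' @param mask binary matrix of the same shape; 1 marks an observed entry.
#' @param modality_of named character vector mapping every feature id
#'   (names) to its modality. Block order follows the first appearance of
#'   each modality in this vector.
#' @param sample_ids character vector of unique sample identifiers.
#' @param class_names character vector of class names (defines C and the
#'   integer coding of `y`).
#' @param y integer class labels in `1..C`, `NA` where unlabeled.
#' @param group character/factor stratum per sample, `NA` where absent.
#' @param pseudo optional numeric matrix (n x C) of soft pseudo-labels;
#'   rows must sum to 1; all-`NA` rows mark samples without a pseudo-label.
#'
#' @return An object of class `pf_cohort` with elements `x`, `mask`,
#'   `feature_ids`, `modality_of`, `blocks`, `sample_ids`, `class_names`,
#'   `y`, `group`, `pseudo`, and a `meta` list (e.g. normalization record).
#' @export
multiomic_cohort <- function(x, mask, modality_of,
                             sample_ids = rownames(x),
                             class_names = NULL,
                             y = NULL, group = NULL, pseudo = NULL) {
  x <- as.matrix(x)
  mask <- as.matrix(mask)
  n <- nrow(x); d <- ncol(x)
  feature_ids <- colnames(x)
  if (is.null(feature_ids)) abort("feature matrix must have column names (feature ids)")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(max(n, 0L)))
  if (anyDuplicated(sample_ids)) abort("duplicated sample ids")
  if (anyDuplicated(feature_ids)) abort("duplicated feature ids")
  if (!all(dim(mask) == dim(x))) abort("mask and x dimensions differ")
  if (!all(mask %in% c(0, 1))) abort("mask entries must be 0 or 1")
  if (any(x[mask == 0] != 0)) abort("values at masked positions must be stored as 0")
  missing_map <- setdiff(feature_ids, names(modality_of))
  if (length(missing_map)) {
    abort(paste0("features absent from modality map: ",
                 paste(head(missing_map, 5), collapse = ", ")))
  }
  extra <- setdiff(names(modality_of), feature_ids)
  if (length(extra)) {
    warn(paste0(length(extra), " feature(s) in the modality map are absent",
                " from the table and are ignored"))
    modality_of <- modality_of[setdiff(names(modality_of), extra)]
  }
  mods <- unique(unname(modality_of))  # first-appearance order
  blocks <- lapply(mods, function(m) {
    which(feature_ids %in% names(modality_of)[modality_of == m])
  })
  names(blocks) <- mods
  stopifnot(sum(lengths(blocks)) == d)
  if (is.null(y)) y <- rep(NA_integer_, n)
  if (is.null(group)) group <- rep(NA_character_, n)
  if (is.null(class_names)) {
    C <- if (all(is.na(y))) 0L else max(y, na.rm = TRUE)
    class_names <- if (C > 0) paste0("class", seq_len(C)) else character()
  }
  C <- length(class_names)
  if (!all(is.na(y)) && (min(y, na.rm = TRUE) < 1 || max(y, na.rm = TRUE) > C))
    abort("labels outside 1..C")
  if (!is.null(pseudo)) {
    pseudo <- as.matrix(pseudo)
    if (nrow(pseudo) != n || ncol(pseudo) != C) abort("pseudo-label matrix must be n x C")
    has <- !is.na(pseudo[, 1])
    if (any(has)) {
      sums <- rowSums(pseudo[has, , drop = FALSE])
      if (any(abs(sums - 1) > 1e-9)) abort("pseudo-labels must sum to 1")
    }
  }
  structure(
    list(x = x, mask = mask, feature_ids = feature_ids,
         modality_of = modality_of, blocks = blocks,
         sample_ids = as.character(sample_ids),
         class_names = class_names,
         y = as.integer(y), group = as.character(group), pseudo = pseudo,
         meta = list()),
    class = "pf_cohort")
}

#' Extract one sample from a cohort
#'
#' Realises the per-subject view of a cohort: the masked feature vector,
#' its observation mask, the modality block structure and any label,
#' stratum or soft pseudo-label attached to the subject.
#'
#' @param cohort a [multiomic_cohort()].
#' @param i sample index or sample id.
#' @return list with `sample_id`, `x`, `mask`, `x_tilde`, `blocks`, `y`,
#'   `group`, `pseudo_label`.
#' @export
cohort_sample <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$sample_ids)
  x <- cohort$x[i, ]; m <- cohort$mask[i, ]
  list(sample_id = cohort$sample_ids[i],
       x = x, mask = m, x_tilde = m * x,
       blocks = cohort$blocks,
       y = cohort$y[i], group = cohort$group[i],
       pseudo_label = if (is.null(cohort$pseudo)) NULL else cohort$pseudo[i, ])
}

#' Number of samples, features and modalities of a cohort
#' @param cohort a [multiomic_cohort()].
#' @return named list `n`, `d`, `M`, `C`, `block_sizes`.
#' @export
cohort_dims <- function(cohort) {
  list(n = nrow(cohort$x), d = ncol(cohort$x), M = length(cohort$blocks),
       C = length(cohort$class_names), block_sizes = lengths(cohort$blocks))
}

#' @export
print.pf_cohort <- function(x, ...) {
  dm <- cohort_dims(x)
  cat(sprintf("<pf_cohort> %d samples x %d features, %d modalities (%s)\n",
              dm$n, dm$d, dm$M,
              paste(sprintf("%s:%d", names(x$blocks), lengths(x$blocks)),
                    collapse = ", ")))
  if (dm$C) cat("  classes:", paste(x$class_names, collapse = ", "), "\n")
  cat(sprintf("  labeled: %d, with pseudo-labels: %d, observed entries: %.1f%%\n",
              sum(!is.na(x$y)),
              if (is.null(x$pseudo)) 0L else sum(!is.na(x$pseudo[, 1])),
              100 * mean(x$mask)))
  invisible(x)
}

#' @method as_tibble pf_cohort
#' @export
as_tibble.pf_cohort <- function(x, ...) {
  tb <- tibble(sample_id = x$sample_ids,
               y = x$y,
               class = ifelse(is.na(x$y), NA_character_, x$class_names[x$y]),
               group = x$group,
               observed_frac = rowMeans(x$mask))
  if (!is.null(x$pseudo)) {
    ps <- as_tibble(as.data.frame(x$pseudo))
    names(ps) <- paste0("p_", x$class_names)
    tb <- dplyr::bind_cols(tb, ps)
  }
  tb
}

#' Pathway collection
#'
#' Named feature sets over a fixed feature universe, with the derived
#' P x d binary membership matrix `C_matrix` (row k has ones at the
#' features belonging to pathway k).
#'
#' @param pathways named list of character vectors of member feature ids.
#' @param feature_ids the cohort's feature universe (defines column order).
#' @param min_size pathways with fewer retained members are excluded.
#' @return object of class `pf_pathways` with `pathways` (member index
#'   vectors), `names`, `C_matrix`, `feature_ids`, `min_size`.
#' @export
pathway_collection <- function(pathways, feature_ids, min_size = 3) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  kept <- list()
  for (nm in names(pathways)) {
    idx <- match(intersect(pathways[[nm]], feature_ids), feature_ids)
    if (length(idx) >= min_size) kept[[nm]] <- sort(idx)
  }
  P <- length(kept); d <- length(feature_ids)
  C_matrix <- matrix(0, P, d, dimnames = list(names(kept), feature_ids))
  for (k in seq_len(P)) C_matrix[k, kept[[k]]] <- 1
  structure(list(pathways = kept, names = names(kept),
                 C_matrix = C_matrix, feature_ids = feature_ids,
                 min_size = min_size),
            class = "pf_pathways")
}

#' @export
print.pf_pathways <- function(x, ...) {
  cat(sprintf("<pf_pathways> %d pathways over %d features (min_size %d)\n",
              length(x$pathways), length(x$feature_ids), x$min_size))
  invisible(x)
}

#' Pathway-mean pooling operator
#'
#' P x d matrix with row k equal to `1/|P_k|` at the members of pathway k,
#' so `pool_matrix %*% H` computes the pathway-mean rows of `H`.
#'
#' @param pathways a [pathway_collection()].
#' @return base matrix (P x d).
#' @export
pathway_pool_matrix <- function(pathways) {
  sizes <- vapply(pathways$pathways, length, integer(1))
  pathways$C_matrix / sizes
}
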