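#' Read a sample-by-feature table with its modality map
#'
#' Reads a TSV whose header row holds feature ids and whose first column
#' holds sample ids, together with a two-column (feature_id, modality)
#' TSV. Empty cells and the tokens `NA`/`NaN` (case-insensitive) are
#' treated as unobserved: the mask is set to 0 there and the stored value
#' is 0, implementing the masked-input convention
#' \eqn{\tilde{x} = m \odot x}. No imputation is ever performed.
#'
#' @param path feature table TSV.
#' @param modality_map_path two-column TSV with header `feature_id`,
#'   `modality`.
#' @return a [multiomic_cohort()] (unlabeled; attach metadata with
#'   [attach_sample_metadata()]).
#' @export
read_feature_table <- function(path, modality_map_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  feature_ids <- colnames(tab)[-1]
  if (anyDuplicated(feature_ids)) abort("duplicated feature ids in header")
  sample_ids <- tab[[1]]
  if (anyDuplicated(sample_ids)) abort("duplicated sample ids")
  n <- nrow(tab); d <- length(feature_ids)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  missing <- is.na(vals) | tolower(trimws(vals)) %in% c("", "na", "nan")
  x <- suppressWarnings(matrix(as.numeric(vals), n, d))
  bad <- !missing & is.na(x)
  if (any(bad)) abort("non-numeric cell(s) in feature table")
  x[missing] <- 0
  mask <- matrix(1, n, d); mask[missing] <- 0
  dimnames(x) <- dimnames(mask) <- list(sample_ids, feature_ids)
  mm <- utils::read.delim(modality_map_path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("feature_id", "modality") %in% names(mm)))
    abort("modality map needs columns feature_id, modality")
  modality_of <- setNames(mm$modality, mm$feature_id)
  multiomic_cohort(x, mask, modality_of, sample_ids = sample_ids)
}

#' Attach labels, groups and pseudo-labels to a cohort
#'
#' Reads a TSV keyed by `sample_id` with optional columns `label`
#' (class name), `group`, and soft pseudo-label columns
#' `p_<class1>..p_<classC>`. Class order follows the pseudo-label
#' columns when present, otherwise first appearance of labels.
#'
#' @param cohort a [multiomic_cohort()].
#' @param path metadata TSV.
#' @param class_names optional explicit class order.
#' @return the cohort with `y`, `group`, `pseudo`, `class_names` filled.
#' @export
attach_sample_metadata <- function(cohort, path, class_names = NULL) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!"sample_id" %in% names(md)) abort("metadata needs a sample_id column")
  idx <- match(cohort$sample_ids, md$sample_id)
  if (anyNA(idx)) abort("metadata missing some cohort samples")
  md <- md[idx, , drop = FALSE]
  pcols <- grep("^p_", names(md), value = TRUE)
  if (is.null(class_names)) {
    class_names <- if (length(pcols)) sub("^p_", "", pcols)
                   else unique(md$label[!is.na(md$label) & md$label != ""])
  }
  y <- if ("label" %in% names(md)) match(md$label, class_names) else rep(NA_integer_, nrow(md))
  group <- if ("group" %in% names(md)) md$group else rep(NA_character_, nrow(md))
  group[!is.na(group) & group == ""] <- NA_character_
  pseudo <- NULL
  if (length(pcols)) {
    pseudo <- matrix(suppressWarnings(as.numeric(as.matrix(md[, pcols, drop = FALSE]))),
                     nrow(md), length(pcols))
    colnames(pseudo) <- sub("^p_", "", pcols)
    pseudo <- pseudo[, class_names, drop = FALSE]
  }
  multiomic_cohort(cohort$x, cohort$mask, cohort$modality_of,
                   sample_ids = cohort$sample_ids, class_names = class_names,
                   y = y, group = group, pseudo = pseudo)
}

#' Z-score features within each modality over observed entries
#'
#' Per-feature statistics are computed over observed (mask = 1) entries
#' only, with the population (1/n) standard deviation; masked entries
#' stay exactly 0 afterwards. Features with fewer than two observed
#' values, and zero-variance features, map to 0. The convention is
#' recorded in `cohort$meta$normalization`.
#'
#' @param cohort a [multiomic_cohort()].
#' @return the normalized cohort.
#' @export
zscore_by_modality <- function(cohort) {
  x <- cohort$x; m <- cohort$mask
  n_obs <- colSums(m)
  sums <- colSums(x * m)
  mu <- ifelse(n_obs > 0, sums / pmax(n_obs, 1), 0)
  cent <- sweep(x, 2, mu) * m
  sdv <- sqrt(colSums(cent^2) / pmax(n_obs, 1))        # population convention
  usable <- n_obs >= 2 & sdv > 0
  z <- sweep(cent, 2, ifelse(usable, sdv, 1), `/`)
  z[, !usable] <- 0
  z <- z * m
  out <- cohort
  out$x <- z
  out$meta$normalization <- list(method = "zscore_by_modality",
                                 sd = "population (1/n)",
                                 per_feature_mean = mu, per_feature_sd = sdv,
                                 n_observed = n_obs)
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one pathway per line, fields `name`, `description`, then
#' member ids, tab-separated. Members absent from `feature_ids` are
#' dropped (with a message); pathways with fewer than `min_size` retained
#' members are excluded.
#'
#' @param path GMT file.
#' @param feature_ids feature universe of the cohort.
#' @param min_size minimum retained members per pathway (default 3).
#' @return a [pathway_collection()].
#' @export
read_gmt <- function(path, feature_ids, min_size = 3) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    if (!nzchar(f[1])) abort(sprintf("malformed GMT line %d: empty set name", i))
    sets[[f[1]]] <- f[-(1:2)]
  }
  dropped <- sum(vapply(sets, function(s) sum(!s %in% feature_ids), integer(1)))
  if (dropped > 0)
    message(dropped, " GMT member(s) absent from the feature universe were dropped")
  pathway_collection(sets, feature_ids, min_size = min_size)
}

#' Read an undirected edge list
#'
#' Two-column TSV of feature-id pairs. Edges are deduplicated regardless
#' of orientation; self-loops are rejected (normalization adds its own
#' self-loops later); both endpoints must exist in `feature_ids`.
#'
#' @param path edge list TSV (header `from`, `to` optional).
#' @param feature_ids feature universe.
#' @return tibble with columns `from`, `to` (feature ids) and `from_idx`,
#'   `to_idx` (1-based indices, `from_idx < to_idx`).
#' @export
read_edge_list <- function(path, feature_ids) {
  empty_edges <- tibble(from = character(), to = character(),
                        from_idx = integer(), to_idx = integer())
  if (!any(nzchar(readLines(path)))) return(empty_edges)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (nrow(raw) &&
      identical(tolower(unname(unlist(raw[1, 1:2]))), c("from", "to")))
    raw <- raw[-1, , drop = FALSE]
  if (!nrow(raw)) return(empty_edges)
  a <- raw[[1]]; b <- raw[[2]]
  ia <- match(a, feature_ids); ib <- match(b, feature_ids)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(a[is.na(ia)], b[is.na(ib)]))
    abort(paste0("edge endpoints not in feature universe: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (any(ia == ib)) abort("self-loops are not allowed in the input edge list")
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  keep <- !duplicated(cbind(lo, hi))
  tibble(from = feature_ids[lo[keep]], to = feature_ids[hi[keep]],
         from_idx = lo[keep], to_idx = hi[keep])
}

fmt_num <- function(v) {
  # bit-stable plain formatting shared by all writers
  ifelse(is.na(v), "NA", sprintf("%.10g", v))
}

#' Write a cohort and its metadata to TSV files
#'
#' Emits the same dialects the readers consume: `features.tsv` (masked
#' entries written as `NA`), `modality_map.tsv`, and `metadata.tsv` with
#' label, group and `p_<class>` pseudo-label columns. Output is
#' deterministic given the cohort.
#'
#' @param cohort a [multiomic_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(features = file.path(dir, "features.tsv"),
             modality_map = file.path(dir, "modality_map.tsv"),
             metadata = file.path(dir, "metadata.tsv"))
  xm <- cohort$x
  xm[cohort$mask == 0] <- NA
  lines <- c(paste(c("sample_id", cohort$feature_ids), collapse = "\t"),
             vapply(seq_len(nrow(xm)), function(i) {
               paste(c(cohort$sample_ids[i], fmt_num(xm[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, paths[["features"]])
  writeLines(c("feature_id\tmodality",
               paste(names(cohort$modality_of), cohort$modality_of, sep = "\t")),
             paths[["modality_map"]])
  md <- c("sample_id\tlabel\tgroup")
  has_pseudo <- !is.null(cohort$pseudo)
  if (has_pseudo)
    md <- paste(c(md, paste0("p_", cohort$class_names)), collapse = "\t")
  rows <- vapply(seq_along(cohort$sample_ids), function(i) {
    lab <- if (is.na(cohort$y[i])) "" else cohort$class_names[cohort$y[i]]
    grp <- if (is.na(cohort$group[i])) "" else cohort$group[i]
    r <- c(cohort$sample_ids[i], lab, grp)
    if (has_pseudo) r <- c(r, fmt_num(cohort$pseudo[i, ]))
    paste(r, collapse = "\t")
  }, character(1))
  writeLines(c(md, rows), paths[["metadata"]])
  invisible(paths)
}

#' Write pathways as GMT
#' @param pathways a [pathway_collection()] or named list of member id vectors.
#' @param path output file.
#' @export
write_gmt <- function(pathways, path) {
  if (inherits(pathways, "pf_pathways")) {
    fid <- pathways$feature_ids
    pathways <- lapply(pathways$pathways, function(i) fid[i])
  }
  writeLines(vapply(names(pathways), function(nm) {
    paste(c(nm, "na", pathways[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Write an undirected edge list as TSV
#' @param edges tibble as returned by [read_edge_list()].
#' @param path output file.
#' @export
write_edge_list <- function(edges, path) {
  writeLines(c("from\tto", paste(edges$from, edges$to, sep = "\t")), path)
  invisible(path)
}
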