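#' Rank-statistic binary AUC
#'
#' Area under the ROC curve computed from the Mann-Whitney rank
#' statistic: the probability that a random positive scores above a
#' random negative, with ties counted half.
#'
#' @param truth logical (or 0/1) vector of positives.
#' @param score numeric scores.
#' @return AUC in `[0, 1]`, or `NA` if one class is absent.
#' @export
auc_rank <- function(truth, score) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics on a cohort split
#'
#' Accuracy, macro-averaged recall, macro-averaged F1 and macro
#' one-vs-rest AUC of the deterministic predictions, reported as
#' fractions in `[0, 1]`. With a single-class split the AUC is `NA`.
#'
#' @param object a [pf_fit()] or [pf_model()].
#' @param cohort the cohort the object was trained on (or a compatible
#'   one).
#' @param indices sample indices to score; defaults to the fit's test
#'   split (all samples for a bare model).
#' @return one-row tibble `accuracy`, `macro_recall`, `macro_f1`,
#'   `macro_auc`, `n`.
#' @export
pf_evaluate <- function(object, cohort, indices = NULL) {
  if (is.null(indices)) {
    indices <- if (inherits(object, "pf_fit")) object$split$test
               else seq_along(cohort$sample_ids)
  }
  pr <- pf_predict(object, cohort, indices)
  y <- cohort$y[indices]
  pred <- max.col(pr, ties.method = "first")
  C <- ncol(pr)
  rec <- f1 <- auc <- numeric(C)
  for (c_ in seq_len(C)) {
    tp <- sum(pred == c_ & y == c_)
    fn <- sum(pred != c_ & y == c_)
    fp <- sum(pred == c_ & y != c_)
    rec[c_] <- if (tp + fn > 0) tp / (tp + fn) else NA
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1[c_] <- if (!is.na(rec[c_]) && (prec + rec[c_]) > 0)
      2 * prec * rec[c_] / (prec + rec[c_]) else 0
    auc[c_] <- auc_rank(y == c_, pr[, c_])
  }
  present <- !is.na(rec)
  tibble(accuracy = mean(pred == y),
         macro_recall = mean(rec[present]),
         macro_f1 = mean(f1[present]),
         macro_auc = if (sum(present) < 2) NA_real_
                     else mean(auc[present], na.rm = TRUE),
         n = length(indices))
}

#' Multi-seed evaluation summary
#'
#' Evaluates several fits (e.g. trained with different seeds) on their
#' own test splits and reports per-seed metrics plus mean and standard
#' deviation, following the convention of averaging over repeated runs
#' with different random seeds.
#'
#' @param fits list of [pf_fit()] objects.
#' @param cohort the shared cohort.
#' @return list with `per_seed` (tibble, one row per fit) and `summary`
#'   (tibble with mean and sd per metric).
#' @export
pf_evaluate_seeds <- function(fits, cohort) {
  per <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
    dplyr::mutate(pf_evaluate(fits[[i]], cohort),
                  seed = fits[[i]]$train_config$seed, .before = 1)
  }))
  summ <- per |>
    tidyr::pivot_longer(c("accuracy", "macro_recall", "macro_f1", "macro_auc"),
                        names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value), .groups = "drop")
  list(per_seed = per, summary = summ)
}
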