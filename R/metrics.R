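#' Screening classification metrics
#'
#' Builds the confusion table from a strict `score > threshold` call and
#' reports the standard virtual-screening metrics: TPR (sensitivity, the
#' fraction of truly related compounds identified), FPR, precision,
#' specificity (= 1 - FPR), F1 and the rank-based AUC.  A metric whose
#' denominator is zero is reported as 0 and named in the `zero_division`
#' flag rather than returned as NaN, so reports stay machine-readable.
#'
#' @param y_true 0/1 labels (factor/logical accepted).
#' @param scores numeric classifier scores.
#' @param threshold decision cutoff; a compound is called related when its
#'   score is strictly greater.  Default 0.5.
#' @return An object of class `fnt_metrics`: list with `tp`, `fp`, `tn`,
#'   `fn`, `tpr`, `fpr`, `precision`, `specificity`, `f1`, `auc` (NA when
#'   only one class is present) and `zero_division` (character vector of
#'   metrics that had an empty denominator).
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
#' @export
classification_metrics <- function(y_true, scores, threshold = 0.5) {
  y <- coerce_labels(y_true)
  if (length(y) == 0L) stop("empty input")
  if (length(y) != length(scores))
    stop("y_true and scores must have equal length")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)

  flags <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); return(0) }
    num / den
  }
  tpr <- div(tp, tp + fn, "tpr")
  fpr <- div(fp, fp + tn, "fpr")
  precision <- div(tp, tp + fp, "precision")
  specificity <- div(tn, tn + fp, "specificity")
  f1 <- div(2 * precision * tpr, precision + tpr, "f1")
  auc <- if (length(unique(y)) == 2L) auc_score(y, scores) else NA_real_

  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 tpr = tpr, fpr = fpr, precision = precision,
                 specificity = specificity, f1 = f1, auc = auc,
                 threshold = threshold, zero_division = flags),
            class = "fnt_metrics")
}

#' @export
print.fnt_metrics <- function(x, ...) {
  cat(sprintf("  confusion: tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf(
    "  TPR %.4f  FPR %.4f  Precision %.4f  Specificity %.4f  F1 %.4f",
    x$tpr, x$fpr, x$precision, x$specificity, x$f1))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.4f", x$auc))
  cat("\n")
  if (length(x$zero_division))
    cat("  (zero denominator, reported as 0:",
        paste(x$zero_division, collapse = ", "), ")\n")
  invisible(x)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed with the Mann-Whitney statistic: the
#' probability that a random related compound scores above a random
#' unrelated one, with tied scores contributing 1/2.
#'
#' @param y_true 0/1 labels; both classes must be present.
#' @param scores numeric scores.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(y_true, scores) {
  y <- coerce_labels(y_true)
  if (length(y) != length(scores))
    stop("y_true and scores must have equal length")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs both classes present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that every fold's class
#' counts differ from an even split by at most one sample per class.
#'
#' @param y 0/1 labels.
#' @param k number of folds.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k = 10L) {
  y <- coerce_labels(y)
  k <- as.integer(k)
  if (any(table(y) < k))
    stop("each class needs at least k = ", k,
         " samples; use a smaller k")
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validate the FNT classifier
#'
#' Stratified k-fold cross-validation of [fnt_fit()]: for each fold the
#' model is trained on the remaining folds (feature scaling refitted on
#' the training part only) and scored on the held-out compounds.  Per-fold
#' metrics plus their mean and standard deviation are returned along with
#' the fold assignment, so a run is fully reproducible from `(data, seed)`.
#'
#' @param x feature matrix.
#' @param y 0/1 labels; each class needs at least `k` members.
#' @param k number of folds (default 10).
#' @param control an [fnt_control()].
#' @param seed integer seed driving both the fold assignment and each
#'   fold's training.
#' @return An object of class `fnt_cv`: list with `folds` (assignment),
#'   `per_fold` (data frame of metrics per fold), `mean`, `sd` (named
#'   numeric vectors over tpr/fpr/precision/specificity/f1/auc), `k`,
#'   `seed`.
#' @export
fnt_cv <- function(x, y, k = 10L, control = fnt_control(), seed = NULL) {
  x <- as.matrix(x)
  y <- coerce_labels(y)
  if (!is.null(seed)) set.seed(as.integer(seed))
  fold <- stratified_folds(y, k)
  metric_names <- c("tpr", "fpr", "precision", "specificity", "f1", "auc")
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- fnt_fit(x[tr, , drop = FALSE], y[tr], control = control,
                   seed = if (is.null(seed)) NULL
                          else (as.integer(seed) + f) %% .Machine$integer.max)
    sc <- predict(fit, x[!tr, , drop = FALSE], type = "score")
    m <- classification_metrics(y[!tr], sc, threshold = control$threshold)
    rows[[f]] <- data.frame(fold = f, t(unlist(m[metric_names])))
  }
  per_fold <- do.call(rbind, rows)
  structure(list(folds = fold,
                 per_fold = per_fold,
                 mean = colMeans(per_fold[metric_names], na.rm = TRUE),
                 sd = apply(per_fold[metric_names], 2L, stats::sd,
                            na.rm = TRUE),
                 k = k, seed = seed),
            class = "fnt_cv")
}

#' @export
print.fnt_cv <- function(x, ...) {
  cat(x$k, "fold cross-validation\n")
  cat("  mean (sd) over folds:\n")
  for (nm in names(x$mean))
    cat(sprintf("    %-11s %.4f (%.4f)\n", nm, x$mean[[nm]], x$sd[[nm]]))
  invisible(x)
}

#' Average-rank comparison of methods across datasets
#'
#' Given a methods-by-datasets table of a performance metric, ranks the
#' methods within each dataset (rank 1 = best; tied values share the mean
#' of their ranks) and returns each method's rank averaged over datasets —
#' the usual way a set of classifiers is compared across several screens.
#'
#' @param metric_table numeric matrix or data frame, rows = methods,
#'   columns = datasets, no missing entries.
#' @param higher_is_better whether larger metric values are better
#'   (default `TRUE`, as for AUC).
#' @return Named numeric vector of averaged ranks, one per method.
#' @export
rank_methods <- function(metric_table, higher_is_better = TRUE) {
  m <- as.matrix(metric_table)
  if (any(is.na(m))) stop("metric table has missing entries")
  ranks <- apply(m, 2L, function(col) {
    if (higher_is_better) rank(-col, ties.method = "average")
    else rank(col, ties.method = "average")
  })
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = nrow(m))
  out <- rowMeans(ranks)
  names(out) <- rownames(m)
  out
}

#' Class-ratio experiment
#'
#' Re-runs decoy selection and cross-validation at several
#' positive:negative ratios (1:r for each r in `ratios`): for each ratio
#' the `r * m` least-similar decoys are selected from the pool, a dataset
#' is assembled from the fingerprints' bit vectors, and the FNT classifier
#' is cross-validated.  A ratio the pool cannot support is reported with
#' an error message and the remaining ratios still run.
#'
#' @param positives `fingerprint_set` of related compounds (label 1).
#' @param decoy_pool `fingerprint_set` of candidate decoys.
#' @param ratios integer vector of negatives-per-positive ratios, default
#'   `c(1, 2, 3, 4, 5, 6, 8, 10)`.
#' @param k cross-validation folds.
#' @param control an [fnt_control()].
#' @param seed integer seed.
#' @return Data frame with one row per ratio: `ratio`, `n_neg`,
#'   `auc_mean`, `auc_sd`, `error` (NA when the ratio ran).
#' @export
ratio_experiment <- function(positives, decoy_pool,
                             ratios = c(1, 2, 3, 4, 5, 6, 8, 10),
                             k = 10L, control = fnt_control(),
                             seed = NULL) {
  stopifnot(inherits(positives, "fingerprint_set"),
            inherits(decoy_pool, "fingerprint_set"))
  pos_x <- fp_to_matrix(positives)
  rows <- lapply(seq_along(ratios), function(i) {
    r <- ratios[[i]]
    res <- tryCatch({
      sel <- select_decoys(positives, decoy_pool, ratio = r)
      neg_x <- fp_to_matrix(decoy_pool)[sel$indices, , drop = FALSE]
      x <- rbind(pos_x, neg_x)
      y <- c(rep(1L, nrow(pos_x)), rep(0L, nrow(neg_x)))
      cv <- fnt_cv(x, y, k = k, control = control,
                   seed = if (is.null(seed)) NULL
                          else (as.integer(seed) + i) %% .Machine$integer.max)
      data.frame(ratio = r, n_neg = length(sel$indices),
                 auc_mean = cv$mean[["auc"]], auc_sd = cv$sd[["auc"]],
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(ratio = r, n_neg = NA_integer_, auc_mean = NA_real_,
                 auc_sd = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE))
    res
  })
  do.call(rbind, rows)
}
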