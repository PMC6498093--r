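#' Cross-validation configuration
#'
#' Defaults mirror the standard protocol for small liquid-biopsy cohorts:
#' stratified 10-fold cross-validation repeated 3 times, with confusion
#' counts pooled over all repeats (so 19 samples yield a denominator of 57).
#'
#' @param n_folds number of folds (default 10).
#' @param n_repeats number of repetitions (default 3).
#' @param stratified stratify folds by class (default `TRUE`).
#' @param feature_selection_scope `"full_data"` (rank features once on the
#'   complete dataset before cross-validation — reproduces the historical
#'   protocol but lets feature selection see the test folds) or `"per_fold"`
#'   (nested selection inside every training fold; unbiased and recommended
#'   for new analyses).
#' @param seed integer seed; repeat `r` uses `seed + r`.
#' @return an object of class `"cv_config"`.
#' @export
cv_config <- function(n_folds = 10, n_repeats = 3, stratified = TRUE,
                      feature_selection_scope = c("full_data", "per_fold"),
                      seed = 1L) {
  feature_selection_scope <- match.arg(feature_selection_scope)
  stopifnot(n_folds >= 2, n_repeats >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified),
                 feature_selection_scope = feature_selection_scope,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Assigns every sample to one of `k` folds so that fold sizes differ by at
#' most one and each fold's class counts are within one of proportionality.
#' Classes are dealt round-robin (largest class first) onto the folds with
#' the fewest samples, with seeded random shuffling within class and random
#' tie-breaking among equally filled folds.
#'
#' @param labels a [label_vector()].
#' @param k number of folds (`k <=` number of samples).
#' @param seed integer seed.
#' @return integer vector of fold numbers (1..k), named by sample id.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  n <- length(labels)
  if (k > n) stop(sprintf("cannot make %d folds from %d samples", k, n))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(substream_seed(seed, 29L))
  fold <- integer(n)
  sizes <- integer(k)
  tab <- sort(table(as.character(labels)), decreasing = TRUE)
  for (cl in names(tab)) {
    idx <- which(as.character(labels) == cl)
    idx <- idx[sample.int(length(idx))]
    for (i in idx) {
      candidates <- which(sizes == min(sizes))
      f <- if (length(candidates) == 1L) candidates else
        candidates[sample.int(length(candidates), 1L)]
      fold[i] <- f
      sizes[f] <- sizes[f] + 1L
    }
  }
  names(fold) <- names(labels)
  fold
}

#' Construct a 2x2 pooled confusion matrix
#'
#' Counts follow the convention positive = adenocarcinoma: `tp` and `fn` are
#' actual positives predicted positive/negative, `fp` and `tn` actual
#' negatives predicted positive/negative.
#'
#' @param tp,fn,fp,tn non-negative counts.
#' @param positive,negative class names.
#' @return an object of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn, positive = "adenocarcinoma",
                             negative = "granuloma") {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 positive = positive, negative = negative),
            class = "confusion_matrix")
}

confusion_from_predictions <- function(truth, pred, positive, negative) {
  confusion_matrix(tp = sum(truth == positive & pred == positive),
                   fn = sum(truth == positive & pred != positive),
                   fp = sum(truth == negative & pred == positive),
                   tn = sum(truth == negative & pred != positive),
                   positive = positive, negative = negative)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), nrow = 2, byrow = TRUE,
              dimnames = list(paste("actual", c(x$negative, x$positive)),
                              paste("predicted", c(x$negative, x$positive))))
  print(m)
  cat(sprintf("%s accuracy: %.2f%%\n", x$negative, class_accuracy(x, x$negative)))
  cat(sprintf("%s accuracy: %.2f%%\n", x$positive, class_accuracy(x, x$positive)))
  cat(sprintf("weighted accuracy: %.2f%%\n", weighted_accuracy(x)))
  invisible(x)
}

#' Per-class accuracy, in percent
#'
#' @param cm a [confusion_matrix()].
#' @param class the class name (positive or negative class of `cm`).
#' @return correct / actual x 100 for that class.
#' @export
class_accuracy <- function(cm, class) {
  if (class == cm$positive) {
    actual <- cm$tp + cm$fn
    correct <- cm$tp
  } else if (class == cm$negative) {
    actual <- cm$tn + cm$fp
    correct <- cm$tn
  } else {
    stop("unknown class: ", class)
  }
  if (actual == 0) stop("no actual samples of class ", class)
  100 * correct / actual
}

#' Weighted (class-balanced) accuracy, in percent
#'
#' The mean of the two per-class accuracies — insensitive to the 10-vs-9
#' class imbalance that plain accuracy would reward.
#'
#' @param cm a [confusion_matrix()].
#' @return mean of the positive- and negative-class accuracies (percent).
#' @export
weighted_accuracy <- function(cm) {
  (class_accuracy(cm, cm$positive) + class_accuracy(cm, cm$negative)) / 2
}

#' Repeated stratified cross-validation of the MCFS–RIPPER classifier
#'
#' For each repeat, samples are split into stratified folds; for each fold a
#' RIPPER ruleset is trained on the remaining samples (restricted to the
#' `k_top` features ranked by Monte-Carlo feature selection, either once on
#' the full data or nested per fold, per
#' `cv$feature_selection_scope`) and the held-out samples are predicted.
#' Confusion counts are pooled over all folds and repeats, so they sum to
#' `n_repeats * n_samples`.
#'
#' @param m expression matrix (features x samples).
#' @param labels a [label_vector()].
#' @param cv a [cv_config()].
#' @param mcfs a [mcfs_params()].
#' @param k_top number of top-ranked features passed to RIPPER (default 10).
#' @param ripper a [ripper_params()].
#' @return pooled [confusion_matrix()], with attribute `"per_repeat"` (list
#'   of per-repeat confusion matrices) and `"selected_features"` (the
#'   full-data selection, when that scope is used).
#' @export
repeated_cv <- function(m, labels, cv = cv_config(), mcfs = mcfs_params(),
                        k_top = 10, ripper = ripper_params()) {
  validate_expression_matrix(m)
  check_both_classes(labels)
  pos <- positive_class(labels)
  neg <- negative_class(labels)
  k_top <- min(k_top, nrow(m))

  selected_full <- NULL
  if (cv$feature_selection_scope == "full_data") {
    ri <- run_mcfs(m, labels, mcfs)
    selected_full <- rank_features(ri)[seq_len(k_top)]
  }

  pool <- c(tp = 0, fn = 0, fp = 0, tn = 0)
  per_repeat <- vector("list", cv$n_repeats)
  for (r in seq_len(cv$n_repeats)) {
    fold <- stratified_folds(labels, cv$n_folds, seed = cv$seed + r)
    truth <- as.character(labels)
    pred <- character(length(labels))
    for (f in sort(unique(fold))) {
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      train_labels <- labels[train_idx]
      if (length(unique(as.character(train_labels))) < 2L)
        stop(sprintf("fold %d leaves a single-class training set", f))
      feats <- selected_full
      if (is.null(feats)) {
        mcfs_fold <- mcfs
        mcfs_fold$seed <- substream_seed(mcfs$seed, 1000L * r + f)
        ri <- run_mcfs(m[, train_idx, drop = FALSE], train_labels, mcfs_fold)
        feats <- rank_features(ri)[seq_len(k_top)]
      }
      rip <- ripper
      rip$seed <- substream_seed(ripper$seed, 500L * r + f)
      rs <- train_ripper(m[feats, train_idx, drop = FALSE], train_labels, rip)
      pred[test_idx] <- predict(rs, m[feats, test_idx, drop = FALSE])
    }
    cm_r <- confusion_from_predictions(truth, pred, pos, neg)
    per_repeat[[r]] <- cm_r
    pool <- pool + c(tp = cm_r$tp, fn = cm_r$fn, fp = cm_r$fp, tn = cm_r$tn)
  }
  out <- confusion_matrix(unname(pool["tp"]), unname(pool["fn"]),
                          unname(pool["fp"]), unname(pool["tn"]),
                          positive = pos, negative = neg)
  attr(out, "per_repeat") <- per_repeat
  attr(out, "selected_features") <- selected_full
  out
}
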