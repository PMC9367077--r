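# Cross-validated evaluation and the embedding-size sweep.

#' Five-fold cross-validation with the full metric suite
#'
#' For each fold, trains the classifier on the remaining folds, scores the
#' held-out pairs, thresholds at 0.5 for the confusion-based metrics and
#' computes AUC from the probability scores. The fold assignment is supplied
#' by the caller so every classifier sees the identical permutation.
#'
#' @param x Feature matrix (pairs x 2k).
#' @param y Binary labels.
#' @param folds Integer fold assignment from [make_folds()].
#' @param spec A [classifier_spec()].
#' @param seed Base seed; each fold trains with a seed derived from it.
#' @param threshold Probability cutoff for hard labels; default 0.5.
#' @return A `metrics_report`: `per_fold` (data frame of Acc/Pre/Sen/Spe/FPR/
#'   F1/AUC per fold), `mean` (arithmetic mean over folds), and `roc` (per-
#'   fold FPR/TPR series).
#' @export
cross_validate <- function(x, y, folds, spec, seed = 1L, threshold = 0.5) {
  stopifnot(nrow(x) == length(y), length(folds) == length(y))
  fold_ids <- sort(unique(folds))
  rows <- vector("list", length(fold_ids))
  roc <- vector("list", length(fold_ids))
  for (f in seq_along(fold_ids)) {
    test <- folds == fold_ids[f]
    model <- train_classifier(spec, x[!test, , drop = FALSE], y[!test],
                              seed = derive_seed(seed, f))
    prob <- predict_prob(model, x[test, , drop = FALSE])
    pred <- as.integer(prob > threshold)
    met <- compute_metrics(confusion_counts(y[test], pred))
    rc <- roc_auc(y[test], prob)
    rows[[f]] <- data.frame(fold = fold_ids[f], t(met), AUC = rc$auc)
    roc[[f]] <- rc
  }
  per_fold <- do.call(rbind, rows)
  means <- colMeans(per_fold[, -1, drop = FALSE])
  structure(list(classifier = spec$name, per_fold = per_fold,
                 mean = means, roc = roc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s, %d folds (values in %%)\n",
              x$classifier, nrow(x$per_fold)))
  pct <- round(100 * x$mean[c("Acc", "F1", "Pre", "Sen", "Spe", "AUC")], 2)
  print(pct)
  invisible(x)
}

#' Embedding-size sweep with per-classifier optimum
#'
#' Cross-validates every classifier at every embedding size and selects, per
#' classifier, the size maximising mean AUC (ties broken toward the smaller
#' size).
#'
#' @param features_by_k Named list (names = sizes) of feature matrices, all
#'   over the same pairs — e.g. built by [featurize_pairs()] from an
#'   [embedding_sweep()].
#' @param y Binary labels.
#' @param folds Shared fold assignment.
#' @param specs List of [classifier_spec()] objects.
#' @param seed Base seed.
#' @return A `sweep_result`: `auc` (classifier x size matrix of mean AUC) and
#'   `optimal` (named integer vector of each classifier's best size).
#' @export
sweep_and_select <- function(features_by_k, y, folds, specs, seed = 1L) {
  stopifnot(length(features_by_k) >= 1)
  sizes <- as.integer(names(features_by_k))
  cls <- vapply(specs, function(s) s$name, "")
  auc <- matrix(NA_real_, length(specs), length(sizes),
                dimnames = list(cls, names(features_by_k)))
  for (si in seq_along(specs)) {
    for (ki in seq_along(sizes)) {
      rep <- cross_validate(features_by_k[[ki]], y, folds, specs[[si]],
                            seed = seed)
      auc[si, ki] <- rep$mean[["AUC"]]
    }
  }
  optimal <- apply(auc, 1, function(a) {
    best <- which(a == max(a))
    sizes[best[which.min(sizes[best])]]
  })
  structure(list(auc = auc, optimal = optimal, sizes = sizes),
            class = "sweep_result")
}

#' Write a metrics report in percentage form
#'
#' Emits one CSV of per-fold metrics and one of fold means, with
#' Acc/F1/Pre/Sen/Spe/AUC expressed as percentages.
#'
#' @param report A `metrics_report`.
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cols <- c("Acc", "F1", "Pre", "Sen", "Spe", "AUC")
  per <- report$per_fold
  per[cols] <- round(100 * per[cols], 3)
  p1 <- file.path(dir, sprintf("metrics_%s_per_fold.csv", report$classifier))
  write.table(per, p1, sep = ",", quote = FALSE, row.names = FALSE)
  m <- data.frame(classifier = report$classifier,
                  t(round(100 * report$mean[cols], 3)))
  p2 <- file.path(dir, sprintf("metrics_%s_mean.csv", report$classifier))
  write.table(m, p2, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
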