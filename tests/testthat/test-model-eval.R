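test_that("confusion counts tally the 2x2 table with positive class 1", {
  c1 <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(c1[c("TP", "FP", "TN", "FN")]), c(TP = 2, FP = 0, TN = 2, FN = 0))
  c2 <- confusion_counts(c(1, 0), c(0, 1))
  expect_equal(c2$FN, 1)
  expect_equal(c2$FP, 1)
  expect_error(confusion_counts(c(1, 0), c(1)), "equal length")

  # element-wise oracle on random labels
  set.seed(7)
  t200 <- rbinom(200, 1, 0.5)
  p200 <- rbinom(200, 1, 0.5)
  cc <- confusion_counts(t200, p200)
  oracle <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in 1:200) {
    cell <- if (t200[i] == 1 && p200[i] == 1) "TP"
            else if (t200[i] == 0 && p200[i] == 1) "FP"
            else if (t200[i] == 0 && p200[i] == 0) "TN" else "FN"
    oracle[cell] <- oracle[cell] + 1
  }
  expect_equal(unlist(cc[names(oracle)]), oracle)
  expect_equal(sum(unlist(cc)), 200)
})

test_that("metrics equal direct substitution into their defining ratios", {
  cc <- structure(list(TP = 9, FP = 1, TN = 8, FN = 2),
                  class = "confusion_counts")
  m <- compute_metrics(cc)
  expect_equal(m[["Acc"]], 17 / 20)
  expect_equal(m[["Pre"]], 0.9)
  expect_equal(m[["Sen"]], 9 / 11)
  expect_equal(m[["Spe"]], 8 / 9)
  expect_equal(m[["FPR"]], 1 / 9)
  expect_equal(m[["F1"]], 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11))

  perfect <- compute_metrics(confusion_counts(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(unname(perfect[c("Acc", "Pre", "Sen", "Spe", "F1")]),
               rep(1, 5))

  degenerate <- compute_metrics(confusion_counts(c(1, 1, 0), c(0, 0, 0)))
  expect_true(is.na(degenerate[["Pre"]]))
  expect_true("Pre" %in% attr(degenerate, "undefined"))
})

test_that("metric identities hold on computed reports", {
  set.seed(11)
  for (rep in 1:20) {
    truth <- rbinom(50, 1, 0.5)
    pred <- rbinom(50, 1, 0.5)
    if (length(unique(truth)) < 2) next
    m <- compute_metrics(confusion_counts(truth, pred))
    P <- sum(truth == 1); N <- sum(truth == 0)
    expect_equal(m[["Spe"]], 1 - m[["FPR"]], tolerance = 1e-12)
    expect_equal(m[["Acc"]],
                 (m[["Sen"]] * P + m[["Spe"]] * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("trapezoid AUC equals brute-force concordance counting", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.5, 0.5, 0.5, 0.5))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.3, 0.4)), "both classes")

  set.seed(23)
  for (rep in 1:10) {
    n <- sample(10:100, 1)
    truth <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(stats::runif(n), 2)  # coarse grid forces ties
    got <- roc_auc(truth, scores)
    expect_equal(got$auc, auc_concordance(truth, scores), tolerance = 1e-12)
    # curve sanity: monotone from (0,0) to (1,1)
    expect_equal(got$fpr[1], 0)
    expect_equal(got$tpr[length(got$tpr)], 1)
    expect_true(all(diff(got$fpr) >= 0) && all(diff(got$tpr) >= 0))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  truth <- rbinom(80, 1, 0.5)
  truth[1:2] <- c(0, 1)
  scores <- stats::rnorm(80)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(truth, scores)$auc, ref, tolerance = 1e-12)
})

test_that("label-shuffled scores drive AUC to chance level", {
  pipe <- cached_pipeline(seed = 1)
  n <- nrow(pipe$benchmark)
  scores <- stats::runif(n)  # any fixed scores; labels get shuffled
  set.seed(42)
  aucs <- vapply(1:20, function(i) {
    roc_auc(sample(pipe$benchmark$label), scores)$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("an uninformative scorer yields fold AUCs of exactly one half", {
  set.seed(5)
  y <- rep(c(0L, 1L), 20)
  scores <- rep(0.5, 40)
  expect_equal(roc_auc(y, scores)$auc, 0.5)
})

test_that("cross-validation separates linearly separable planted features", {
  set.seed(19)
  n <- 100
  y <- rep(c(0L, 1L), n / 2)
  x <- matrix(stats::rnorm(n * 6), n, 6)
  x[, 1] <- 3 * y  # perfectly separable direction, identical across folds
  folds <- make_folds(data.frame(label = y), n_folds = 5, seed = 1)
  for (cls in c("RF", "XGB")) {
    rep <- cross_validate(x, y, folds, classifier_spec(cls), seed = 2)
    expect_equal(unname(rep$mean[["Acc"]]), 1)
    expect_equal(unname(rep$mean[["AUC"]]), 1)
  }
})

test_that("all six classifiers run under the shared fold permutation", {
  set.seed(29)
  n <- 60
  y <- rep(c(0L, 1L), n / 2)
  x <- matrix(stats::rnorm(n * 4), n, 4)
  x[, 1] <- x[, 1] + 3 * y
  folds <- make_folds(data.frame(label = y), n_folds = 5, seed = 1)
  for (cls in c("SVM", "LR", "RF", "ABRF", "XGB", "MP")) {
    rep <- cross_validate(x, y, folds, classifier_spec(cls), seed = 3)
    expect_equal(nrow(rep$per_fold), 5)
    expect_true(all(rep$per_fold$AUC >= 0 & rep$per_fold$AUC <= 1))
    expect_gt(rep$mean[["AUC"]], 0.8, label = cls)
  }
})

test_that("XGB cross-validation is deterministic for a fixed seed", {
  pipe <- cached_pipeline(seed = 1)
  r1 <- cross_validate(pipe$features, pipe$benchmark$label, pipe$folds,
                       classifier_spec("XGB"), seed = 10)
  r2 <- cross_validate(pipe$features, pipe$benchmark$label, pipe$folds,
                       classifier_spec("XGB"), seed = 10)
  expect_identical(r1$per_fold, r2$per_fold)
})

test_that("sweep selects the AUC-maximising size, ties toward smaller k", {
  set.seed(37)
  n <- 60
  y <- rep(c(0L, 1L), n / 2)
  x <- matrix(stats::rnorm(n * 4), n, 4)
  x[, 1] <- x[, 1] + 3 * y
  folds <- make_folds(data.frame(label = y), n_folds = 5, seed = 1)

  single <- sweep_and_select(list("4" = x), y, folds,
                             list(classifier_spec("XGB")))
  expect_equal(unname(single$optimal["XGB"]), 4)

  # identical features under two size labels force a tie -> smaller k wins
  tied <- sweep_and_select(list("4" = x, "8" = x), y, folds,
                           list(classifier_spec("XGB")))
  expect_equal(unname(tied$optimal["XGB"]), 4)
  expect_equal(tied$auc[1, 1], tied$auc[1, 2])
})
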