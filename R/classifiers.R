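# The six benchmark classifiers behind one train/score interface.

CLASSIFIER_NAMES <- c("SVM", "LR", "RF", "ABRF", "XGB", "MP")

#' Specify one of the six benchmark classifiers
#'
#' Supported names: `SVM` (radial support vector machine), `LR` (logistic
#' regression), `RF` (random forest), `ABRF` (AdaBoost over random-forest base
#' learners), `XGB` (gradient-boosted trees, the pipeline default) and `MP`
#' (single-hidden-layer multilayer perceptron). `params` overrides any
#' hyperparameter of the underlying fit, so externally published settings can
#' be pinned in one place.
#'
#' @param name Classifier name.
#' @param params Named list of hyperparameter overrides.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(name = "XGB", params = list()) {
  name <- toupper(name)
  if (!name %in% CLASSIFIER_NAMES) {
    stop(sprintf("unknown classifier '%s' (expected one of %s)", name,
                 paste(CLASSIFIER_NAMES, collapse = ", ")), call. = FALSE)
  }
  structure(list(name = name, params = params,
                 probability = TRUE),
            class = "classifier_spec")
}

defaults_for <- function(name) {
  switch(name,
    SVM = list(kernel = "radial", cost = 1),
    LR = list(),
    RF = list(ntree = 500),
    ABRF = list(n_rounds = 10, base_ntree = 50),
    XGB = list(nrounds = 100, max_depth = 6, eta = 0.3),
    MP = list(size = 16, decay = 5e-4, maxit = 300)
  )
}

merge_params <- function(name, params) {
  p <- defaults_for(name)
  p[names(params)] <- params
  p
}

#' Train a specified classifier
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric feature matrix.
#' @param y Binary labels over \{0, 1\}.
#' @param seed Integer seed for the learner's internal randomness.
#' @return A `trained_classifier` holding the fit and the spec.
#' @export
train_classifier <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("there must be at least two classes in the dataset", call. = FALSE)
  }
  p <- merge_params(spec$name, spec$params)
  fit <- with_local_seed(seed, switch(spec$name,
    SVM = e1071::svm(x, factor(y, levels = c(0, 1)), probability = TRUE,
                     kernel = p$kernel, cost = p$cost),
    LR = {
      df <- data.frame(y = y, x)
      suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    },
    RF = randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                    ntree = p$ntree),
    ABRF = adaboost_rf_fit(x, y, n_rounds = p$n_rounds,
                           base_ntree = p$base_ntree),
    XGB = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = p$max_depth,
                    eta = p$eta, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = p$nrounds, verbose = 0),
    MP = nnet::nnet(x, y, size = p$size, decay = p$decay, maxit = p$maxit,
                    entropy = TRUE, trace = FALSE,
                    MaxNWts = (ncol(x) + 2) * p$size + p$size + 10)
  ))
  structure(list(spec = spec, fit = fit, features = colnames(x)),
            class = "trained_classifier")
}

#' Positive-class probability scores from a trained classifier
#'
#' @param model A `trained_classifier`.
#' @param x Feature matrix to score.
#' @return Numeric vector of P(label = 1) per row.
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "trained_classifier"))
  fit <- model$fit
  switch(model$spec$name,
    SVM = {
      pr <- predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    LR = unname(predict(fit, newdata = data.frame(x), type = "response")),
    RF = unname(predict(fit, x, type = "prob")[, "1"]),
    ABRF = adaboost_rf_prob(fit, x),
    XGB = unname(predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))),
    MP = as.numeric(predict(fit, x))
  )
}

# AdaBoost (discrete, two-class) with small random forests as base learners.
# Rounds reweight the training pairs; each round fits its forest on a
# weighted bootstrap resample.
adaboost_rf_fit <- function(x, y, n_rounds = 10, base_ntree = 50) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  learners <- list()
  alphas <- numeric(0)
  yf <- factor(y, levels = c(0, 1))
  for (m in seq_len(n_rounds)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    fit <- randomForest::randomForest(x[idx, , drop = FALSE], yf[idx],
                                      ntree = base_ntree)
    pred <- as.integer(as.character(predict(fit, x)))
    err <- sum(w * (pred != y))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5 && m > 1) break
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(ifelse(pred != y, alpha, -alpha))
    w <- w / sum(w)
    learners[[length(learners) + 1L]] <- fit
    alphas <- c(alphas, alpha)
  }
  list(learners = learners, alphas = alphas)
}

adaboost_rf_prob <- function(fit, x) {
  scores <- vapply(seq_along(fit$learners), function(m) {
    fit$alphas[m] * predict(fit$learners[[m]], x, type = "prob")[, "1"]
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(x))
  rowSums(scores) / sum(fit$alphas)
}
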