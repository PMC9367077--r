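# Case-study protocol: train on all positives plus a third of the negatives,
# then rank every untrained candidate pair by predicted probability.

#' Train the case-study scorer
#'
#' Trains on every positive pair plus `floor(n_neg * neg_fraction)` negatives
#' sampled uniformly without replacement. Using only a third of the negatives
#' limits how much the model learns from sampled "negatives" that may in
#' truth be undiscovered positives, while keeping both classes present.
#'
#' @param benchmark Benchmark data frame (circ_id, disease_id, label).
#' @param emb An `embedding_matrix` covering the benchmark nodes.
#' @param neg_fraction Fraction of negatives to train on; default 1/3.
#' @param seed Integer seed for the negative subsample.
#' @param spec Classifier; default XGB, the pipeline's final model.
#' @return A `case_model` holding the trained scorer, the embedding and the
#'   set of trained pairs.
#' @export
train_case_model <- function(benchmark, emb, neg_fraction = 1 / 3, seed = 1L,
                             spec = classifier_spec("XGB")) {
  pos <- benchmark[benchmark$label == 1L, , drop = FALSE]
  neg <- benchmark[benchmark$label == 0L, , drop = FALSE]
  if (nrow(neg) < 3) {
    stop("need at least 3 negative pairs: there must be at least two classes ",
         "in the training set", call. = FALSE)
  }
  n_take <- floor(nrow(neg) * neg_fraction)
  if (n_take < 1) stop("neg_fraction leaves no negatives", call. = FALSE)
  take <- with_local_seed(seed, sample.int(nrow(neg), n_take))
  train <- rbind(pos, neg[sort(take), , drop = FALSE])
  x <- featurize_pairs(train, emb)
  model <- train_classifier(spec, x, train$label, seed = derive_seed(seed, 99L))
  structure(list(model = model, emb = emb,
                 trained_pairs = train[, c("circ_id", "disease_id")],
                 n_neg_trained = n_take),
            class = "case_model")
}

#' Probability-ranked candidate pairs for selected diseases
#'
#' Candidates are every (circRNA, disease) combination of the benchmark's
#' circRNAs with the requested diseases, minus the pairs the model was
#' trained on. Each candidate is scored with the predicted association
#' probability and ranked per disease, descending; ties break by circRNA id
#' so output is stable.
#'
#' @param case_model A `case_model` from [train_case_model()].
#' @param diseases Character vector of disease ids to rank candidates for.
#' @param circ_ids Candidate circRNA universe; defaults to the circRNAs of
#'   the trained pairs.
#' @return Data frame (disease_id, circ_id, probability, rank).
#' @export
rank_candidates <- function(case_model, diseases,
                            circ_ids = unique(case_model$trained_pairs$circ_id)) {
  stopifnot(inherits(case_model, "case_model"))
  emb <- case_model$emb
  missing <- setdiff(diseases, rownames(emb))
  if (length(missing) > 0) {
    stop(sprintf("no embedding for disease(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  cand <- expand.grid(circ_id = sort(unique(circ_ids)),
                      disease_id = sort(unique(diseases)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  trained_key <- paste(case_model$trained_pairs$circ_id,
                       case_model$trained_pairs$disease_id, sep = "\r")
  cand <- cand[!(paste(cand$circ_id, cand$disease_id, sep = "\r") %in%
                   trained_key), , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(disease_id = character(), circ_id = character(),
                      probability = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  x <- featurize_pairs(cand, emb)
  cand$probability <- predict_prob(case_model$model, x)
  out <- do.call(rbind, lapply(split(cand, cand$disease_id), function(d) {
    d <- d[order(-d$probability, d$circ_id), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(out) <- NULL
  out[, c("disease_id", "circ_id", "probability", "rank")]
}
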