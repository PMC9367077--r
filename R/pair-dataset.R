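# Balanced labeled benchmark of circRNA-disease pairs with concatenated
# embedding features and shared cross-validation folds.

#' Positive circRNA-disease pairs from the known-association edge set
#'
#' @param circ_disease_edges A `"circRNA-disease"` [bipartite_network()] or a
#'   two-column data frame (circ_id, disease_id). Duplicate edges collapse to
#'   one positive.
#' @return Data frame (circ_id, disease_id, label = 1) with attributes
#'   `n_pos`, `n_circ`, `n_disease`.
#' @export
build_positive_pairs <- function(circ_disease_edges) {
  if (inherits(circ_disease_edges, "bipartite_network")) {
    stopifnot(circ_disease_edges$relation == "circRNA-disease")
    e <- circ_disease_edges$edges
  } else {
    e <- data.frame(from = as.character(circ_disease_edges[[1]]),
                    to = as.character(circ_disease_edges[[2]]),
                    stringsAsFactors = FALSE)
  }
  e <- unique(e[, 1:2])
  pairs <- data.frame(circ_id = e[[1]], disease_id = e[[2]], label = 1L,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$circ_id, pairs$disease_id), ]
  rownames(pairs) <- NULL
  attr(pairs, "n_pos") <- nrow(pairs)
  attr(pairs, "n_circ") <- length(unique(pairs$circ_id))
  attr(pairs, "n_disease") <- length(unique(pairs$disease_id))
  pairs
}

#' Candidate space of circRNA x disease combinations
#'
#' Enumerates every combination of the circRNAs and diseases occurring in the
#' positive set, counts the unknown (non-positive) pairs, and reports the
#' false-negative exposure of uniform negative sampling — the chance that a
#' sampled "negative" is in truth an undiscovered positive, n_pos / n_unknown.
#'
#' @param positives Output of [build_positive_pairs()].
#' @return List with `n_circ`, `n_disease`, `n_total`, `n_pos`, `n_unknown`,
#'   `fn_exposure`, and `unknowns` (data frame enumerating each unknown pair
#'   exactly once).
#' @export
candidate_space <- function(positives) {
  stopifnot(nrow(positives) >= 1)
  circ <- sort(unique(positives$circ_id))
  dis <- sort(unique(positives$disease_id))
  all_pairs <- expand.grid(circ_id = circ, disease_id = dis,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$circ_id, d$disease_id, sep = "\r")
  unknown <- all_pairs[!(key(all_pairs) %in% key(positives)), , drop = FALSE]
  unknown <- unknown[order(unknown$circ_id, unknown$disease_id), ]
  rownames(unknown) <- NULL
  n_total <- length(circ) * length(dis)
  n_pos <- nrow(positives)
  list(
    n_circ = length(circ),
    n_disease = length(dis),
    n_total = n_total,
    n_pos = n_pos,
    n_unknown = n_total - n_pos,
    fn_exposure = n_pos / (n_total - n_pos),
    unknowns = unknown
  )
}

#' Sample negative pairs uniformly from the unknown set
#'
#' Draws exactly as many label-0 pairs as there are positives, uniformly
#' without replacement from the circRNA x disease combinations never reported
#' as associated — the balanced-benchmark design.
#'
#' @param positives Output of [build_positive_pairs()].
#' @param seed Integer seed.
#' @return Data frame (circ_id, disease_id, label = 0), disjoint from the
#'   positives.
#' @export
sample_negatives <- function(positives, seed) {
  space <- candidate_space(positives)
  n_pos <- space$n_pos
  if (space$n_unknown < n_pos) {
    stop(sprintf("only %d unknown pairs available but %d negatives required",
                 space$n_unknown, n_pos), call. = FALSE)
  }
  idx <- with_local_seed(seed, sample.int(space$n_unknown, n_pos))
  neg <- space$unknowns[sort(idx), , drop = FALSE]
  neg$label <- 0L
  rownames(neg) <- NULL
  neg
}

#' Assemble the balanced benchmark (positives + sampled negatives)
#'
#' @param circ_disease_edges Known associations (see
#'   [build_positive_pairs()]).
#' @param seed Seed for negative sampling.
#' @return Data frame (circ_id, disease_id, label) with positives first.
#' @export
build_benchmark <- function(circ_disease_edges, seed) {
  pos <- build_positive_pairs(circ_disease_edges)
  neg <- sample_negatives(pos, seed)
  bench <- rbind(pos[, c("circ_id", "disease_id", "label")], neg)
  rownames(bench) <- NULL
  bench
}

#' Concatenated pair features from a node embedding
#'
#' Each pair's feature vector is the circRNA embedding followed by the
#' disease embedding (fixed order), length 2k.
#'
#' @param pairs Data frame with `circ_id`, `disease_id`.
#' @param emb An `embedding_matrix` covering every referenced node.
#' @return Numeric matrix (n_pairs x 2k).
#' @export
featurize_pairs <- function(pairs, emb) {
  emb <- unclass(emb)
  need <- unique(c(pairs$circ_id, pairs$disease_id))
  missing <- setdiff(need, rownames(emb))
  if (length(missing) > 0) {
    stop(sprintf("no embedding for node(s): %s",
                 paste(head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  x <- cbind(emb[pairs$circ_id, , drop = FALSE],
             emb[pairs$disease_id, , drop = FALSE])
  rownames(x) <- NULL
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  x
}

#' Assign cross-validation folds shared by all classifiers
#'
#' By default folds are stratified by label so each fold's class balance
#' matches the benchmark's; fold sizes differ by at most one pair.
#'
#' @param pairs Benchmark data frame with a `label` column.
#' @param n_folds Number of folds; default 5.
#' @param seed Integer seed.
#' @param stratified Stratify by label (default) or plain shuffle.
#' @return Integer vector of fold indices in `1..n_folds`, one per row of
#'   `pairs`.
#' @export
make_folds <- function(pairs, n_folds = 5, seed = 1L, stratified = TRUE) {
  n <- nrow(pairs)
  assert_count(n_folds, "n_folds", min = 2L)
  if (n < n_folds) stop("fewer pairs than folds", call. = FALSE)
  with_local_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      for (lab in unique(pairs$label)) {
        rows <- which(pairs$label == lab)
        fold[rows[sample.int(length(rows))]] <-
          rep_len(seq_len(n_folds), length(rows))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
    fold
  })
}
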