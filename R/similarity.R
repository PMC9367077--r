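# Derived edge sets: circRNA-circRNA sequence similarity (mean-score cutoff)
# and disease-disease Wang semantic similarity (0.8 cutoff).

#' Pairwise global-alignment similarity between circRNA sequences
#'
#' Scores every unordered pair with a Needleman-Wunsch global alignment under
#' a simple bounded scheme (default match = +1, mismatch = 0, no gap penalty)
#' and normalizes each score by the length of the shorter sequence, so scores
#' are length-comparable and lie in \[0, 1\] under the default scheme.
#' Identical sequences score 1; sequences over disjoint alphabets score 0.
#'
#' @param records A named [Biostrings::DNAStringSet] (names are circRNA ids),
#'   or a named character vector of sequences over \{A, C, G, T, N\}.
#' @param match,mismatch Substitution scores. `N` scores 0 against anything.
#' @param gap_opening,gap_extension Gap penalties (non-negative magnitudes, as
#'   in [Biostrings::pairwiseAlignment()]).
#' @param max_pairs Guard against accidental quadratic blow-up; raise for
#'   large inputs.
#' @return A symmetric `similarity_matrix` (ids as dimnames, unit diagonal)
#'   with the scoring scheme stored in `attr(, "scheme")`.
#' @export
pairwise_sequence_scores <- function(records, match = 1, mismatch = 0,
                                     gap_opening = 0, gap_extension = 0,
                                     max_pairs = 250000) {
  chars <- if (is.character(records)) records else as.character(records)
  ids <- names(chars)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("records must carry unique names", call. = FALSE)
  }
  n <- length(chars)
  if (n < 2) stop("need at least two sequence records", call. = FALSE)
  bad <- which(!nzchar(chars) | grepl("[^ACGTN]", chars))
  if (length(bad) > 0) {
    stop(sprintf("empty or non-nucleotide sequence in record(s): %s",
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  records <- Biostrings::DNAStringSet(chars)
  widths <- Biostrings::width(records)
  if (n * (n - 1) / 2 > max_pairs) {
    stop(sprintf("all-pairs alignment would need %d pairs (> max_pairs = %d)",
                 n * (n - 1) %/% 2, max_pairs), call. = FALSE)
  }
  alpha <- c("A", "C", "G", "T", "N")
  submat <- matrix(mismatch, 5, 5, dimnames = list(alpha, alpha))
  diag(submat) <- match
  submat["N", ] <- 0
  submat[, "N"] <- 0
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(m) <- 1
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    sc <- Biostrings::pairwiseAlignment(
      pattern = records[rest], subject = records[[i]],
      type = "global", substitutionMatrix = submat,
      gapOpening = gap_opening, gapExtension = gap_extension,
      scoreOnly = TRUE
    )
    norm <- pmin(widths[rest], widths[i])
    m[i, rest] <- m[rest, i] <- sc / norm
  }
  attr(m, "scheme") <- list(match = match, mismatch = mismatch,
                            gap_opening = gap_opening,
                            gap_extension = gap_extension,
                            normalization = "shorter-sequence length")
  class(m) <- c("similarity_matrix", class(m))
  m
}

#' circRNA-circRNA edges above the mean pairwise similarity
#'
#' The cutoff is the arithmetic mean over all off-diagonal unordered pair
#' scores; retained edges are exactly the pairs scoring strictly above it.
#'
#' @param m A `similarity_matrix` from [pairwise_sequence_scores()].
#' @return A [bipartite_network()] with relation `"circRNA-circRNA"`;
#'   attributes `cutoff` and `n_edges` record the threshold used.
#' @export
mean_threshold_edges <- function(m) {
  stopifnot(inherits(m, "similarity_matrix") || (is.matrix(m) && isSymmetric(unclass(m))))
  n <- nrow(m)
  if (n < 2) stop("similarity matrix has no off-diagonal pairs", call. = FALSE)
  ut <- upper.tri(m)
  cutoff <- mean(m[ut])
  keep <- which(ut & m > cutoff, arr.ind = TRUE)
  ids <- rownames(m)
  net <- bipartite_network("circRNA-circRNA",
                           data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
                                      stringsAsFactors = FALSE))
  attr(net, "cutoff") <- cutoff
  attr(net, "n_edges") <- nrow(net$edges)
  net
}

#' Construct a disease ontology DAG from tree-number records
#'
#' Parent resolution follows the MeSH dialect: each tree number's parent is
#' the longest proper prefix (dot-separated) present among the records; a term
#' holding several tree numbers gets the union of the implied parents, so the
#' term graph is a DAG rooted at the prefix-minimal terms.
#'
#' @param terms Data frame with columns `term_id`, `tree_number` (a term may
#'   appear on several rows).
#' @param attachment Data frame with columns `disease_id`, `term_id` mapping
#'   each disease to its ontology term(s).
#' @return An `ontology_dag` with `terms`, `parents` (term -> character vector
#'   of parent terms) and `attachment`.
#' @export
ontology_dag <- function(terms, attachment) {
  stopifnot(all(c("term_id", "tree_number") %in% names(terms)),
            all(c("disease_id", "term_id") %in% names(attachment)))
  terms <- data.frame(term_id = as.character(terms$term_id),
                      tree_number = as.character(terms$tree_number),
                      stringsAsFactors = FALSE)
  if (!all(attachment$term_id %in% terms$term_id)) {
    missing <- setdiff(attachment$term_id, terms$term_id)
    stop(sprintf("attachment references unknown term(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  num_owner <- setNames(terms$term_id, terms$tree_number)
  parent_of_number <- function(num) {
    parts <- strsplit(num, ".", fixed = TRUE)[[1]]
    while (length(parts) > 1) {
      parts <- parts[-length(parts)]
      cand <- paste(parts, collapse = ".")
      if (cand %in% names(num_owner)) return(unname(num_owner[cand]))
    }
    NA_character_
  }
  par_by_row <- vapply(terms$tree_number, parent_of_number, "")
  parents <- lapply(split(par_by_row, terms$term_id), function(p) {
    sort(unique(p[!is.na(p)]))
  })
  ids <- unique(terms$term_id)
  parents <- parents[ids]
  structure(
    list(terms = terms,
         parents = setNames(parents, ids),
         attachment = data.frame(
           disease_id = as.character(attachment$disease_id),
           term_id = as.character(attachment$term_id),
           stringsAsFactors = FALSE)),
    class = "ontology_dag"
  )
}

# Wang S-values for one term: every ancestor t of `term` (including itself)
# receives the decayed contribution D(t) = 1 for the term itself, otherwise
# delta * max over its children lying on a path to the term.
wang_svalues <- function(dag, term, delta) {
  s <- setNames(1, term)
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (t in frontier) {
      for (p in dag$parents[[t]]) {
        cand <- delta * s[[t]]
        if (!(p %in% names(s)) || cand > s[[p]]) {
          s[p] <- cand
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  s
}

# Wang similarity between two ontology *terms*.
wang_term_similarity <- function(dag, t1, t2, delta = 0.5) {
  if (!t1 %in% names(dag$parents) || !t2 %in% names(dag$parents)) {
    stop("term not present in ontology", call. = FALSE)
  }
  s1 <- wang_svalues(dag, t1, delta)
  s2 <- wang_svalues(dag, t2, delta)
  shared <- intersect(names(s1), names(s2))
  if (length(shared) == 0) return(0)
  sum(s1[shared] + s2[shared]) / (sum(s1) + sum(s2))
}

#' Wang semantic similarity between two diseases
#'
#' Implements the decayed-ancestor-contribution measure on the ontology DAG:
#' each ancestor `t` of a disease's term contributes
#' `D(t) = 1` for the term itself and `delta * max(D over children on the
#' path)` otherwise; the semantic value is the sum of contributions and the
#' similarity of diseases A and B is
#' `sum_(t in T_A intersect T_B) (D_A(t) + D_B(t)) / (DV(A) + DV(B))`.
#' Diseases attached to several terms score as the maximum over term pairs.
#'
#' @param dag An [ontology_dag()].
#' @param a,b Disease ids present in the DAG's attachment table.
#' @param delta Semantic contribution decay factor in (0, 1); default 0.5.
#' @return Similarity in \[0, 1\]; symmetric in its arguments.
#' @export
wang_similarity <- function(dag, a, b, delta = 0.5) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (delta <= 0 || delta >= 1) stop("`delta` must lie in (0, 1)", call. = FALSE)
  terms_of <- function(d) {
    t <- dag$attachment$term_id[dag$attachment$disease_id == d]
    if (length(t) == 0) {
      stop(sprintf("disease '%s' is not attached to the ontology", d),
           call. = FALSE)
    }
    t
  }
  ta <- terms_of(a)
  tb <- terms_of(b)
  max(vapply(ta, function(x) {
    max(vapply(tb, function(y) wang_term_similarity(dag, x, y, delta), 0))
  }, 0))
}

#' Disease-disease edges above a semantic-similarity cutoff
#'
#' Computes the Wang similarity for every unordered disease pair and retains
#' exactly the pairs scoring strictly above the cutoff (default 0.8).
#'
#' @param dag An [ontology_dag()].
#' @param diseases Character vector of disease ids (all attached).
#' @param cutoff Strict retention threshold; default 0.8.
#' @param delta Wang decay factor; default 0.5.
#' @return A [bipartite_network()] with relation `"disease-disease"`; the full
#'   pairwise score matrix is stored in `attr(, "scores")`.
#' @export
disease_similarity_edges <- function(dag, diseases, cutoff = 0.8, delta = 0.5) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (cutoff <= 0 || cutoff > 1) stop("`cutoff` must lie in (0, 1]", call. = FALSE)
  diseases <- unique(as.character(diseases))
  n <- length(diseases)
  scores <- matrix(1, n, n, dimnames = list(diseases, diseases))
  from <- character(0); to <- character(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- wang_similarity(dag, diseases[i], diseases[j], delta)
        scores[i, j] <- scores[j, i] <- s
        if (s > cutoff) {
          from <- c(from, diseases[i])
          to <- c(to, diseases[j])
        }
      }
    }
  }
  net <- bipartite_network("disease-disease",
                           data.frame(from = from, to = to,
                                      stringsAsFactors = FALSE))
  attr(net, "scores") <- scores
  attr(net, "cutoff") <- cutoff
  net
}
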