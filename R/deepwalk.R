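# DeepWalk: truncated uniform random walks + skip-gram node embeddings.

#' Random-walk and skip-gram training configuration
#'
#' Defaults follow the original DeepWalk presentation: 10 walks per node of
#' length 80, context window 5, 5 training epochs. The embedding size `dim`
#' (k) is the quantity swept in [embedding_sweep()].
#'
#' @param walks_per_node Walks started at every node.
#' @param walk_length Maximum number of nodes per walk; a walk reaching a
#'   degree-0 node terminates early.
#' @param window Context radius w of the skip-gram objective.
#' @param dim Embedding size k (>= 2).
#' @param epochs Passes of skip-gram training over the walk corpus.
#' @param alpha,min_alpha Initial and floor learning rate of the linear decay.
#' @param seed Integer seed driving walk generation and weight initialisation.
#' @return A validated `walk_config` list.
#' @export
walk_config <- function(walks_per_node = 10, walk_length = 80, window = 5,
                        dim = 20, epochs = 5, alpha = 0.025,
                        min_alpha = 1e-4, seed = 1L) {
  assert_count(walks_per_node, "walks_per_node")
  assert_count(walk_length, "walk_length", min = 2L)
  assert_count(window, "window")
  assert_count(dim, "dim", min = 2L)
  assert_count(epochs, "epochs")
  if (walk_length <= window) {
    stop("`walk_length` must exceed `window`", call. = FALSE)
  }
  structure(list(walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 window = as.integer(window),
                 dim = as.integer(dim),
                 epochs = as.integer(epochs),
                 alpha = alpha, min_alpha = min_alpha,
                 seed = as.integer(seed)),
            class = "walk_config")
}

#' Generate truncated uniform random walks over a heterogeneous network
#'
#' Starts `walks_per_node` walks at every node and extends each by sampling
#' the next node uniformly from the current node's neighbours, ignoring node
#' kinds — heterogeneity enters only through which edges exist. A walk
#' stranded at a degree-0 node stops there.
#'
#' @param net A `hetnet`.
#' @param cfg A [walk_config()].
#' @return List of character vectors (node-id sequences), deterministic for a
#'   fixed (network, cfg, seed).
#' @export
generate_walks <- function(net, cfg) {
  stopifnot(inherits(net, "hetnet"), inherits(cfg, "walk_config"))
  adj <- hetnet_adjacency(net)
  ids <- names(adj)
  if (length(ids) == 0) stop("network has no nodes", call. = FALSE)
  with_local_seed(cfg$seed, {
    walks <- vector("list", length(ids) * cfg$walks_per_node)
    w <- 1L
    for (rep in seq_len(cfg$walks_per_node)) {
      for (v in ids) {
        walk <- character(cfg$walk_length)
        walk[1] <- v
        cur <- v
        len <- 1L
        while (len < cfg$walk_length) {
          nb <- adj[[cur]]
          if (length(nb) == 0) break
          cur <- nb[sample.int(length(nb), 1L)]
          len <- len + 1L
          walk[len] <- cur
        }
        walks[[w]] <- walk[seq_len(len)]
        w <- w + 1L
      }
    }
    walks
  })
}

#' Train skip-gram node embeddings on a walk corpus
#'
#' Maximises the probability of each walk position's context window under a
#' hierarchical-softmax skip-gram model (the word2vec formulation the original
#' DeepWalk uses), single-threaded so results are reproducible for a fixed
#' seed. Nodes listed in `nodes` but absent from every walk receive a zero
#' vector and a warning.
#'
#' @param walks List of node-id walks from [generate_walks()].
#' @param cfg A [walk_config()].
#' @param nodes Optional character vector of node ids the embedding must
#'   cover (e.g. `net$nodes$id`).
#' @return An `embedding_matrix`: numeric matrix (nodes x dim) with node ids
#'   as rownames; the trained model (output vectors, Huffman coding) is kept
#'   in `attr(, "model")` for likelihood evaluation.
#' @export
train_skipgram <- function(walks, cfg, nodes = NULL) {
  stopifnot(inherits(cfg, "walk_config"), length(walks) > 0)
  vocab <- sort(unique(unlist(walks, use.names = FALSE)))
  idx <- setNames(seq_along(vocab) - 1L, vocab)
  counts <- table(factor(unlist(walks, use.names = FALSE), levels = vocab))
  iwalks <- lapply(walks, function(w) unname(idx[w]))
  fit <- sg_train_cpp(iwalks, length(vocab), cfg$dim, cfg$window, cfg$epochs,
                      cfg$alpha, cfg$min_alpha, as.numeric(cfg$seed),
                      as.numeric(counts))
  emb <- fit$syn0
  rownames(emb) <- vocab
  starved <- character(0)
  if (!is.null(nodes)) {
    starved <- setdiff(nodes, vocab)
    if (length(starved) > 0) {
      warning(sprintf("%d node(s) absent from all walks; assigned zero vectors: %s",
                      length(starved), paste(head(starved, 5), collapse = ", ")))
      zero <- matrix(0, length(starved), cfg$dim, dimnames = list(starved, NULL))
      emb <- rbind(emb, zero)
    }
    emb <- emb[nodes[order(nodes)], , drop = FALSE]
  }
  attr(emb, "model") <- list(syn1 = fit$syn1, code = fit$code,
                             point = fit$point, vocab = vocab,
                             window = cfg$window)
  attr(emb, "starved") <- starved
  class(emb) <- c("embedding_matrix", class(emb))
  emb
}

#' Average skip-gram log-likelihood of walk windows under a trained embedding
#'
#' Used to verify that training actually increases the skip-gram objective:
#' returns the mean hierarchical-softmax log-probability of every
#' (center, context) pair within the window across `walks`.
#'
#' @param emb An `embedding_matrix` from [train_skipgram()].
#' @param walks Walk corpus to score (may be held out from training).
#' @return Mean log-likelihood per window pair (a negative number; closer to
#'   zero is better).
#' @export
skipgram_loglik <- function(emb, walks) {
  model <- attr(emb, "model")
  if (is.null(model)) stop("embedding carries no trained model", call. = FALSE)
  idx <- setNames(seq_along(model$vocab) - 1L, model$vocab)
  walks <- lapply(walks, function(w) w[w %in% model$vocab])
  walks <- walks[vapply(walks, length, 0L) > 0]
  iwalks <- lapply(walks, function(w) unname(idx[w]))
  syn0 <- unclass(emb)[model$vocab, , drop = FALSE]
  attr(syn0, "model") <- NULL
  sg_loglik_cpp(iwalks, model$window, syn0, model$syn1, model$code, model$point)
}

#' Train embeddings for a range of sizes, reusing one walk corpus
#'
#' Generates the walk corpus once per seed and trains one skip-gram model per
#' requested embedding size, the protocol behind the feature-size sweep
#' (multiples of 10 from 10 through 200 by default).
#'
#' @param net A `hetnet`.
#' @param sizes Embedding sizes k; default `seq(10, 200, by = 10)`.
#' @param cfg Base [walk_config()]; its `dim` is overridden per size.
#' @return Named list (names = sizes) of `embedding_matrix` objects covering
#'   the identical node set.
#' @export
embedding_sweep <- function(net, sizes = seq(10L, 200L, by = 10L),
                            cfg = walk_config()) {
  stopifnot(length(sizes) >= 1)
  walks <- generate_walks(net, cfg)
  out <- lapply(sizes, function(k) {
    cfg_k <- cfg
    cfg_k$dim <- as.integer(k)
    train_skipgram(walks, cfg_k, nodes = net$nodes$id)
  })
  names(out) <- as.character(sizes)
  out
}
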