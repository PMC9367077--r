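make_hetnet <- function(edges, relation = "circRNA-miRNA") {
  merge_networks(list(bipartite_network(relation, edges)))
}

test_that("walks on a two-node path alternate between the endpoints", {
  net <- make_hetnet(data.frame(from = "a", to = "b"))
  cfg <- walk_config(walks_per_node = 2, walk_length = 10, window = 2,
                     dim = 2, seed = 1)
  walks <- generate_walks(net, cfg)
  expect_length(walks, 4)
  for (w in walks) {
    expect_length(w, 10)
    expect_identical(w, rep(c(w[1], setdiff(c("a", "b"), w[1])), 5))
  }
})

test_that("walks never cross between disconnected components", {
  net <- merge_networks(list(
    bipartite_network("circRNA-miRNA",
                      data.frame(from = c("c1", "c2"), to = c("m1", "m2")))))
  cfg <- walk_config(walks_per_node = 5, walk_length = 20, window = 2,
                     dim = 2, seed = 3)
  comp <- connectivity_report(net)$membership
  for (w in generate_walks(net, cfg)) {
    expect_length(unique(comp[w]), 1)
  }
})

test_that("every consecutive walk pair is an edge, exhaustively", {
  pipe <- cached_pipeline(seed = 1)
  cfg <- walk_config(walks_per_node = 2, walk_length = 30, seed = 5)
  walks <- generate_walks(pipe$net, cfg)
  adj <- hetnet_adjacency(pipe$net)
  ok <- vapply(walks, function(w) {
    if (length(w) < 2) return(TRUE)
    all(vapply(seq_len(length(w) - 1),
               function(i) w[i + 1] %in% adj[[w[i]]], logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("uniform transitions: star-graph leaves are visited equally", {
  net <- make_hetnet(data.frame(from = "hub", to = paste0("l", 1:4)))
  cfg <- walk_config(walks_per_node = 100, walk_length = 17, window = 2,
                     dim = 2, seed = 9)
  walks <- generate_walks(net, cfg)
  # count transitions out of the hub only (leaves always return to the hub)
  steps <- unlist(lapply(walks, function(w) {
    w[which(w[-length(w)] == "hub") + 1]
  }))
  n <- length(steps)
  freq <- table(factor(steps, levels = paste0("l", 1:4))) / n
  se <- sqrt(0.25 * 0.75 / n)
  expect_gte(n, 4000)
  expect_true(all(abs(freq - 0.25) < 3 * se))
})

test_that("walks and embeddings are reproducible under a fixed seed", {
  net <- cached_pipeline(seed = 1)$net
  cfg <- walk_config(walks_per_node = 3, walk_length = 20, dim = 8, seed = 21)
  w1 <- generate_walks(net, cfg)
  w2 <- generate_walks(net, cfg)
  expect_identical(w1, w2)
  e1 <- train_skipgram(w1, cfg)
  e2 <- train_skipgram(w2, cfg)
  expect_identical(unclass(e1)[, ], unclass(e2)[, ])
})

test_that("requested embedding size is honoured and starved nodes get zeros", {
  net <- make_hetnet(data.frame(from = "a", to = "b"))
  cfg <- walk_config(walks_per_node = 2, walk_length = 12, window = 2,
                     dim = 10, seed = 2)
  walks <- generate_walks(net, cfg)
  expect_warning(
    emb <- train_skipgram(walks, cfg, nodes = c("a", "b", "ghost")),
    "zero vectors")
  expect_equal(dim(unclass(emb)), c(3, 10))
  expect_equal(unname(unclass(emb)["ghost", ]), rep(0, 10))
  expect_true(all(is.finite(unclass(emb))))
})

test_that("embeddings separate the cliques of a barbell graph", {
  cliq <- function(ids) {
    pairs <- t(combn(ids, 2))
    data.frame(from = pairs[, 1], to = pairs[, 2])
  }
  edges <- rbind(cliq(paste0("a", 1:6)), cliq(paste0("b", 1:6)),
                 data.frame(from = "a1", to = "b1"))
  net <- make_hetnet(edges, relation = "circRNA-circRNA")
  cos <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  seps <- vapply(1:3, function(s) {
    cfg <- walk_config(walks_per_node = 10, walk_length = 40, window = 4,
                       dim = 8, seed = s)
    emb <- unclass(train_skipgram(generate_walks(net, cfg), cfg))
    within <- across <- c()
    ids <- rownames(emb)
    for (i in 1:11) {
      for (j in (i + 1):12) {
        cs <- cos(emb[i, ], emb[j, ])
        same <- substr(ids[i], 1, 1) == substr(ids[j], 1, 1)
        if (same) within <- c(within, cs) else across <- c(across, cs)
      }
    }
    mean(within) - mean(across)
  }, 0)
  expect_true(all(seps > 0))
})

test_that("planted associated pairs are closer in embedding space than others", {
  pipe <- cached_pipeline(seed = 1)
  emb <- unclass(pipe$emb)
  truth_key <- paste(pipe$fixture$truth$from, pipe$fixture$truth$to)
  circ <- pipe$fixture$nodes$id[pipe$fixture$nodes$kind == "circRNA"]
  dis <- pipe$fixture$nodes$id[pipe$fixture$nodes$kind == "disease"]
  d_pos <- d_neg <- c()
  for (c_id in circ) {
    for (d_id in dis) {
      d <- sqrt(sum((emb[c_id, ] - emb[d_id, ])^2))
      if (paste(c_id, d_id) %in% truth_key) d_pos <- c(d_pos, d)
      else d_neg <- c(d_neg, d)
    }
  }
  expect_lt(mean(d_pos), mean(d_neg))
})

test_that("skip-gram log-likelihood of walk windows increases with training", {
  net <- cached_pipeline(seed = 1)$net
  cfg1 <- walk_config(walks_per_node = 5, walk_length = 40, dim = 10,
                      epochs = 1, seed = 31)
  cfg5 <- walk_config(walks_per_node = 5, walk_length = 40, dim = 10,
                      epochs = 5, seed = 31)
  walks <- generate_walks(net, cfg1)
  heldout <- generate_walks(net, walk_config(walks_per_node = 1,
                                             walk_length = 40, dim = 10,
                                             seed = 99))
  e1 <- train_skipgram(walks, cfg1)
  e5 <- train_skipgram(walks, cfg5)
  expect_gt(skipgram_loglik(e5, heldout), skipgram_loglik(e1, heldout))
})

test_that("the sweep reuses one walk corpus and matches direct training", {
  # default sweep grid: multiples of 10 from 10 through 200
  sizes <- eval(formals(embedding_sweep)$sizes)
  expect_length(sizes, 20)
  expect_equal(range(sizes), c(10, 200))

  net <- make_hetnet(data.frame(from = paste0("c", 1:4),
                                to = paste0("m", c(1, 1, 2, 2))))
  cfg <- walk_config(walks_per_node = 3, walk_length = 15, window = 2,
                     dim = 2, seed = 17)
  sw <- embedding_sweep(net, sizes = c(6, 10), cfg = cfg)
  expect_named(sw, c("6", "10"))
  cfg10 <- cfg; cfg10$dim <- 10L
  direct <- train_skipgram(generate_walks(net, cfg10), cfg10,
                           nodes = net$nodes$id)
  expect_identical(unclass(sw[["10"]])[, ], unclass(direct)[, ])
  # all matrices cover the identical node set
  expect_identical(rownames(sw[["6"]]), rownames(sw[["10"]]))
  expect_setequal(rownames(sw[["6"]]), net$nodes$id)
})
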