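# Positive-pair construction mirroring published benchmark bookkeeping:
# each unique circRNA i paired with disease (i mod n_dis), topped up with
# extra distinct pairs to reach the requested total.
make_positive_set <- function(n_circ, n_dis, n_pos) {
  circ <- sprintf("c%04d", seq_len(n_circ))
  dis <- sprintf("d%03d", seq_len(n_dis))
  base <- data.frame(circ_id = circ,
                     disease_id = dis[(seq_len(n_circ) - 1) %% n_dis + 1],
                     stringsAsFactors = FALSE)
  extra_n <- n_pos - n_circ
  stopifnot(extra_n >= 0, extra_n <= n_circ)
  extra <- data.frame(circ_id = circ[seq_len(extra_n)],
                      disease_id = dis[seq_len(extra_n) %% n_dis + 1],
                      stringsAsFactors = FALSE)
  out <- unique(rbind(base, extra))
  stopifnot(nrow(out) == n_pos)
  out
}

test_that("positive pairs deduplicate edges and report unique counts", {
  edges <- data.frame(from = c("c1", "c1", "c1"), to = c("d1", "d2", "d2"))
  pos <- build_positive_pairs(edges)
  expect_equal(nrow(pos), 2)
  expect_equal(attr(pos, "n_circ"), 1)
  expect_equal(attr(pos, "n_disease"), 2)
  expect_true(all(pos$label == 1L))
})

test_that("fixture positives are exactly the planted associations", {
  pipe <- cached_pipeline(seed = 1)
  pos <- build_positive_pairs(pipe$fixture$truth)
  expect_equal(nrow(pos), nrow(pipe$fixture$truth))
  expect_setequal(paste(pos$circ_id, pos$disease_id),
                  paste(pipe$fixture$truth$from, pipe$fixture$truth$to))
})

test_that("candidate space counts combinations and unknowns exhaustively", {
  pos <- build_positive_pairs(data.frame(from = "c1", to = "d1",
                                         stringsAsFactors = FALSE))
  pos2 <- build_positive_pairs(data.frame(from = c("c1", "c2", "c1"),
                                          to = c("d1", "d1", "d2")))
  sp <- candidate_space(pos2)
  expect_equal(sp$n_total, 4)
  expect_equal(sp$n_unknown, 1)
  expect_equal(nrow(sp$unknowns), 1)
  expect_equal(sp$unknowns$circ_id, "c2")
  expect_equal(sp$unknowns$disease_id, "d2")

  # enumeration yields each unknown pair exactly once
  big <- build_positive_pairs(make_positive_set(20, 6, 30))
  spb <- candidate_space(big)
  expect_equal(spb$n_total, 120)
  expect_equal(spb$n_unknown, 90)
  keys <- paste(spb$unknowns$circ_id, spb$unknowns$disease_id)
  expect_equal(anyDuplicated(keys), 0)
  expect_length(intersect(keys, paste(big$circ_id, big$disease_id)), 0)
})

test_that("negative sampling is balanced, disjoint and deterministic", {
  pos <- build_positive_pairs(make_positive_set(20, 6, 30))
  neg <- sample_negatives(pos, seed = 4)
  expect_equal(nrow(neg), 30)
  expect_true(all(neg$label == 0L))
  expect_length(intersect(paste(neg$circ_id, neg$disease_id),
                          paste(pos$circ_id, pos$disease_id)), 0)
  expect_identical(neg, sample_negatives(pos, seed = 4))

  # forced case: unknown set exactly the size required
  pos_forced <- build_positive_pairs(data.frame(from = c("c1", "c2"),
                                                to = c("d1", "d2")))
  neg_forced <- sample_negatives(pos_forced, seed = 99)
  expect_setequal(paste(neg_forced$circ_id, neg_forced$disease_id),
                  c("c1 d2", "c2 d1"))
})

test_that("negative sampling is uniform over the unknown set", {
  # 3 positives on the 3x3 diagonal: 6 unknowns, 3 drawn per seed
  pos <- build_positive_pairs(data.frame(from = c("c1", "c2", "c3"),
                                         to = c("d1", "d2", "d3")))
  cells <- c("c1 d2", "c1 d3", "c2 d1", "c2 d3", "c3 d1", "c3 d2")
  hits <- integer(6)
  n_rep <- 2000
  for (s in seq_len(n_rep)) {
    neg <- sample_negatives(pos, seed = s)
    key <- match(paste(neg$circ_id, neg$disease_id), cells)
    hits[key] <- hits[key] + 1L
  }
  freq <- hits / n_rep
  se <- sqrt(0.5 * 0.5 / n_rep)
  expect_true(all(abs(freq - 0.5) < 3 * se))
})

test_that("pair features concatenate circRNA then disease embeddings", {
  emb <- matrix(seq_len(12), nrow = 3, byrow = TRUE,
                dimnames = list(c("c1", "c2", "d1"), NULL))
  pairs <- data.frame(circ_id = c("c1", "c2"), disease_id = c("d1", "d1"))
  x <- featurize_pairs(pairs, emb)
  expect_equal(dim(x), c(2, 8))
  expect_equal(x[1, ], c(emb["c1", ], emb["d1", ]))
  # order sensitivity: swapping the two halves changes the feature
  swapped <- cbind(x[, 5:8], x[, 1:4])
  expect_false(isTRUE(all.equal(x[1, ], swapped[1, ])))
  # zero embeddings produce the zero feature
  emb0 <- matrix(0, 2, 4, dimnames = list(c("c1", "d1"), NULL))
  x0 <- featurize_pairs(pairs[1, ], emb0)
  expect_equal(unname(x0[1, ]), rep(0, 8))
  expect_error(featurize_pairs(data.frame(circ_id = "cX", disease_id = "d1"),
                               emb), "cX")
})

test_that("folds are stratified, balanced and shared across runs", {
  pairs <- data.frame(circ_id = sprintf("c%d", 1:10),
                      disease_id = sprintf("d%d", 1:10),
                      label = rep(c(1L, 0L), each = 5))
  f <- make_folds(pairs, n_folds = 5, seed = 2)
  expect_setequal(f, 1:5)
  for (k in 1:5) {
    expect_equal(sum(f == k & pairs$label == 1), 1)
    expect_equal(sum(f == k & pairs$label == 0), 1)
  }
  expect_identical(f, make_folds(pairs, n_folds = 5, seed = 2))
  expect_error(make_folds(pairs[1:3, ], n_folds = 5), "fewer pairs")

  # a balanced 1150-pair benchmark partitions into five folds of 230
  pairs_big <- data.frame(circ_id = sprintf("c%04d", 1:1150),
                          disease_id = "d1",
                          label = rep(c(1L, 0L), each = 575))
  fb <- make_folds(pairs_big, n_folds = 5, seed = 3)
  expect_equal(as.integer(table(fb)), rep(230L, 5))
  # each fold's positive fraction within one pair of the global balance
  expect_true(all(abs(tapply(pairs_big$label, fb, sum) - 115) <= 1))
})
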