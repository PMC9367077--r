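# Independent oracles used across test files.

# Needleman-Wunsch global alignment score by direct dynamic programming
# (match/mismatch substitution, zero gap penalty).
nw_score <- function(a, b, match = 1, mismatch = 0) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  d <- matrix(0, length(a) + 1, length(b) + 1)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      sub <- d[i, j] + if (a[i] == b[j]) match else mismatch
      d[i + 1, j + 1] <- max(sub, d[i, j + 1], d[i + 1, j])
    }
  }
  d[length(a) + 1, length(b) + 1]
}

# AUC as concordance over all positive x negative score pairs, ties half.
auc_concordance <- function(truth, scores) {
  sp <- scores[truth == 1]
  sn <- scores[truth == 0]
  grid <- expand.grid(p = sp, n = sn)
  mean(ifelse(grid$p > grid$n, 1, ifelse(grid$p == grid$n, 0.5, 0)))
}

# Pairwise sequence identity (same-position matches / length).
seq_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  mean(av == bv)
}

# Community lookup for a fixture: named vector id -> community.
community_of <- function(fixture) {
  setNames(fixture$nodes$community, fixture$nodes$id)
}
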