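---
title: "Methods: ceRNA-network embeddings for circRNA-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA-network embeddings for circRNA-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`cewalk` predicts circRNA–disease associations by supervised link prediction
on a heterogeneous ceRNA network. The biological premise is the competing
endogenous RNA hypothesis: circRNAs sponge miRNAs and thereby regulate the
miRNAs' mRNA targets, so a circRNA can influence a disease *indirectly*
through circRNA→miRNA→(mRNA→)disease paths. The pipeline therefore merges
seven relation sets over four node kinds into one undirected, unweighted
graph `G = (V, E)`:

* five observed bipartite relations — circRNA–disease (the known positives),
  circRNA–miRNA, miRNA–disease, miRNA–mRNA, mRNA–disease;
* two derived similarity relations — circRNA–circRNA (sequence similarity
  above the mean pairwise score) and disease–disease (Wang semantic
  similarity above 0.8).

Nodes are embedded with DeepWalk: truncated uniform random walks are treated
as sentences and a skip-gram model with hierarchical softmax maximises

$$\max_\Phi \prod_{\substack{j = i-w \\ j \neq i}}^{i+w}
  P\!\left(v_j \mid \Phi(v_i)\right)$$

over all walk positions $i$, giving $\Phi : V \to \mathbb{R}^k$. A
(circRNA, disease) pair is represented by the $2k$-vector
$\Phi(\text{circ}) \,\Vert\, \Phi(\text{disease})$ (circRNA half first), and
a binary classifier trained on a balanced benchmark predicts the association
probability.

Assumptions worth making explicit: all relations are treated as symmetric,
unweighted associations (walks are uniform; node kinds influence nothing but
which edges exist); the known positives are trustworthy; the sampled
negatives are only *probably* negative — with $n_{pos}$ positives and
$n_{unk}$ unknown pairs, a uniformly sampled negative is an undiscovered
positive with probability about $n_{pos}/n_{unk}$ (the "false-negative
exposure" the package reports; about 1.9 % for a 575-positive,
474 × 64-combination inventory).

## Parameters that matter

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `walks_per_node`, `walk_length` | 10, 80 | walk corpus per node (nodes); the original DeepWalk settings |
| `window` (w) | 5 | skip-gram context radius (walk positions) |
| `dim` (k) | 20 | embedding size; 20 is the sweep optimum for the default XGBoost classifier; sweep grid 10–200 in steps of 10 |
| `epochs`, `alpha` | 5, 0.025 | training passes and initial learning rate (linear decay to `1e-4`) |
| circRNA similarity scheme | match +1, mismatch 0, no gap penalty, score ÷ shorter length | bounded in [0, 1]; the alignment scheme behind published pipelines is rarely stated, so every knob is an argument |
| circRNA edge cutoff | mean of all off-diagonal pair scores, strict `>` | "above the average of all pairs" with a strict inequality |
| disease edge cutoff | 0.8, strict `>` | the conventional Wang-similarity threshold for calling two diseases related |
| `delta` (Wang decay) | 0.5 | the customary semantic-contribution factor of the Wang measure |
| negative sampling | `n_neg = n_pos`, uniform without replacement, once per experiment | balanced benchmark; resampling once (not per fold) keeps the benchmark a single artifact |
| folds | 5, stratified by label | stratification removes fold-level class skew; plain shuffling is available (`stratified = FALSE`) |
| case-study negatives | ⌊n_neg/3⌋, uniform | training on fewer negatives limits learning from false negatives while keeping two classes |

## The synthetic fixture

`synth_config()` plants community structure shared by all four node kinds:
round-robin community assignment, Bernoulli(`p_within` = 0.3) edges inside a
community and Bernoulli(`p_between` = 0.02) across, for each of the four
mechanistic relations. Ground-truth positives are defined *mechanistically*:
a circRNA is associated with a disease exactly when both are in the same
community and share at least one miRNA — the same graph paths the embedding
is supposed to exploit. Sequences are per-community families (independent
uniform ancestors, per-base substitution at rate 0.05), so the
sequence-similarity edges reinforce the planted communities; the ontology is
a perfect tree (branching 3, depth 2) with same-community diseases routed
into the same depth-1 subtree.

Default sizes are 60 circRNAs, 40 miRNAs, 40 mRNAs and 10 diseases in three
communities, which yields a benchmark of roughly 270–310 pairs and lets the
full pipeline (network, walks, skip-gram, five-fold XGBoost) run in a few
seconds per seed; the shipped tests and the acceptance script use exactly
these sizes, with three seeds for the recovery estimate.

What the fixture does *not* emulate: real degree distributions (hub miRNAs,
heavily studied diseases), literature ascertainment bias, identifier noise,
expression levels, binding affinities, or sequence-determined miRNA response
elements. A high AUC on the fixture shows the pipeline recovers reachable
graph structure end-to-end; it does not certify performance on real
databases, whose signal-to-noise characteristics are different.

## Numerical and design choices

* **Skip-gram internals.** Training follows the word2vec formulation: the
  context word supplies the input vector and the center word's Huffman path
  the output; the full ±w window is used (matching the stated objective)
  rather than a randomly reduced window. The C++ core uses its own
  xorshift64* RNG stream seeded from the configuration, runs single-threaded,
  and is therefore bit-reproducible across runs and independent of R's
  global RNG state. Weights initialise uniform in ±0.5/k; the learning rate
  decays linearly per processed walk position.
* **Huffman coding** of the vocabulary follows the classic two-minimum merge
  on walk-corpus frequencies; a degenerate single-node vocabulary has an
  empty code (probability 1).
* **Walk starvation.** A node absent from every walk (isolated nodes) gets a
  zero vector plus a warning, and `connectivity_report()` flags isolated
  circRNA/disease nodes before embedding.
* **Ties and strictness.** Both similarity cutoffs are strict (`>`); when
  every pair score equals the mean, no circRNA–circRNA edge is retained.
  Ranked predictions break probability ties by circRNA id so output is
  byte-stable.
* **ROC/AUC.** The curve sweeps the threshold over distinct scores (tied
  scores collapse into one step), and trapezoidal integration then equals the
  concordance probability `P(score_pos > score_neg) + ½ P(tie)`; the test
  suite asserts this equivalence to 1e-12 against an O(n²) counting oracle.
* **Undefined metrics.** A metric with a zero denominator (e.g. precision
  with no positive calls) is reported as `NA` and flagged, never as 0.
* **F1 bookkeeping.** F1 is computed per fold from that fold's precision and
  recall via `2·Pre·Sen/(Pre+Sen)`, then averaged; the mean F1 therefore
  need not equal the F1 of the mean precision/recall — reports based on
  fold means can differ slightly in the second decimal.
* **Ontology parents** resolve by longest-proper-prefix on dot-separated
  tree numbers (the MeSH dialect); a term with several tree numbers gets the
  union of implied parents, and a disease attached to several terms scores
  as the maximum over term pairs — an interpretation, flagged as such, since
  multi-attachment conventions vary.
* **Determinism.** Fixture generation, walks, embeddings, negative sampling,
  folds and XGBoost training (nthread = 1) are reproducible bit-for-bit under
  a fixed seed. libsvm's internal Platt calibration is the one component
  whose randomness cannot be seeded from R; reproducibility is therefore
  guaranteed (and tested) for the XGBoost pipeline default.
* **Classifier hyperparameters** default to the underlying libraries'
  defaults (SVM: radial, C = 1; RF: 500 trees; ABRF: 10 AdaBoost rounds over
  50-tree forests; XGB: 100 rounds, depth 6, η 0.3; MP: one hidden layer of
  16 units, weight decay 5e-4). Any published non-default setting can be
  pinned through `classifier_spec(name, params = list(...))`.
* **Walk-corpus reuse.** The embedding-size sweep generates the walk corpus
  once per seed and retrains the skip-gram per size, so sweep differences
  reflect the embedding dimension only.

## Known limitations

* All-pairs sequence alignment is O(n²) dynamic programming; a `max_pairs`
  guard refuses accidental blow-ups and should be raised deliberately for
  large catalogues.
* The negative-sampling design measures ranking quality against *unknown*
  pairs, not verified negatives; reported specificity inherits that caveat.
* Uniform walks ignore edge semantics; metapath-constrained or biased
  (node2vec-style) walks are out of scope by design.
* Disease-name unification is table-driven (explicit synonym lists with
  case/whitespace folding), not fuzzy matching: reproducibility is preferred
  over recall of unlisted synonyms.
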