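# End-to-end pipeline over the synthetic fixture: build the seven-relation
# network, embed it, assemble the benchmark, and cross-validate.

#' Assemble the seven-relation heterogeneous network from a fixture
#'
#' Merges the five generated bipartite edge lists with the two derived
#' similarity edge sets (circRNA-circRNA above the mean alignment score,
#' disease-disease above 0.8 Wang similarity).
#'
#' @param config A [synth_config()].
#' @param fixture Optional pre-generated [generate_network_fixture()] output
#'   (regenerated from `config` when omitted).
#' @return List with the merged `net` (a `hetnet`), the `fixture`, the
#'   circRNA similarity network `circ_sim` and disease similarity network
#'   `dis_sim`.
#' @export
build_fixture_network <- function(config, fixture = NULL) {
  if (is.null(fixture)) fixture <- generate_network_fixture(config)
  seqs <- generate_sequence_fixture(config)
  ont <- generate_ontology_fixture(config)
  parts <- lapply(names(fixture$edges), function(rel) {
    bipartite_network(rel, fixture$edges[[rel]])
  })
  circ_sim <- mean_threshold_edges(pairwise_sequence_scores(seqs))
  dis <- fixture$nodes$id[fixture$nodes$kind == "disease"]
  dis_sim <- disease_similarity_edges(ont, dis)
  net <- merge_networks(c(parts, list(circ_sim, dis_sim)))
  list(net = net, fixture = fixture, circ_sim = circ_sim, dis_sim = dis_sim)
}

#' Run the full association-prediction pipeline on the synthetic fixture
#'
#' Generates the fixture, builds the seven-relation network, learns DeepWalk
#' embeddings, assembles the balanced benchmark (planted positives plus an
#' equal number of uniformly sampled unknown pairs), and evaluates a
#' classifier under stratified five-fold cross-validation.
#'
#' @param config A [synth_config()].
#' @param dim Embedding size k; default 20.
#' @param seed Pipeline seed (walks, negative sampling, folds, training).
#' @param spec Classifier; default XGB.
#' @param n_folds Number of CV folds; default 5.
#' @param walk_cfg Optional [walk_config()] override (its `dim` and `seed`
#'   are replaced by the `dim`/`seed` arguments).
#' @return List with `report` (a `metrics_report`), `benchmark`, `features`,
#'   `folds`, `emb`, `net`, and the `fixture`.
#' @export
run_fixture_pipeline <- function(config, dim = 20, seed = 1L,
                                 spec = classifier_spec("XGB"), n_folds = 5,
                                 walk_cfg = walk_config()) {
  built <- build_fixture_network(config)
  walk_cfg$dim <- as.integer(dim)
  walk_cfg$seed <- derive_seed(seed, 11L)
  walks <- generate_walks(built$net, walk_cfg)
  emb <- train_skipgram(walks, walk_cfg, nodes = built$net$nodes$id)
  benchmark <- build_benchmark(built$fixture$truth, seed = derive_seed(seed, 22L))
  features <- featurize_pairs(benchmark, emb)
  folds <- make_folds(benchmark, n_folds = n_folds, seed = derive_seed(seed, 33L))
  report <- cross_validate(features, benchmark$label, folds, spec, seed = seed)
  list(report = report, benchmark = benchmark, features = features,
       folds = folds, emb = emb, net = built$net, fixture = built$fixture)
}
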