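#' Configuration for the synthetic ceRNA fixture generator
#'
#' The generator plants community structure shared across all four node kinds:
#' nodes inside the same community are densely interconnected through
#' circRNA-miRNA, miRNA-mRNA, miRNA-disease and mRNA-disease relations, while
#' edges across communities are rare. Communities are the synthetic analogue of
#' disease mechanisms: a circRNA is truly associated with a disease exactly
#' when both sit in the same community and share at least one miRNA, which is
#' the miRNA-sponge path the ceRNA hypothesis exploits.
#'
#' @param n_circ,n_mirna,n_mrna,n_disease Number of nodes of each kind.
#' @param n_modules Number of planted communities.
#' @param p_within Bernoulli edge probability for node pairs in the same
#'   community.
#' @param p_between Edge probability across communities. Must be smaller than
#'   `p_within` for the planted structure to be recoverable.
#' @param seq_length Length (nt) of the simulated circRNA sequences.
#' @param seq_mutation_rate Per-base substitution probability applied to each
#'   circRNA's community ancestor sequence.
#' @param ontology_branching Children per ontology term.
#' @param ontology_depth Levels below the root of the ontology tree.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_circ = 60, n_mirna = 40, n_mrna = 40,
                         n_disease = 10, n_modules = 3,
                         p_within = 0.3, p_between = 0.02,
                         seq_length = 100, seq_mutation_rate = 0.05,
                         ontology_branching = 3, ontology_depth = 2,
                         seed = 1L) {
  for (nm in c("n_circ", "n_mirna", "n_mrna", "n_disease", "n_modules")) {
    assert_count(get(nm), nm)
  }
  assert_prob(p_within, "p_within")
  assert_prob(p_between, "p_between")
  if (p_within <= p_between) {
    stop("`p_within` must exceed `p_between` for recoverable planted structure",
         call. = FALSE)
  }
  assert_count(seq_length, "seq_length", min = 20L)
  assert_prob(seq_mutation_rate, "seq_mutation_rate")
  assert_count(ontology_branching, "ontology_branching")
  assert_count(ontology_depth, "ontology_depth", min = 2L)
  cfg <- list(
    n_circ = as.integer(n_circ), n_mirna = as.integer(n_mirna),
    n_mrna = as.integer(n_mrna), n_disease = as.integer(n_disease),
    n_modules = as.integer(n_modules),
    p_within = p_within, p_between = p_between,
    seq_length = as.integer(seq_length),
    seq_mutation_rate = seq_mutation_rate,
    ontology_branching = as.integer(ontology_branching),
    ontology_depth = as.integer(ontology_depth),
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

# Deterministic round-robin community assignment for every node kind.
fixture_nodes <- function(config) {
  make <- function(prefix, n, kind) {
    data.frame(
      id = sprintf("%s_%03d", prefix, seq_len(n)),
      kind = kind,
      community = ((seq_len(n) - 1L) %% config$n_modules) + 1L,
      stringsAsFactors = FALSE
    )
  }
  rbind(
    make("circ", config$n_circ, "circRNA"),
    make("mir", config$n_mirna, "miRNA"),
    make("mrna", config$n_mrna, "mRNA"),
    make("dis", config$n_disease, "disease")
  )
}

# Draw a Bernoulli bipartite edge set between two node tables, with
# within-community probability p_within and across-community p_between.
draw_bipartite <- function(a, b, p_within, p_between) {
  grid <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  same <- a$community[grid$i] == b$community[grid$j]
  p <- ifelse(same, p_within, p_between)
  keep <- stats::runif(nrow(grid)) < p
  data.frame(
    from = a$id[grid$i[keep]],
    to = b$id[grid$j[keep]],
    stringsAsFactors = FALSE
  )
}

# Analytic expectation of the number of planted circRNA-disease positives.
expected_positive_count <- function(config) {
  nodes <- fixture_nodes(config)
  per_comm <- function(kind) {
    tab <- table(factor(nodes$community[nodes$kind == kind],
                        levels = seq_len(config$n_modules)))
    as.numeric(tab)
  }
  n_circ_c <- per_comm("circRNA")
  n_dis_c <- per_comm("disease")
  n_mir_c <- per_comm("miRNA")
  n_mir_total <- sum(n_mir_c)
  p_w2 <- config$p_within^2
  p_b2 <- config$p_between^2
  # P(some miRNA links both a circRNA and a disease of community c)
  p_path <- 1 - (1 - p_w2)^n_mir_c * (1 - p_b2)^(n_mir_total - n_mir_c)
  sum(n_circ_c * n_dis_c * p_path)
}

#' Generate the bipartite edge-list fixture with planted associations
#'
#' Draws the four mechanistic relation sets (circRNA-miRNA, miRNA-mRNA,
#' miRNA-disease, mRNA-disease) as Bernoulli bipartite graphs with
#' within-community probability `p_within` and across-community `p_between`,
#' then defines the ground-truth circRNA-disease positives as the
#' same-community pairs connected through at least one shared miRNA (a
#' circRNA-miRNA edge plus a miRNA-disease edge). The positives double as the
#' known circRNA-disease edge list, giving five bipartite edge lists in total.
#'
#' @param config A [synth_config()].
#' @return A list with elements `edges` (named list of five two-column edge
#'   data frames), `truth` (the planted circRNA-disease positives),
#'   and `nodes` (id, kind, community).
#' @export
generate_network_fixture <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (expected_positive_count(config) < 10) {
    stop("configuration yields an expected positive count < 10; ",
         "benchmark would be unbuildable", call. = FALSE)
  }
  nodes <- fixture_nodes(config)
  by_kind <- split(nodes, nodes$kind)
  edges <- with_local_seed(config$seed, list(
    "circRNA-miRNA" = draw_bipartite(by_kind$circRNA, by_kind$miRNA,
                                     config$p_within, config$p_between),
    "miRNA-mRNA"    = draw_bipartite(by_kind$miRNA, by_kind$mRNA,
                                     config$p_within, config$p_between),
    "miRNA-disease" = draw_bipartite(by_kind$miRNA, by_kind$disease,
                                     config$p_within, config$p_between),
    "mRNA-disease"  = draw_bipartite(by_kind$mRNA, by_kind$disease,
                                     config$p_within, config$p_between)
  ))
  cm <- edges[["circRNA-miRNA"]]
  md <- edges[["miRNA-disease"]]
  # circ-disease pairs sharing >= 1 miRNA
  shared <- merge(cm, md, by.x = "to", by.y = "from")[, c("from", "to.y")]
  names(shared) <- c("from", "to")
  shared <- unique(shared)
  comm <- setNames(nodes$community, nodes$id)
  same <- comm[shared$from] == comm[shared$to]
  truth <- shared[same, , drop = FALSE]
  truth <- truth[order(truth$from, truth$to), , drop = FALSE]
  rownames(truth) <- NULL
  edges[["circRNA-disease"]] <- truth
  edges <- edges[c("circRNA-disease", "circRNA-miRNA", "miRNA-disease",
                   "miRNA-mRNA", "mRNA-disease")]
  list(edges = edges, truth = truth, nodes = nodes)
}

#' Generate circRNA sequences as mutated copies of community ancestors
#'
#' Each community receives an independent uniform-random ancestor sequence;
#' every circRNA's sequence is its community ancestor with per-base
#' substitutions at `seq_mutation_rate`. Same-community circRNAs are therefore
#' a sequence family, mirroring how paralogous circRNA families share high
#' alignment similarity.
#'
#' @param config A [synth_config()].
#' @return A named [Biostrings::DNAStringSet], one record per circRNA.
#' @export
generate_sequence_fixture <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nodes <- fixture_nodes(config)
  circ <- nodes[nodes$kind == "circRNA", ]
  bases <- c("A", "C", "G", "T")
  seqs <- with_local_seed(derive_seed(config$seed, 1L), {
    ancestors <- lapply(seq_len(config$n_modules), function(i) {
      sample(bases, config$seq_length, replace = TRUE)
    })
    vapply(seq_len(nrow(circ)), function(i) {
      s <- ancestors[[circ$community[i]]]
      mut <- stats::runif(config$seq_length) < config$seq_mutation_rate
      if (any(mut)) {
        s[mut] <- vapply(s[mut], function(b) sample(setdiff(bases, b), 1L), "")
      }
      paste(s, collapse = "")
    }, "")
  })
  Biostrings::DNAStringSet(setNames(seqs, circ$id))
}

#' Generate a MeSH-style ontology tree with diseases attached to leaves
#'
#' Builds a rooted tree with `ontology_branching` children per term and
#' `ontology_depth` levels below the root, encoded as tree numbers whose
#' longest proper prefix identifies the parent (the MeSH dialect). Each fixture
#' disease is attached to exactly one leaf; diseases from the same community
#' are routed into the same depth-1 subtree so that community co-membership is
#' visible to the Wang semantic similarity.
#'
#' @param config A [synth_config()].
#' @return An [ontology_dag()] with the fixture diseases attached.
#' @export
generate_ontology_fixture <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  b <- config$ontology_branching
  depth <- config$ontology_depth
  numbers <- "C"
  level <- list("C")
  for (d in seq_len(depth)) {
    level[[d + 1L]] <- unlist(lapply(level[[d]], function(p) {
      paste(p, seq_len(b), sep = ".")
    }))
    numbers <- c(numbers, level[[d + 1L]])
  }
  terms <- data.frame(
    term_id = sprintf("T%03d", seq_along(numbers)),
    tree_number = numbers,
    stringsAsFactors = FALSE
  )
  leaves <- terms$term_id[terms$tree_number %in% level[[depth + 1L]]]
  leaf_subtree <- as.integer(sub("^C\\.(\\d+).*$", "\\1",
                                 terms$tree_number[match(leaves, terms$term_id)]))
  nodes <- fixture_nodes(config)
  dis <- nodes[nodes$kind == "disease", ]
  attach_term <- character(nrow(dis))
  for (i in seq_len(nrow(dis))) {
    subtree <- ((dis$community[i] - 1L) %% b) + 1L
    pool <- leaves[leaf_subtree == subtree]
    idx <- ((sum(dis$community[seq_len(i)] == dis$community[i]) - 1L) %%
              length(pool)) + 1L
    attach_term[i] <- pool[idx]
  }
  attachment <- data.frame(disease_id = dis$id, term_id = attach_term,
                           stringsAsFactors = FALSE)
  ontology_dag(terms, attachment)
}

#' Write a complete fixture bundle to disk
#'
#' Emits the five bipartite edge lists and the ground truth as two-column TSV
#' files, the circRNA sequences as FASTA, the ontology as a
#' (term_id, tree_number) TSV and the disease attachment as a
#' (disease_id, term_id) TSV.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixture <- function(config, dir) {
  fix <- generate_network_fixture(config)
  seqs <- generate_sequence_fixture(config)
  ont <- generate_ontology_fixture(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (rel in names(fix$edges)) {
    p <- file.path(dir, paste0(gsub("-", "_", rel), ".tsv"))
    write_edge_tsv(fix$edges[[rel]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "ground_truth.tsv")
  write_edge_tsv(fix$truth, p)
  paths <- c(paths, p)
  p <- file.path(dir, "circ_sequences.fasta")
  Biostrings::writeXStringSet(seqs, p)
  paths <- c(paths, p)
  p <- file.path(dir, "ontology.tsv")
  write.table(ont$terms, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "disease_terms.tsv")
  write.table(ont$attachment, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
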