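# Identifier unification and assembly of the heterogeneous ceRNA network.

#' Construct an identifier map for unification
#'
#' Holds per-kind alias tables: a circRNA alias table (CircBase-style canonical
#' ids) and a disease synonym table. The mapping must be functional — an alias
#' naming two different canonicals is a hard error — and canonical ids map to
#' themselves. Disease aliases are compared after case-folding and whitespace
#' normalization.
#'
#' @param circ Optional data frame with columns `alias`, `canonical` for
#'   circRNA ids. When supplied, circRNAs without a canonical mapping are
#'   dropped during unification (mirroring restriction to a reference
#'   catalogue). `NULL` passes circRNA ids through unchanged.
#' @param disease Optional data frame with columns `alias`, `canonical` for
#'   disease-name synonyms.
#' @return An `identifier_map` object.
#' @export
identifier_map <- function(circ = NULL, disease = NULL) {
  build <- function(tab, fold) {
    if (is.null(tab)) return(NULL)
    stopifnot(all(c("alias", "canonical") %in% names(tab)))
    alias <- if (fold) normalize_name(tab$alias) else tab$alias
    canonical <- as.character(tab$canonical)
    # canonical ids always map to themselves
    alias <- c(alias, if (fold) normalize_name(canonical) else canonical)
    canonical <- c(canonical, canonical)
    dup <- !duplicated(alias)
    map <- setNames(canonical[dup], alias[dup])
    conflict <- tapply(canonical, alias, function(x) length(unique(x)) > 1)
    if (any(conflict)) {
      stop(sprintf("alias mapped to multiple canonical ids: %s",
                   paste(names(conflict)[conflict], collapse = ", ")),
           call. = FALSE)
    }
    map
  }
  structure(
    list(circRNA = build(circ, fold = FALSE),
         disease = build(disease, fold = TRUE)),
    class = "identifier_map"
  )
}

#' Create a bipartite relation network
#'
#' @param relation One of the seven relation labels (e.g. `"circRNA-miRNA"`).
#' @param edges Data frame whose first two columns are the endpoint ids, in
#'   the order the relation label declares. Self-loops and duplicate edges are
#'   removed; same-kind relations store each edge with sorted endpoints.
#' @return A `bipartite_network` object.
#' @export
bipartite_network <- function(relation, edges) {
  if (!relation %in% names(RELATION_KINDS)) {
    stop(sprintf("unknown relation '%s'", relation), call. = FALSE)
  }
  edges <- data.frame(from = as.character(edges[[1]]),
                      to = as.character(edges[[2]]),
                      stringsAsFactors = FALSE)
  kinds <- RELATION_KINDS[[relation]]
  if (kinds[1] == kinds[2]) {
    edges <- sort_pairs(edges$from, edges$to)
  }
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  edges <- unique(edges)
  rownames(edges) <- NULL
  structure(list(relation = relation, kinds = kinds, edges = edges),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %s: %d edges\n", x$relation, nrow(x$edges)))
  invisible(x)
}

#' Unify identifiers in a raw edge list
#'
#' Replaces aliases by canonical identifiers using an [identifier_map()].
#' When a circRNA alias table is present, records whose circRNA has no
#' canonical mapping are dropped and the drop count reported. Disease names
#' are matched after case-folding and whitespace normalization; names without
#' a synonym entry are kept as-is (normalized).
#'
#' @param raw_edges Data frame with two id columns, ordered as the relation
#'   label declares.
#' @param id_map An [identifier_map()].
#' @param relation The relation label of the records.
#' @return A [bipartite_network()] with attribute `dropped` (records removed
#'   for lacking a canonical circRNA id).
#' @export
unify_identifiers <- function(raw_edges, id_map, relation) {
  stopifnot(inherits(id_map, "identifier_map"))
  if (!relation %in% names(RELATION_KINDS)) {
    stop(sprintf("unknown relation '%s'", relation), call. = FALSE)
  }
  kinds <- RELATION_KINDS[[relation]]
  ids <- list(as.character(raw_edges[[1]]), as.character(raw_edges[[2]]))
  keep <- rep(TRUE, length(ids[[1]]))
  for (side in 1:2) {
    kind <- kinds[side]
    if (kind == "disease") {
      x <- normalize_name(ids[[side]])
      if (!is.null(id_map$disease)) {
        hit <- x %in% names(id_map$disease)
        x[hit] <- unname(id_map$disease[x[hit]])
      }
      ids[[side]] <- x
    } else if (kind == "circRNA" && !is.null(id_map$circRNA)) {
      x <- ids[[side]]
      hit <- x %in% names(id_map$circRNA)
      keep <- keep & hit
      x[hit] <- unname(id_map$circRNA[x[hit]])
      ids[[side]] <- x
    }
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("unify_identifiers: dropped %d record(s) with unmapped circRNA ids",
                    n_dropped))
  }
  net <- bipartite_network(relation,
                           data.frame(from = ids[[1]][keep], to = ids[[2]][keep],
                                      stringsAsFactors = FALSE))
  attr(net, "dropped") <- n_dropped
  net
}

#' Merge bipartite relation networks into one heterogeneous network
#'
#' Nodes are the union of all endpoints, typed by the relation each part
#' declares; edges are the union of all part edges with duplicates collapsed.
#' An identifier carrying two different kinds across parts is a hard error.
#' The result is an undirected, unweighted graph.
#'
#' @param parts List of [bipartite_network()] objects.
#' @return A `hetnet` object: `nodes` (id, kind), `edges`
#'   (from, to, relation), and adjacency access via [hetnet_adjacency()].
#' @export
merge_networks <- function(parts) {
  stopifnot(length(parts) >= 1, all(vapply(parts, inherits, TRUE, "bipartite_network")))
  node_tabs <- lapply(parts, function(p) {
    rbind(data.frame(id = p$edges$from, kind = p$kinds[1], stringsAsFactors = FALSE),
          data.frame(id = p$edges$to, kind = p$kinds[2], stringsAsFactors = FALSE))
  })
  nodes <- unique(do.call(rbind, node_tabs))
  conflict <- nodes$id[duplicated(nodes$id)]
  if (length(conflict) > 0) {
    stop(sprintf("id(s) assigned more than one node kind: %s",
                 paste(unique(conflict), collapse = ", ")), call. = FALSE)
  }
  edge_tabs <- lapply(parts, function(p) {
    if (nrow(p$edges) == 0) return(NULL)
    e <- sort_pairs(p$edges$from, p$edges$to)
    e$relation <- p$relation
    e
  })
  edges <- do.call(rbind, edge_tabs)
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  # collapse the same unordered pair appearing in several parts
  edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
  nodes <- nodes[order(nodes$id), ]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "hetnet")
}

#' @export
print.hetnet <- function(x, ...) {
  cat(sprintf("<hetnet> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  kt <- table(x$nodes$kind)
  cat("  nodes:", paste(sprintf("%s=%d", names(kt), kt), collapse = ", "), "\n")
  rt <- table(x$edges$relation)
  cat("  edges:", paste(sprintf("%s=%d", names(rt), rt), collapse = ", "), "\n")
  invisible(x)
}

#' Adjacency list of a heterogeneous network
#'
#' @param net A `hetnet`.
#' @return Named list mapping each node id to the sorted character vector of
#'   its neighbours (empty for isolated nodes).
#' @export
hetnet_adjacency <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  adj <- lapply(setNames(vector("list", nrow(net$nodes)), net$nodes$id),
                function(x) character(0))
  if (nrow(net$edges) > 0) {
    half <- split(net$edges$to, net$edges$from)
    other <- split(net$edges$from, net$edges$to)
    for (v in names(half)) adj[[v]] <- c(adj[[v]], half[[v]])
    for (v in names(other)) adj[[v]] <- c(adj[[v]], other[[v]])
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  adj
}

#' Convert a heterogeneous network to an igraph graph
#'
#' @param net A `hetnet`.
#' @return An undirected [igraph::graph] with vertex attribute `kind` and edge
#'   attribute `relation`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = net$nodes)
  igraph::E(g)$relation <- net$edges$relation
  g
}

#' Connected components and isolated-node report
#'
#' Isolated circRNA or disease nodes are flagged because random walks starting
#' there terminate immediately, leaving their embeddings untrained
#' (walk-starved).
#'
#' @param net A `hetnet`.
#' @return List with `n_components`, `component_sizes`, `membership` (named
#'   integer vector), and `isolated` (ids of degree-0 circRNA/disease nodes).
#' @export
connectivity_report <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  g <- as_igraph(net)
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  iso <- names(deg)[deg == 0]
  kind <- setNames(net$nodes$kind, net$nodes$id)
  iso <- iso[kind[iso] %in% c("circRNA", "disease")]
  list(
    n_components = comp$no,
    component_sizes = sort(as.integer(comp$csize), decreasing = TRUE),
    membership = comp$membership,
    isolated = iso
  )
}

#' Read a merged network written by [write_hetnet()]
#'
#' @param dir Directory containing `edges.tsv` and `nodes.tsv`.
#' @return A `hetnet`.
#' @export
read_hetnet <- function(dir) {
  nodes <- read.delim(file.path(dir, "nodes.tsv"), stringsAsFactors = FALSE)
  edges <- read.delim(file.path(dir, "edges.tsv"), stringsAsFactors = FALSE)
  stopifnot(all(c("id", "kind") %in% names(nodes)),
            all(c("from", "to", "relation") %in% names(edges)))
  structure(list(nodes = nodes, edges = edges), class = "hetnet")
}

#' Write a merged network to disk
#'
#' @param net A `hetnet`.
#' @param dir Output directory.
#' @return Invisibly, the paths written (edge list TSV plus node-kind sidecar).
#' @export
write_hetnet <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ep <- file.path(dir, "edges.tsv")
  np <- file.path(dir, "nodes.tsv")
  write.table(net$edges, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(net$nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ep, np))
}
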