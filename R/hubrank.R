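# Hub-gene ranking within a co-expression module: connectivity in the
# score-filtered protein-interaction subgraph, with annotation-term membership
# as tie-break (the logic that singled out MYD88 in the motivating study).

#' Induced protein-interaction subgraph of a module
#'
#' Nodes are exactly the module genes (genes absent from the edge list are
#' kept as isolates with degree 0); edges are those with both endpoints in the
#' module. The edge list should already be score-filtered (see
#' [read_edges()]).
#'
#' @param edges data.frame with node_a, node_b (and score).
#' @param genes Character vector of module genes.
#' @return An igraph undirected graph over `genes`.
#' @export
induced_subgraph <- function(edges, genes) {
  genes <- unique(genes)
  keep <- edges$node_a %in% genes & edges$node_b %in% genes
  el <- edges[keep, c("node_a", "node_b"), drop = FALSE]
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = genes))
}

#' Count annotation terms containing each gene
#'
#' @param gene_sets Named list of gene sets (GO + KEGG collections combined as
#'   desired).
#' @param genes Character vector of genes to count for.
#' @return Named integer vector gene -> number of sets containing it.
#' @export
count_terms <- function(gene_sets, genes) {
  members <- unlist(lapply(gene_sets, unique), use.names = FALSE)
  tab <- table(factor(members, levels = unique(genes)))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[genes]
}

#' Rank module genes by connectivity, then term membership
#'
#' Sorts by degree in the induced subgraph (descending), annotation-term count
#' (descending), then gene id (ascending) as a deterministic tie-break.
#'
#' @param graph igraph graph from [induced_subgraph()].
#' @param term_counts Named integer vector gene -> term count; genes missing
#'   from it count 0.
#' @return data.frame: gene_id, degree, term_count, rank (1 = top hub).
#' @export
rank_hubs <- function(graph, term_counts = integer(0)) {
  genes <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  tc <- term_counts[genes]
  tc[is.na(tc)] <- 0L
  ord <- order(-deg, -tc, genes)
  out <- data.frame(gene_id = genes[ord], degree = as.integer(deg[ord]),
                    term_count = as.integer(tc[ord]),
                    rank = seq_along(genes), row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}
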