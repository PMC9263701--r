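# shared fixture builders -------------------------------------------------

random_otu <- function(n_samples = 5, n_taxa = 8, lambda = 20,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("t", seq_len(n_taxa))))
  otu_table(m)
}

toy_taxonomy <- function(taxon_ids, phyla = NULL) {
  n <- length(taxon_ids)
  if (is.null(phyla)) phyla <- rep("PhylumA", n)
  taxonomy_table(taxon_ids, kingdom = rep("Bacteria", n), phylum = phyla,
                 class = rep("unclassified", n),
                 order = rep("unclassified", n), family = taxon_ids,
                 genus = rep("unclassified", n))
}

# small undirected graph from an edge list matrix (2 columns of ints)
graph_from_pairs <- function(pairs, n_nodes) {
  g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
  if (nrow(pairs)) g <- igraph::add_edges(g, t(pairs))
  igraph::set_vertex_attr(g, "name", value = paste0("v", seq_len(n_nodes)))
}

random_small_graph <- function(n_max = 7) {
  n <- sample(2:n_max, 1)
  all_pairs <- t(combn(n, 2))
  m <- sample(0:nrow(all_pairs), 1)
  pairs <- all_pairs[sample(nrow(all_pairs), m), , drop = FALSE]
  graph_from_pairs(pairs, n)
}
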