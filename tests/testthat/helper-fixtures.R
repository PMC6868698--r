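# small hand-built fixtures shared across test files

toy_assoc <- function(values, n_diseases = nrow(values), n_drugs = ncol(values)) {
  association_matrix(values,
                     disease_ids = sprintf("e%d", seq_len(n_diseases)),
                     drug_ids = sprintf("r%d", seq_len(n_drugs)))
}

random_assoc <- function(n_diseases, n_drugs, density = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n_diseases * n_drugs, 1, density), n_diseases, n_drugs)
  toy_assoc(m)
}

toy_sim <- function(values, ids = sprintf("x%d", seq_len(nrow(values)))) {
  similarity_matrix(values, entity_ids = ids)
}

# unit-weight graph from an edge list given as a 2-column matrix of names
toy_graph <- function(edges, weights = rep(1, nrow(edges))) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- weights
  g
}
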