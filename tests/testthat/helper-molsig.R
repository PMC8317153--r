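# Shared test helpers: an independent Floyd-Warshall oracle, random
# connected graphs wrapped as minimal molsig_graph stubs, and a cached
# synthetic dataset so expensive fixtures are built once per test run.

# Independent all-pairs shortest-path oracle (triple loop, no BFS).
floyd_warshall <- function(n, edges) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    d[edges[r, 1], edges[r, 2]] <- 1
    d[edges[r, 2], edges[r, 1]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# random connected graph on n nodes: spanning tree + extra edges
random_connected_graph <- function(n, extra = 2) {
  edges <- cbind(2:n, vapply(2:n, function(v) sample(v - 1, 1), integer(1)))
  for (e in seq_len(extra)) {
    cand <- sort(sample(n, 2))
    edges <- rbind(edges, cand)
  }
  edges <- unique(t(apply(edges, 1, sort)))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  edges
}

# wrap an abstract graph as the minimal object shortest_path_matrix() needs
as_graph_stub <- function(n, edges) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  structure(list(mol_id = "stub", graph = g), class = "molsig_graph")
}

# cached synthetic study dataset (molecules + labels + features), built once
.molsig_test_cache <- new.env(parent = emptyenv())

synthetic_study <- function(n = 1000, seed = 42) {
  key <- sprintf("study_%d_%d", n, seed)
  if (is.null(.molsig_test_cache[[key]])) {
    cfg <- generator_config(n_molecules = n, seed = seed)
    mols <- generate_molecules(cfg)
    lab <- generate_labels(mols, cfg)
    feats <- suppressWarnings(featurize_batch(mols[, c("smiles", "mol_id")]))
    .molsig_test_cache[[key]] <- list(config = cfg, molecules = mols,
                                      labels = lab$labels, gi50 = lab$gi50,
                                      records = lab$activity_records,
                                      features = feats)
  }
  .molsig_test_cache[[key]]
}
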