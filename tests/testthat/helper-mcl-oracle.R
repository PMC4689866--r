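# Independent reference Markov Clustering, used only as an oracle.
#
# Deliberately a different code path and interpretation rule than
# run_mcl(): no pruning during iteration, and clusters are read off the
# limit matrix as weakly connected components of its nonzero pattern (the
# canonical limit-matrix interpretation), rather than attractor-row
# supports with lowest-id overlap resolution.
mcl_reference <- function(adj, inflation, expansion = 2, loop = 1,
                          tol = 1e-8, max_iter = 500) {
  diag(adj) <- loop
  M <- t(t(adj) / colSums(adj))
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (i in seq_len(expansion - 1)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf <- t(t(Minf) / colSums(Minf))
    done <- max(abs(Minf - M)) < tol
    M <- Minf
    if (done) break
  }
  M[M < 1e-7] <- 0
  g <- igraph::graph_from_adjacency_matrix((M > 0) + (t(M) > 0) > 0,
                                           mode = "undirected")
  membership <- igraph::components(g)$membership
  names(membership) <- rownames(adj)
  membership
}

# random weighted graph as a signed_network plus its adjacency matrix
random_weighted_graph <- function(n, p = 0.15) {
  g <- igraph::sample_gnp(n, p = p)
  el <- igraph::as_edgelist(g)
  ids <- sprintf("n%02d", seq_len(n))
  edges <- data.frame(gene_a = ids[el[, 1]], gene_b = ids[el[, 2]],
                      r = stats::runif(nrow(el), 0.5, 1),
                      stringsAsFactors = FALSE)
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(el)) {
    adj[cbind(el[, 1], el[, 2])] <- edges$r
    adj <- pmax(adj, t(adj))
  }
  list(network = make_network(edges, cutoff = 0.4, nodes = ids), adj = adj)
}
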