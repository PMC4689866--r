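# Small builders used across test files.

# signed network from an edge data.frame (gene_a, gene_b, r)
make_network <- function(edges, cutoff = 0.85, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff),
            class = "signed_network")
}

# correlation matrix object from a full symmetric matrix
make_corr <- function(r, n_samples = 10L) {
  structure(list(r = r, gene_ids = rownames(r), n_samples = n_samples),
            class = "correlation_matrix")
}

# mutual rank matrix object from a full symmetric matrix
make_mr <- function(mr) {
  structure(list(mr = mr, gene_ids = rownames(mr)),
            class = "mutual_rank_matrix")
}

# expression matrix with a one-condition design
make_expr <- function(values, conditions = NULL) {
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  }
  if (is.null(conditions)) conditions <- rep("c1", ncol(values))
  design <- data.frame(sample = colnames(values), condition = conditions,
                       replicate = stats::ave(seq_along(conditions),
                                              conditions, FUN = seq_along))
  expr_matrix(values, design)
}

# edges of a clique over the given gene ids
clique_edges <- function(ids, r = 0.9) {
  pairs <- t(utils::combn(ids, 2))
  data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2], r = r,
             stringsAsFactors = FALSE)
}

# adversarial 4-gene fixture: guide g, a passes both thresholds, b fails MR,
# c fails PCC; chain d behind a tests depth accounting
make_guide_fixture <- function() {
  ids <- c("a", "b", "c", "d", "g")
  r <- matrix(0.1, 5, 5, dimnames = list(ids, ids))
  diag(r) <- 1
  r["g", "a"] <- r["a", "g"] <- 0.70  # qualifies
  r["g", "b"] <- r["b", "g"] <- 0.90  # high r but MR forced over threshold
  r["g", "c"] <- r["c", "g"] <- 0.55  # below pcc_min
  r["a", "d"] <- r["d", "a"] <- 0.80  # second hop
  mr <- matrix(50, 5, 5, dimnames = list(ids, ids))
  diag(mr) <- NA
  mr["g", "a"] <- mr["a", "g"] <- 3
  mr["g", "b"] <- mr["b", "g"] <- 6   # MR over threshold
  mr["g", "c"] <- mr["c", "g"] <- 2
  mr["a", "d"] <- mr["d", "a"] <- 4
  list(corr = make_corr(r), mr = make_mr(mr))
}

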