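#' All-vs-all Pearson correlation between gene profiles
#'
#' Computes the sample Pearson correlation coefficient (PCC, r) for every
#' gene pair on the log2 expression matrix. Genes with zero variance across
#' samples carry no correlation signal and are excluded beforehand (their
#' ids are reported via a message).
#'
#' @param matrix An [expr_matrix()] with at least 3 samples.
#' @return A `correlation_matrix`: list with `r` (symmetric, unit diagonal),
#'   `gene_ids`, `n_samples`.
#' @export
pearson_all_pairs <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (ncol(matrix$values) < 3) stop("need >= 3 samples for correlation")
  v <- apply(matrix$values, 1, stats::var)
  degenerate <- names(v)[v == 0]
  if (length(degenerate)) {
    message(length(degenerate), " zero-variance genes excluded: ",
            paste(utils::head(degenerate, 5), collapse = ", "))
  }
  vals <- matrix$values[v > 0, , drop = FALSE]
  r <- stats::cor(t(vals))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(r = r, gene_ids = rownames(vals),
                 n_samples = ncol(vals)),
            class = "correlation_matrix")
}

#' Build the signed co-expression network at a correlation cutoff
#'
#' Retains the edge (a, b) iff `|r(a,b)| > cutoff` (strict, following the
#' "PCC magnitude > 0.85" convention; set `strict = FALSE` for `>=`). The
#' signed r value is kept on the edge; nodes are genes with at least one
#' retained edge.
#'
#' @param corr A `correlation_matrix`.
#' @param cutoff Absolute-correlation threshold in (0, 1).
#' @param strict Use strict inequality (default) or `>=`.
#' @return A `signed_network`: list with `nodes`, `edges` (data.frame
#'   `gene_a`, `gene_b`, `r`), `cutoff`.
#' @export
build_network <- function(corr, cutoff, strict = TRUE) {
  stopifnot(inherits(corr, "correlation_matrix"),
            cutoff > 0, cutoff < 1)
  r <- corr$r
  keep <- if (strict) abs(r) > cutoff else abs(r) >= cutoff
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    gene_a = corr$gene_ids[idx[, 1]],
    gene_b = corr$gene_ids[idx[, 2]],
    r = r[idx],
    stringsAsFactors = FALSE
  )
  swap <- edges$gene_a > edges$gene_b
  if (any(swap)) {
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
  }
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 edges = edges, cutoff = cutoff),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network: %d nodes, %d edges (|r| > %.2f; %d negative)\n",
              length(x$nodes), nrow(x$edges), x$cutoff,
              sum(x$edges$r < 0)))
  invisible(x)
}

#' Convert a signed network to an igraph object
#'
#' Edge attribute `r` carries the signed correlation; `weight` its absolute
#' value.
#'
#' @param network A `signed_network`.
#' @return An undirected igraph graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "signed_network"))
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  igraph::E(g)$weight <- abs(igraph::E(g)$r)
  g
}

#' Node degrees of a signed network
#'
#' @param network A `signed_network`.
#' @return Named integer vector of degrees over `network$nodes`.
#' @export
node_degrees <- function(network) {
  tab <- table(c(network$edges$gene_a, network$edges$gene_b))
  deg <- stats::setNames(rep(0L, length(network$nodes)), network$nodes)
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Threshold sweep diagnostics for cutoff selection
#'
#' For each cutoff: node count, edge count, network density
#' `2E / (N (N - 1))` (0 when N < 2) and the scale-free fit R-squared,
#' used to pick a stringent but not edge-starving correlation threshold.
#'
#' @param corr A `correlation_matrix`.
#' @param cutoffs Strictly increasing vector of thresholds.
#' @param strict Passed to [build_network()].
#' @return data.frame `cutoff`, `n_nodes`, `n_edges`, `density`,
#'   `scale_free_r2` (NA where undefined).
#' @export
sweep_thresholds <- function(corr, cutoffs = seq(0.5, 0.95, by = 0.05),
                             strict = TRUE) {
  stopifnot(all(diff(cutoffs) > 0))
  rows <- lapply(cutoffs, function(ct) {
    net <- build_network(corr, ct, strict = strict)
    n <- length(net$nodes)
    e <- nrow(net$edges)
    data.frame(cutoff = ct, n_nodes = n, n_edges = e,
               density = if (n < 2) 0 else 2 * e / (n * (n - 1)),
               scale_free_r2 = scale_free_fit(net))
  })
  do.call(rbind, rows)
}

#' Scale-free topology fit of the degree distribution
#'
#' Ordinary least squares of `log10(frequency of degree k)` on `log10(k)`
#' over the observed degrees k >= 1; the returned R-squared measures how
#' well the degree distribution follows a power law.
#'
#' @param network A `signed_network`.
#' @return R-squared in \[0, 1\], or `NA` when fewer than 3 distinct
#'   positive degrees are observed.
#' @export
scale_free_fit <- function(network) {
  deg <- node_degrees(network)
  deg <- deg[deg >= 1]
  tab <- table(deg)
  if (length(tab) < 3) return(NA_real_)
  k <- as.numeric(names(tab))
  freq <- as.numeric(tab)
  fit <- stats::lm(log10(freq) ~ log10(k))
  # summary.lm warns on an exactly perfect fit; R^2 = 1 is a valid answer
  suppressWarnings(summary(fit)$r.squared)
}

#' Mutual rank matrix of a correlation matrix
#'
#' For a pair (a, b): `rank_a(b)` is the rank of b among all genes other
#' than a, ordered by decreasing r(a, .) with ties broken by gene-id order
#' (best = 1). The mutual rank is the geometric mean
#' `MR(a,b) = sqrt(rank_a(b) * rank_b(a))`; small MR means robustly mutual
#' co-expression.
#'
#' @param corr A `correlation_matrix` over at least 3 genes.
#' @return A `mutual_rank_matrix`: list with `mr` (symmetric, entries >= 1,
#'   diagonal NA) and `gene_ids`.
#' @export
mutual_ranks <- function(corr) {
  stopifnot(inherits(corr, "correlation_matrix"))
  n <- length(corr$gene_ids)
  if (n < 3) stop("need >= 3 genes for mutual ranks")
  rk <- matrix(NA_real_, n, n,
               dimnames = list(corr$gene_ids, corr$gene_ids))
  for (a in seq_len(n)) {
    others <- setdiff(seq_len(n), a)
    ord <- others[order(-corr$r[a, others], corr$gene_ids[others])]
    rk[a, ord] <- seq_along(ord)
  }
  mr <- sqrt(rk * t(rk))
  structure(list(mr = mr, gene_ids = corr$gene_ids),
            class = "mutual_rank_matrix")
}

#' Write a signed network's edge list and GraphML
#'
#' Edge list TSV has columns `gene_a`, `gene_b`, `r`, `sign`; the GraphML
#' export carries the same attributes for external viewers.
#'
#' @param network A `signed_network`.
#' @param edge_path TSV path, or `NULL` to skip.
#' @param graphml_path GraphML path, or `NULL` to skip.
#' @return Invisibly, the network.
#' @export
write_network <- function(network, edge_path = NULL, graphml_path = NULL) {
  if (!is.null(edge_path)) {
    out <- network$edges
    out$sign <- ifelse(out$r >= 0, "+", "-")
    write_tsv(out, edge_path)
  }
  if (!is.null(graphml_path)) {
    g <- as_igraph(network)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(network)
}
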