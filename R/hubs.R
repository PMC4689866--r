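#' Degree-based hub genes of a signed network
#'
#' Hubs are nodes whose degree (count of unique neighbours) reaches
#' `min_hub_degree`. For each hub the edge signs are split and the mean
#' absolute correlation is reported per sign.
#'
#' @param network A `signed_network`.
#' @param min_hub_degree Minimum degree to call a hub (default 5).
#' @param partition Optional `module_partition`; adds a `module` column.
#' @return data.frame `gene`, `degree`, `positive_edges`, `negative_edges`,
#'   `mean_abs_r_positive`, `mean_abs_r_negative`, (`module`), sorted by
#'   decreasing degree then gene id.
#' @export
find_hubs <- function(network, min_hub_degree = 5L, partition = NULL) {
  deg <- node_degrees(network)
  hubs <- names(deg)[deg >= min_hub_degree]
  rows <- lapply(hubs, function(g) {
    e <- network$edges[network$edges$gene_a == g |
                         network$edges$gene_b == g, , drop = FALSE]
    pos <- e$r[e$r >= 0]
    neg <- e$r[e$r < 0]
    data.frame(gene = g,
               degree = nrow(e),
               positive_edges = length(pos),
               negative_edges = length(neg),
               mean_abs_r_positive = if (length(pos)) mean(abs(pos)) else NA_real_,
               mean_abs_r_negative = if (length(neg)) mean(abs(neg)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), degree = integer(0),
                      positive_edges = integer(0),
                      negative_edges = integer(0),
                      mean_abs_r_positive = numeric(0),
                      mean_abs_r_negative = numeric(0))
  }
  if (!is.null(partition) && nrow(out)) {
    labs <- partition_labels(partition, include_unassigned = FALSE)
    out$module <- ifelse(out$gene %in% names(labs), labs[out$gene],
                         "unassigned")
  }
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ego subnetwork of a gene
#'
#' Induced subgraph on a gene and its first neighbours; edge signs are
#' preserved. Used to inspect a hub's immediate co-expression context.
#'
#' @param network A `signed_network`.
#' @param gene A node of the network.
#' @return A `signed_network` restricted to the ego set.
#' @export
ego_subnetwork <- function(network, gene) {
  if (!gene %in% network$nodes) stop("gene not in network: ", gene)
  e <- network$edges
  nbr <- unique(c(e$gene_b[e$gene_a == gene], e$gene_a[e$gene_b == gene]))
  keep_nodes <- sort(unique(c(gene, nbr)))
  sub <- e[e$gene_a %in% keep_nodes & e$gene_b %in% keep_nodes, ,
           drop = FALSE]
  rownames(sub) <- NULL
  structure(list(nodes = keep_nodes, edges = sub, cutoff = network$cutoff),
            class = "signed_network")
}
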