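#' Parameters for Markov Clustering
#'
#' MCL alternates expansion (a matrix power, spreading random-walk flow)
#' and inflation (an entrywise power followed by column renormalisation,
#' sharpening flow) on a column-stochastic matrix until the flow matrix
#' converges; clusters are read off the limit matrix. The inflation value
#' `I > 1` controls granularity: larger I gives more, smaller clusters.
#'
#' @param inflation Inflation exponent I (> 1).
#' @param expansion Expansion power (integer >= 2, default 2).
#' @param self_loop_weight Weight of the self-loop added to every node
#'   (canonical MCL practice; stabilises flow on bipartite-ish structure).
#' @param prune_threshold Entries below this are zeroed after each
#'   inflation step (sparsity control).
#' @param max_iterations Iteration cap; non-convergence is flagged, not an
#'   error.
#' @param convergence_tol Max column-wise change declaring convergence.
#' @param min_cluster_size Clusters smaller than this are moved to the
#'   unassigned set (clusters under 3 genes are typically biologically
#'   meaningless).
#' @return An `mcl_params` list.
#' @export
mcl_params <- function(inflation = 1.4, expansion = 2L,
                       self_loop_weight = 1.0, prune_threshold = 1e-6,
                       max_iterations = 200L, convergence_tol = 1e-8,
                       min_cluster_size = 3L) {
  stopifnot(inflation > 1, expansion >= 2, min_cluster_size >= 1,
            self_loop_weight >= 0, prune_threshold >= 0,
            max_iterations >= 1, convergence_tol > 0)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 self_loop_weight = self_loop_weight,
                 prune_threshold = prune_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "mcl_params")
}

#' Run Markov Clustering on a signed network
#'
#' The |r|-weighted adjacency (signs dropped: MCL needs non-negative flow)
#' with self-loops is column-normalised to a stochastic matrix and iterated
#' through expansion / inflation / pruning until convergence. Attractors
#' are rows with positive diagonal mass in the limit matrix; each node is
#' assigned to the lowest-indexed attractor whose row supports it. Clusters
#' below `min_cluster_size` are moved to `unassigned`.
#'
#' @param network A non-empty `signed_network`.
#' @param params An [mcl_params()].
#' @return A `module_partition`: list with `modules` (named list of gene
#'   vectors, labels `M01`, `M02`, ... in decreasing size order),
#'   `unassigned`, `inflation_used`, `modularity` (Newman-Girvan Q with
#'   unassigned genes as singletons), `converged`, `n_iterations`.
#' @export
run_mcl <- function(network, params = mcl_params()) {
  stopifnot(inherits(network, "signed_network"),
            inherits(params, "mcl_params"))
  nodes <- network$nodes
  n <- length(nodes)
  if (n == 0) stop("empty network")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(network$edges)) {
    ia <- match(network$edges$gene_a, nodes)
    ib <- match(network$edges$gene_b, nodes)
    w <- abs(network$edges$r)
    A[cbind(ia, ib)] <- w
    A[cbind(ib, ia)] <- w
  }
  diag(A) <- params$self_loop_weight
  M <- sweep(A, 2, colSums(A), "/")

  expand <- function(M, p) {
    out <- M
    for (i in seq_len(p - 1)) out <- out %*% M
    out
  }
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    M2 <- expand(M, params$expansion)
    M2 <- M2 ^ params$inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < params$prune_threshold] <- 0
    cs <- colSums(M2)
    if (any(cs == 0)) {
      # a fully pruned column gets its self-loop back
      empty <- which(cs == 0)
      M2[cbind(empty, empty)] <- 1
      cs[empty] <- 1
    }
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", params$max_iterations,
            " iterations; interpreting the current flow matrix")
  }

  attractors <- which(diag(M) > 0)
  if (length(attractors) == 0) attractors <- seq_len(n)
  cluster_of <- integer(n)
  for (a in attractors) {
    support <- which(M[a, ] > 0)
    fresh <- support[cluster_of[support] == 0L]
    cluster_of[fresh] <- a
  }
  orphan <- which(cluster_of == 0L)
  for (j in orphan) {
    rows <- which(M[, j] > 0)
    cluster_of[j] <- if (length(rows)) min(rows) else j
  }

  groups <- split(nodes, cluster_of)
  sizes <- lengths(groups)
  retained <- groups[sizes >= params$min_cluster_size]
  unassigned <- sort(unlist(groups[sizes < params$min_cluster_size],
                            use.names = FALSE))
  if (is.null(unassigned)) unassigned <- character(0)
  # deterministic labels: decreasing size, then first gene id
  ord <- order(-lengths(retained),
               vapply(retained, function(g) sort(g)[1], character(1)))
  retained <- lapply(retained[ord], sort)
  names(retained) <- sprintf("M%02d", seq_along(retained))

  partition <- structure(list(modules = retained,
                              unassigned = unassigned,
                              inflation_used = params$inflation,
                              modularity = NA_real_,
                              converged = converged,
                              n_iterations = iter),
                         class = "module_partition")
  partition$modularity <- modularity_score(network, partition)
  partition
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf(
    "module_partition: %d modules (sizes %s), %d unassigned, I = %.2f, Q = %s\n",
    length(x$modules), paste(lengths(x$modules), collapse = "/"),
    length(x$unassigned), x$inflation_used,
    ifelse(is.na(x$modularity), "NA", sprintf("%.3f", x$modularity))))
  invisible(x)
}

#' Newman-Girvan modularity of a partition
#'
#' Q on the unweighted simple graph, with unassigned genes treated as
#' singleton communities: `Q = sum_c (e_c/m - (d_c/2m)^2)`.
#'
#' @param network A `signed_network`.
#' @param partition A `module_partition` covering the network's nodes.
#' @return Q, or `NA` for an empty edge set.
#' @export
modularity_score <- function(network, partition) {
  if (nrow(network$edges) == 0) return(NA_real_)
  labs <- partition_labels(partition, include_unassigned = TRUE)
  missing <- setdiff(network$nodes, names(labs))
  if (length(missing)) {
    labs <- c(labs, stats::setNames(paste0("u", missing), missing))
  }
  g <- as_igraph(network)
  membership <- as.integer(factor(labs[igraph::V(g)$name]))
  igraph::modularity(g, membership)
}

#' Inflation sweep scored by GO-enrichment F-measure
#'
#' Runs MCL at each inflation value, scores every partition by the
#' specificity / sensitivity / F-measure of its annotation enrichment
#' ([cluster_quality()]), and returns the partition with the highest F
#' (ties broken toward the smallest inflation). Partitions with fewer than
#' two retained modules are unusable for the sweep and score F = 0.
#'
#' @param network A `signed_network`.
#' @param annotations A non-empty [annotation_map()].
#' @param inflation_values Inflation grid (default 1.1 to 3.0 by 0.1).
#' @param params Base [mcl_params()]; its inflation is overridden per grid
#'   point.
#' @param fdr_threshold FDR cutoff for calling a term enriched.
#' @return List with `best` (the argmax-F `module_partition`), `table`
#'   (data.frame per inflation: `inflation`, `n_modules`, `n_unassigned`,
#'   `specificity`, `sensitivity`, `f_measure`, `modularity`), and
#'   `partitions` (all partitions, named by inflation).
#' @export
inflation_sweep <- function(network, annotations,
                            inflation_values = seq(1.1, 3.0, by = 0.1),
                            params = mcl_params(),
                            fdr_threshold = 0.05) {
  stopifnot(length(annotations$term_genes) > 0)
  partitions <- list()
  rows <- vector("list", length(inflation_values))
  for (i in seq_along(inflation_values)) {
    p <- params
    p$inflation <- inflation_values[i]
    part <- run_mcl(network, p)
    enr <- enrich_partition(part, annotations, fdr_threshold = fdr_threshold)
    q <- cluster_quality(part, enr, annotations)
    if (length(part$modules) < 2) q$f_measure <- 0
    partitions[[sprintf("%.1f", inflation_values[i])]] <- part
    rows[[i]] <- data.frame(inflation = inflation_values[i],
                            n_modules = length(part$modules),
                            n_unassigned = length(part$unassigned),
                            specificity = q$specificity,
                            sensitivity = q$sensitivity,
                            f_measure = q$f_measure,
                            modularity = part$modularity)
  }
  table <- do.call(rbind, rows)
  best_i <- which.max(table$f_measure)  # ties -> first, i.e. smallest I
  list(best = partitions[[best_i]], table = table, partitions = partitions)
}

#' Write a module partition's membership table
#'
#' @param partition A `module_partition`.
#' @param path TSV path; columns `gene`, `module` (`unassigned` for
#'   filtered genes), `inflation`.
#' @return Invisibly, the path.
#' @export
write_partition <- function(partition, path) {
  labs <- partition_labels(partition, include_unassigned = FALSE)
  df <- rbind(
    data.frame(gene = names(labs), module = unname(labs)),
    if (length(partition$unassigned))
      data.frame(gene = partition$unassigned, module = "unassigned")
  )
  df <- df[order(df$gene), , drop = FALSE]
  df$inflation <- partition$inflation_used
  write_tsv(df, path)
}
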