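#' Configuration for guide-gene network expansion
#'
#' @param guides Character vector of guide gene ids (functionally
#'   characterised seeds).
#' @param hierarchy_depth Expansion depth in edges from a guide
#'   (default 2).
#' @param mr_max Maximum mutual rank for an edge to qualify (inclusive,
#'   default 5).
#' @param pcc_min Minimum correlation for an edge to qualify (inclusive,
#'   default 0.6).
#' @return A `guide_config`.
#' @export
guide_config <- function(guides, hierarchy_depth = 2L, mr_max = 5,
                         pcc_min = 0.6) {
  stopifnot(length(guides) > 0, hierarchy_depth >= 1, mr_max >= 1,
            pcc_min > 0, pcc_min < 1)
  structure(list(guides = unique(as.character(guides)),
                 hierarchy_depth = as.integer(hierarchy_depth),
                 mr_max = mr_max, pcc_min = pcc_min),
            class = "guide_config")
}

#' Expand a network outward from guide genes
#'
#' Breadth-first expansion: a gene enters at level k (k = 1 ..
#' `hierarchy_depth`) when it is linked to a level-(k-1) gene by an edge
#' with mutual rank `<= mr_max` and correlation `>= pcc_min`. Guides are
#' level 0; a gene reachable at several depths keeps its minimal level.
#' All qualifying edges among included genes are retained.
#'
#' @param corr A `correlation_matrix`.
#' @param mr A `mutual_rank_matrix` over the same genes (see
#'   [mutual_ranks()]).
#' @param config A [guide_config()]; every guide must be present in the
#'   matrices.
#' @return A `guide_network`: list with `nodes` (data.frame `gene`,
#'   `level`; level 0 = guide), `edges` (data.frame `gene_a`, `gene_b`,
#'   `r`, `mr`), `config`.
#' @export
expand_from_guides <- function(corr, mr, config) {
  stopifnot(inherits(corr, "correlation_matrix"),
            inherits(mr, "mutual_rank_matrix"),
            inherits(config, "guide_config"))
  genes <- corr$gene_ids
  stopifnot(identical(genes, mr$gene_ids))
  unknown <- setdiff(config$guides, genes)
  if (length(unknown)) {
    stop("guide genes absent from the matrices: ",
         paste(unknown, collapse = ", "))
  }
  qualifies <- mr$mr <= config$mr_max & corr$r >= config$pcc_min
  diag(qualifies) <- FALSE
  qualifies[is.na(qualifies)] <- FALSE

  level <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  level[config$guides] <- 0L
  frontier <- config$guides
  for (k in seq_len(config$hierarchy_depth)) {
    if (length(frontier) == 0) break
    reached <- genes[colSums(qualifies[frontier, , drop = FALSE]) > 0]
    fresh <- reached[is.na(level[reached])]
    level[fresh] <- k
    frontier <- fresh
  }
  included <- names(level)[!is.na(level)]

  sub <- qualifies[included, included, drop = FALSE]
  sub[lower.tri(sub, diag = TRUE)] <- FALSE
  idx <- which(sub, arr.ind = TRUE)
  edges <- data.frame(
    gene_a = included[idx[, 1]],
    gene_b = included[idx[, 2]],
    r = corr$r[cbind(match(included[idx[, 1]], genes),
                     match(included[idx[, 2]], genes))],
    mr = mr$mr[cbind(match(included[idx[, 1]], genes),
                     match(included[idx[, 2]], genes))],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(gene = included, level = unname(level[included]),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$level, nodes$gene), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, config = config),
            class = "guide_network")
}

#' @export
print.guide_network <- function(x, ...) {
  cat(sprintf(
    "guide_network: %d guides, %d first neighbours, %d nodes, %d edges\n",
    sum(x$nodes$level == 0), sum(x$nodes$level == 1), nrow(x$nodes),
    nrow(x$edges)))
  invisible(x)
}

#' Nominate putative targets among first neighbours of guides
#'
#' A first neighbour (level-1 gene) possessing at least one MYB-binding
#' cis-element in its promoter is nominated as a putative target of every
#' guide it is directly linked to by a qualifying edge. One row per
#' (guide, target, hit); correlation is reported rounded to one decimal.
#'
#' @param guide_net A `guide_network` from [expand_from_guides()].
#' @param hits Hit table from [scan_promoters()] covering the guide
#'   network's genes.
#' @param dictionary Motif dictionary used for the scan.
#' @return data.frame `guide`, `target`, `r`, `motif`, `consensus`,
#'   `strand`, `position`, `drought_mbs` (whether the hit is a
#'   drought-inducibility MBS).
#' @export
nominate_targets <- function(guide_net, hits,
                             dictionary = default_motif_dictionary()) {
  stopifnot(inherits(guide_net, "guide_network"))
  lvl <- stats::setNames(guide_net$nodes$level, guide_net$nodes$gene)
  e <- guide_net$edges
  guide_edges <- e[(lvl[e$gene_a] == 0 & lvl[e$gene_b] == 1) |
                     (lvl[e$gene_a] == 1 & lvl[e$gene_b] == 0), ,
                   drop = FALSE]
  if (nrow(guide_edges) == 0 || nrow(hits) == 0) {
    return(data.frame(guide = character(0), target = character(0),
                      r = numeric(0), motif = character(0),
                      consensus = character(0), strand = character(0),
                      position = integer(0), drought_mbs = logical(0)))
  }
  guide <- ifelse(lvl[guide_edges$gene_a] == 0, guide_edges$gene_a,
                  guide_edges$gene_b)
  target <- ifelse(lvl[guide_edges$gene_a] == 0, guide_edges$gene_b,
                   guide_edges$gene_a)
  pairs <- data.frame(guide = guide, target = target,
                      r = round(guide_edges$r, 1),
                      stringsAsFactors = FALSE)
  out <- merge(pairs, hits, by.x = "target", by.y = "gene")
  if (nrow(out) == 0) {
    return(data.frame(guide = character(0), target = character(0),
                      r = numeric(0), motif = character(0),
                      consensus = character(0), strand = character(0),
                      position = integer(0), drought_mbs = logical(0)))
  }
  out$drought_mbs <- out$category == "drought_mbs"
  out <- out[order(out$guide, out$target, out$position),
             c("guide", "target", "r", "motif", "consensus", "strand",
               "position", "drought_mbs")]
  rownames(out) <- NULL
  out
}

#' Write a guide network as GraphML with level attributes
#'
#' @param guide_net A `guide_network`.
#' @param path GraphML path.
#' @return Invisibly, the path.
#' @export
write_guide_network <- function(guide_net, path) {
  g <- igraph::graph_from_data_frame(
    guide_net$edges, directed = FALSE,
    vertices = guide_net$nodes
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
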