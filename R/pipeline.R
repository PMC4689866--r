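#' Top-down co-regulatory network workflow
#'
#' Runs the full top-down analysis: optional probe collapsing, all-vs-all
#' Pearson correlation, threshold sweep diagnostics, signed network at the
#' chosen cutoff, MCL inflation sweep scored by enrichment F-measure, hub
#' calling, and an optional differential-expression overlay. All stages
#' are deterministic given their inputs; artifacts are written as TSV /
#' GraphML when `outdir` is given, together with a run manifest.
#'
#' @param expr An [expr_matrix()] (probe- or gene-level).
#' @param annotations An [annotation_map()].
#' @param probe_mapping Optional probe -> gene mapping for
#'   [collapse_probes()].
#' @param pcc_cutoff Correlation cutoff for the analysis network
#'   (default 0.85, strict).
#' @param sweep_cutoffs Grid for the threshold diagnostics.
#' @param inflation_values Inflation grid for the MCL sweep.
#' @param fdr_threshold Enrichment FDR cutoff.
#' @param min_hub_degree Hub degree threshold (default 5).
#' @param deg_contrast Optional `c(control, treatment)` condition pair for
#'   the DEG overlay.
#' @param mcl Base [mcl_params()].
#' @param outdir Output directory, or `NULL` for no files.
#' @return List with `corr`, `sweep`, `network`, `retention`,
#'   `scale_free_r2`, `partition` (argmax-F), `sweep_table`,
#'   `enrichments`, `quality`, `hubs`, `degs` (or NULL), `manifest`.
#'   When the network at `pcc_cutoff` has no edges the clustering stages
#'   are skipped and the manifest notes the short-circuit.
#' @export
run_topdown <- function(expr, annotations, probe_mapping = NULL,
                        pcc_cutoff = 0.85,
                        sweep_cutoffs = seq(0.5, 0.95, by = 0.05),
                        inflation_values = seq(1.1, 3.0, by = 0.1),
                        fdr_threshold = 0.05, min_hub_degree = 5L,
                        deg_contrast = NULL, mcl = mcl_params(),
                        outdir = NULL) {
  stages <- character(0)
  if (!is.null(probe_mapping)) {
    expr <- collapse_probes(expr, probe_mapping)
    stages <- c(stages, "collapse_probes")
  }
  corr <- pearson_all_pairs(expr)
  stages <- c(stages, "pearson_all_pairs")
  sweep <- sweep_thresholds(corr, sweep_cutoffs)
  stages <- c(stages, "sweep_thresholds")
  network <- build_network(corr, pcc_cutoff)
  stages <- c(stages, "build_network")
  retention <- retention_pct(length(network$nodes), length(corr$gene_ids))

  partition <- NULL
  sweep_table <- NULL
  enrichments <- NULL
  quality <- NULL
  hubs <- find_hubs(network, min_hub_degree)
  stages <- c(stages, "find_hubs")

  if (nrow(network$edges) == 0) {
    message("no edges at cutoff ", pcc_cutoff, "; no modules to report")
    short_circuit <- TRUE
  } else {
    short_circuit <- FALSE
    sw <- inflation_sweep(network, annotations, inflation_values,
                          params = mcl, fdr_threshold = fdr_threshold)
    partition <- sw$best
    sweep_table <- sw$table
    enrichments <- enrich_partition(partition, annotations,
                                    fdr_threshold = fdr_threshold)
    quality <- cluster_quality(partition, enrichments, annotations)
    stages <- c(stages, "inflation_sweep", "enrich_partition")
    if (nrow(hubs) && !is.null(partition)) {
      hubs <- find_hubs(network, min_hub_degree, partition = partition)
    }
  }

  degs <- NULL
  if (!is.null(deg_contrast)) {
    degs <- call_degs(expr, deg_contrast[1], deg_contrast[2])
    stages <- c(stages, "call_degs")
  }

  manifest <- list(
    workflow = "topdown",
    package_version = as.character(utils::packageVersion("mybcoexp")),
    stages = stages,
    short_circuit = short_circuit,
    thresholds = list(pcc_cutoff = pcc_cutoff,
                      fdr_threshold = fdr_threshold,
                      min_hub_degree = min_hub_degree,
                      inflation_values = inflation_values),
    n_genes = length(corr$gene_ids),
    n_nodes = length(network$nodes),
    n_edges = nrow(network$edges),
    retention_pct = retention
  )

  result <- list(corr = corr, sweep = sweep, network = network,
                 retention = retention,
                 scale_free_r2 = scale_free_fit(network),
                 partition = partition, sweep_table = sweep_table,
                 enrichments = enrichments, quality = quality,
                 hubs = hubs, degs = degs, manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(sweep, file.path(outdir, "threshold_sweep.tsv"))
    write_network(network, file.path(outdir, "edges.tsv"),
                  file.path(outdir, "network.graphml"))
    if (!is.null(partition)) {
      write_partition(partition, file.path(outdir, "modules.tsv"))
      write_tsv(sweep_table, file.path(outdir, "inflation_sweep.tsv"))
      write_tsv(enrichments, file.path(outdir, "enrichment.tsv"))
    }
    write_tsv(hubs, file.path(outdir, "hubs.tsv"))
    if (!is.null(degs)) write_tsv(degs, file.path(outdir, "degs.tsv"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Guide-gene transcriptional regulatory network workflow
#'
#' Runs the guide-gene analysis: correlation, mutual ranks, breadth-first
#' expansion from the guides under MR and PCC thresholds, promoter
#' scanning of the expanded genes, target nomination, and composition-based
#' motif enrichment over the nominated targets' promoters.
#'
#' @param expr An [expr_matrix()] at gene level.
#' @param guides Character vector of guide gene ids.
#' @param promoters Named `DNAStringSet` (or character vector) of promoter
#'   sequences covering at least the expanded genes.
#' @param dictionary Motif dictionary (default
#'   [default_motif_dictionary()]).
#' @param hierarchy_depth,mr_max,pcc_min Expansion thresholds, see
#'   [guide_config()].
#' @param outdir Output directory, or `NULL` for no files.
#' @return List with `corr`, `mr`, `guide_net`, `hits`, `targets`
#'   (nomination table), `target_sets` (from [putative_target_filter()]),
#'   `enrichment` (per-motif observed/expected/p over target promoters),
#'   `manifest`.
#' @export
run_guidegene <- function(expr, guides, promoters,
                          dictionary = default_motif_dictionary(),
                          hierarchy_depth = 2L, mr_max = 5, pcc_min = 0.6,
                          outdir = NULL) {
  config <- guide_config(guides, hierarchy_depth, mr_max, pcc_min)
  corr <- pearson_all_pairs(expr)
  mr <- mutual_ranks(corr)
  guide_net <- expand_from_guides(corr, mr, config)
  if (is.character(promoters)) {
    promoters <- Biostrings::DNAStringSet(promoters)
  }
  net_genes <- guide_net$nodes$gene
  covered <- intersect(net_genes, names(promoters))
  hits <- scan_promoters(promoters[covered], dictionary)
  targets <- nominate_targets(guide_net, hits, dictionary)
  first_neighbours <- guide_net$nodes$gene[guide_net$nodes$level == 1]
  target_sets <- putative_target_filter(hits, first_neighbours, dictionary)

  target_proms <- promoters[intersect(target_sets$myb_targets,
                                      names(promoters))]
  enrichment <- if (length(target_proms)) {
    target_hits <- hits[hits$gene %in% names(target_proms), , drop = FALSE]
    do.call(rbind, lapply(dictionary$id, function(m) {
      e <- motif_enrichment(target_hits, target_proms, m, dictionary)
      data.frame(motif = m, observed = e$observed, expected = e$expected,
                 p_value = e$p_value)
    }))
  } else NULL

  manifest <- list(
    workflow = "guidegene",
    package_version = as.character(utils::packageVersion("mybcoexp")),
    stages = c("pearson_all_pairs", "mutual_ranks", "expand_from_guides",
               "scan_promoters", "nominate_targets", "motif_enrichment"),
    thresholds = list(hierarchy_depth = hierarchy_depth, mr_max = mr_max,
                      pcc_min = pcc_min),
    n_guides = length(config$guides),
    n_first_neighbours = length(first_neighbours),
    n_nodes = nrow(guide_net$nodes),
    n_edges = nrow(guide_net$edges),
    n_myb_targets = length(target_sets$myb_targets),
    n_drought_targets = length(target_sets$drought_targets)
  )

  result <- list(corr = corr, mr = mr, guide_net = guide_net, hits = hits,
                 targets = targets, target_sets = target_sets,
                 enrichment = enrichment, manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_guide_network(guide_net, file.path(outdir, "guide_network.graphml"))
    write_tsv(guide_net$nodes, file.path(outdir, "guide_nodes.tsv"))
    write_tsv(guide_net$edges, file.path(outdir, "guide_edges.tsv"))
    write_tsv(hits, file.path(outdir, "promoter_hits.tsv"))
    write_tsv(targets, file.path(outdir, "putative_targets.tsv"))
    if (!is.null(enrichment)) {
      write_tsv(enrichment, file.path(outdir, "motif_enrichment.tsv"))
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
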