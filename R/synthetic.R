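#' Configuration for the synthetic expression study
#'
#' Describes a simulated multi-condition expression compendium with planted
#' co-expression modules, differential expression, module-aligned annotation
#' terms, and promoter cis-elements at known positions. The defaults emulate
#' a small transcription-factor-family compendium: a few tight co-expression
#' modules among a larger background, many conditions with few replicates
#' each, log2-scale values.
#'
#' Co-expression is generated by a single latent factor per module:
#' `x_g = baseline_g + s_g * lambda * z_m + eps`, with `z_m` a shared
#' standard-normal sample profile, `eps ~ N(0, noise_sd^2)` iid, and
#' `s_g = -1` for the anti-correlated fraction of module members. The
#' loading is calibrated analytically so the expected within-module |PCC|
#' equals `within_module_correlation`:
#' `lambda = noise_sd * sqrt(r / (1 - r))` (since r = lambda^2 /
#' (lambda^2 + noise_sd^2)).
#'
#' @param n_genes Total genes (modules + background).
#' @param module_sizes Integer vector of planted module sizes; each must be
#'   >= 3 (smaller modules would always be erased by the downstream cluster
#'   size filter).
#' @param anticorrelated_fraction Fraction of each module's members whose
#'   loading sign is flipped, producing negative within-module correlations.
#' @param n_conditions,replicates_per_condition Design: conditions x
#'   replicates samples. Differential expression is planted in the last
#'   condition (the designated treatment).
#' @param within_module_correlation Target expected |PCC| between two
#'   members of the same module, in (0, 1).
#' @param noise_sd Residual standard deviation in log2 units.
#' @param n_deg_genes Number of genes receiving a planted condition effect.
#' @param deg_effect Planted log2 fold-change magnitude in the treatment
#'   condition.
#' @param annotation_coverage Fraction of each module annotated with its
#'   dedicated term.
#' @param n_noise_terms Extra annotation terms over uniformly random gene
#'   sets, making the enrichment sweep non-trivial.
#' @param promoter_length Promoter length in bases (1 kb upstream of the
#'   translational start codon by convention).
#' @param planted_motifs Optional data.frame with columns `gene`, `motif`,
#'   `strand` (+/-), `position` (1-based leftmost) of cis-elements to plant.
#' @param base_composition Named probabilities over A, C, G, T for the
#'   background promoter sequence.
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 200L,
                             module_sizes = c(10L, 15L, 20L, 25L),
                             anticorrelated_fraction = 0.1,
                             n_conditions = 10L,
                             replicates_per_condition = 3L,
                             within_module_correlation = 0.9,
                             noise_sd = 0.2,
                             n_deg_genes = 0L,
                             deg_effect = 2.0,
                             annotation_coverage = 0.8,
                             n_noise_terms = 10L,
                             promoter_length = 1000L,
                             planted_motifs = NULL,
                             base_composition = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                             seed = 1L) {
  if (any(module_sizes < 3L)) {
    stop("module sizes below 3 are rejected: the downstream cluster size ",
         "filter would always erase them")
  }
  if (sum(module_sizes) > n_genes) {
    stop("sum(module_sizes) exceeds n_genes")
  }
  stopifnot(within_module_correlation > 0, within_module_correlation < 1,
            anticorrelated_fraction >= 0, anticorrelated_fraction <= 1,
            noise_sd >= 0, n_conditions >= 1, replicates_per_condition >= 1,
            annotation_coverage >= 0, annotation_coverage <= 1,
            promoter_length >= 1, n_deg_genes >= 0,
            n_deg_genes <= n_genes)
  stopifnot(setequal(names(base_composition), c("A", "C", "G", "T")),
            abs(sum(base_composition) - 1) < 1e-8)
  if (!is.null(planted_motifs)) {
    stopifnot(all(c("gene", "motif", "strand", "position") %in%
                    names(planted_motifs)))
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_background_genes = as.integer(n_genes - sum(module_sizes)),
    module_sizes = as.integer(module_sizes),
    anticorrelated_fraction = anticorrelated_fraction,
    n_conditions = as.integer(n_conditions),
    replicates_per_condition = as.integer(replicates_per_condition),
    within_module_correlation = within_module_correlation,
    noise_sd = noise_sd,
    n_deg_genes = as.integer(n_deg_genes),
    deg_effect = deg_effect,
    annotation_coverage = annotation_coverage,
    n_noise_terms = as.integer(n_noise_terms),
    promoter_length = as.integer(promoter_length),
    planted_motifs = planted_motifs,
    base_composition = base_composition[c("A", "C", "G", "T")],
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic expression matrix with planted structure
#'
#' @param config A [synthetic_config()].
#' @return List with `expr` (an [expr_matrix()]) and `truth`, a
#'   `synthetic_truth` list recording `module_of_gene` (gene -> module label
#'   or "background"), `deg_genes`, `deg_condition`, and empty slots filled
#'   by [generate_annotations()] / [generate_promoters()].
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)

  n_mod <- length(config$module_sizes)
  gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
  conds <- sprintf("cond%02d", seq_len(config$n_conditions))
  design <- data.frame(
    sample = as.vector(t(outer(conds, seq_len(config$replicates_per_condition),
                               function(c, r) sprintf("%s_r%d", c, r)))),
    condition = rep(conds, each = config$replicates_per_condition),
    replicate = rep(seq_len(config$replicates_per_condition),
                    times = config$n_conditions),
    stringsAsFactors = FALSE
  )
  n_samples <- nrow(design)

  module_of_gene <- stats::setNames(rep("background", config$n_genes),
                                    gene_ids)
  idx <- 1L
  for (m in seq_len(n_mod)) {
    sz <- config$module_sizes[m]
    module_of_gene[idx:(idx + sz - 1L)] <- sprintf("M%02d", m)
    idx <- idx + sz
  }

  baseline <- stats::runif(config$n_genes, 4, 12)
  values <- matrix(stats::rnorm(config$n_genes * n_samples,
                                sd = config$noise_sd),
                   nrow = config$n_genes,
                   dimnames = list(gene_ids, design$sample))
  values <- values + baseline

  r <- config$within_module_correlation
  # zero-noise limit: any positive loading gives |PCC| = 1 exactly
  lambda <- if (config$noise_sd == 0) 1 else
    config$noise_sd * sqrt(r / (1 - r))

  sign_of_gene <- stats::setNames(rep(1, config$n_genes), gene_ids)
  for (m in seq_len(n_mod)) {
    members <- gene_ids[module_of_gene == sprintf("M%02d", m)]
    z <- stats::rnorm(n_samples)
    n_flip <- floor(config$anticorrelated_fraction * length(members))
    if (n_flip > 0) {
      flipped <- sample(members, n_flip)
      sign_of_gene[flipped] <- -1
    }
    values[members, ] <- values[members, ] +
      outer(sign_of_gene[members] * lambda, z)
  }

  deg_condition <- conds[length(conds)]
  deg_genes <- character(0)
  if (config$n_deg_genes > 0) {
    deg_genes <- sort(sample(gene_ids, config$n_deg_genes))
    trt_cols <- design$sample[design$condition == deg_condition]
    values[deg_genes, trt_cols] <- values[deg_genes, trt_cols] +
      config$deg_effect
  }

  truth <- list(
    module_of_gene = module_of_gene,
    sign_of_gene = sign_of_gene,
    deg_genes = deg_genes,
    deg_condition = deg_condition,
    term_of_module = NULL,
    planted_hits = NULL
  )
  class(truth) <- "synthetic_truth"
  list(expr = expr_matrix(values, design), truth = truth)
}

#' Generate module-aligned annotation terms
#'
#' Each planted module gets one dedicated term annotating a fraction
#' `annotation_coverage` of its members; `n_noise_terms` additional terms
#' annotate uniformly random gene sets. The universe is all genes.
#'
#' @param truth `synthetic_truth` from [generate_expression()].
#' @param config The same [synthetic_config()].
#' @return List with `annotations` (an [annotation_map()]) and the updated
#'   `truth` whose `term_of_module` maps module labels to their dedicated
#'   terms.
#' @export
generate_annotations <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  universe <- names(truth$module_of_gene)
  modules <- sort(unique(truth$module_of_gene[truth$module_of_gene !=
                                                "background"]))
  if (config$annotation_coverage * min(config$module_sizes) < 2) {
    warning("annotation_coverage * smallest module < 2: enrichment requires ",
            "at least two annotated genes per module")
  }
  term_sets <- list()
  term_of_module <- stats::setNames(character(length(modules)), modules)
  for (m in modules) {
    members <- universe[truth$module_of_gene == m]
    n_ann <- round(config$annotation_coverage * length(members))
    term <- sprintf("TERM_%s", m)
    term_of_module[m] <- term
    term_sets[[term]] <- sort(sample(members, n_ann))
  }
  if (config$n_noise_terms > 0) {
    for (i in seq_len(config$n_noise_terms)) {
      sz <- sample(5:30, 1)
      term_sets[[sprintf("NOISE%02d", i)]] <-
        sort(sample(universe, min(sz, length(universe))))
    }
  }
  truth$term_of_module <- term_of_module
  list(annotations = annotation_map(term_sets, universe), truth = truth)
}

#' Generate promoter sequences with planted cis-elements
#'
#' Promoters are iid sequences from `base_composition`, written 5'->3' on
#' the coding strand and ending immediately before the translational start
#' codon. Planted motifs overwrite the background sequence at their recorded
#' 1-based leftmost positions (minus-strand plants insert the reverse
#' complement of the consensus), so promoter length stays fixed.
#'
#' @param truth `synthetic_truth` from [generate_expression()].
#' @param config The [synthetic_config()]; `config$planted_motifs` gives the
#'   plants, with motif ids resolved against `dictionary`.
#' @param dictionary A motif dictionary (default
#'   [default_motif_dictionary()]).
#' @return List with `promoters` (a named `DNAStringSet`) and the updated
#'   `truth` whose `planted_hits` records every plant.
#' @export
generate_promoters <- function(truth, config,
                               dictionary = default_motif_dictionary()) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  genes <- names(truth$module_of_gene)
  L <- config$promoter_length
  comp <- config$base_composition
  seqs <- vapply(genes, function(g) {
    paste(sample(names(comp), L, replace = TRUE, prob = comp), collapse = "")
  }, character(1))

  plants <- config$planted_motifs
  if (!is.null(plants) && nrow(plants) > 0) {
    if (!all(plants$motif %in% dictionary$id)) {
      stop("planted motif ids not in dictionary: ",
           paste(setdiff(plants$motif, dictionary$id), collapse = ", "))
    }
    if (!all(plants$gene %in% genes)) {
      stop("planted motifs reference unknown genes")
    }
    consensus <- stats::setNames(dictionary$consensus, dictionary$id)
    widths <- nchar(consensus[plants$motif])
    if (any(plants$position < 1 | plants$position > L - widths + 1)) {
      stop("planted position outside the promoter for the motif length")
    }
    # reject overlapping plants on the same gene
    for (g in unique(plants$gene)) {
      p <- plants[plants$gene == g, , drop = FALSE]
      w <- nchar(consensus[p$motif])
      ivl <- cbind(p$position, p$position + w - 1)
      ivl <- ivl[order(ivl[, 1]), , drop = FALSE]
      if (nrow(ivl) > 1 &&
          any(ivl[-1, 1] <= ivl[-nrow(ivl), 2])) {
        stop("overlapping planted motifs on gene ", g)
      }
    }
    for (i in seq_len(nrow(plants))) {
      site <- consensus[plants$motif[i]]
      if (plants$strand[i] == "-") site <- revcomp(site)
      substr(seqs[plants$gene[i]], plants$position[i],
             plants$position[i] + nchar(site) - 1) <- site
    }
    truth$planted_hits <- plants[, c("gene", "motif", "strand", "position")]
  } else {
    truth$planted_hits <- data.frame(gene = character(0),
                                     motif = character(0),
                                     strand = character(0),
                                     position = integer(0))
  }
  list(promoters = Biostrings::DNAStringSet(seqs), truth = truth)
}

#' Write a synthetic study to disk as plain-text files
#'
#' Expression TSV (genes x samples), design TSV, two-column annotation TSV,
#' promoters FASTA and truth JSON.
#'
#' @param sim List with `expr`, `truth`, and optionally `annotations`,
#'   `promoters`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_df <- data.frame(gene = rownames(sim$expr$values),
                        sim$expr$values, check.names = FALSE)
  write_tsv(expr_df, file.path(dir, "expression.tsv"))
  write_tsv(sim$expr$design, file.path(dir, "design.tsv"))
  if (!is.null(sim$annotations)) {
    ann_df <- do.call(rbind, lapply(names(sim$annotations$term_genes),
      function(t) data.frame(gene = sim$annotations$term_genes[[t]],
                             term = t)))
    write_tsv(ann_df, file.path(dir, "annotations.tsv"))
  }
  if (!is.null(sim$promoters)) {
    Biostrings::writeXStringSet(sim$promoters,
                                file.path(dir, "promoters.fasta"))
  }
  truth <- sim$truth
  truth_json <- list(
    module_of_gene = as.list(truth$module_of_gene),
    deg_genes = truth$deg_genes,
    deg_condition = truth$deg_condition,
    term_of_module = as.list(truth$term_of_module),
    planted_hits = truth$planted_hits
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
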