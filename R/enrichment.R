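#' Annotation map: term -> gene set over a universe
#'
#' Terms are opaque labels (e.g. pre-propagated GO ids); no ontology
#' structure is assumed.
#'
#' @param term_genes Named list, term id -> character vector of gene ids.
#' @param universe Character vector of all annotatable genes; every
#'   annotated gene must belong to it.
#' @return An `annotation_map`.
#' @export
annotation_map <- function(term_genes, universe) {
  stopifnot(is.list(term_genes), length(universe) > 0)
  universe <- sort(unique(universe))
  if (is.null(names(term_genes)) && length(term_genes)) {
    stop("term_genes must be a named list")
  }
  term_genes <- term_genes[sort(names(term_genes))]
  term_genes <- lapply(term_genes, function(g) sort(unique(g)))
  stray <- setdiff(unlist(term_genes, use.names = FALSE), universe)
  if (length(stray)) {
    stop("annotated genes outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  structure(list(term_genes = term_genes, universe = universe),
            class = "annotation_map")
}

#' Read a two-column (gene, term) annotation TSV
#'
#' @param path TSV with header columns `gene` and `term`.
#' @param universe Optional explicit universe; defaults to all genes seen
#'   in the file.
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path, universe = NULL) {
  df <- read_tsv(path)
  stopifnot(all(c("gene", "term") %in% names(df)))
  if (is.null(universe)) universe <- unique(df$gene)
  annotation_map(split(df$gene, df$term), universe)
}

#' Hypergeometric term over-representation for every module of a partition
#'
#' For each (module, term) pair with at least one annotated gene in the
#' module, the upper-tail hypergeometric probability
#' `p = P(X >= k)` of drawing k or more of the K term genes when sampling
#' the module's n genes from the N-gene universe. Benjamini-Hochberg
#' adjustment is applied jointly over all (module, term) tests of the
#' partition; a record is significant iff its adjusted p is below
#' `fdr_threshold` and the term has at least two genes in the module.
#'
#' @param partition A `module_partition` (only its retained modules are
#'   tested).
#' @param annotations An [annotation_map()]; every module gene must be in
#'   the universe.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return data.frame `module`, `term`, `k`, `n`, `K`, `N`, `p`,
#'   `adjusted_p`, `significant`.
#' @export
enrich_partition <- function(partition, annotations, fdr_threshold = 0.05) {
  stopifnot(inherits(annotations, "annotation_map"))
  recs <- lapply(names(partition$modules), function(mod) {
    hypergeom_records(mod, partition$modules[[mod]], annotations)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs) || nrow(recs) == 0) {
    return(data.frame(module = character(0), term = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0),
                      adjusted_p = numeric(0), significant = logical(0)))
  }
  recs$adjusted_p <- stats::p.adjust(recs$p, method = "BH")
  recs$significant <- recs$adjusted_p < fdr_threshold & recs$k >= 2
  rownames(recs) <- NULL
  recs
}

#' Term over-representation for a single gene set
#'
#' Same test as [enrich_partition()] but for one stand-alone module, with
#' BH adjustment across its own terms.
#'
#' @param module Character vector of gene ids (subset of the universe).
#' @param annotations An [annotation_map()].
#' @param fdr_threshold FDR cutoff.
#' @return data.frame as in [enrich_partition()] (module label `"module"`).
#' @export
enrich_module <- function(module, annotations, fdr_threshold = 0.05) {
  recs <- hypergeom_records("module", module, annotations)
  if (nrow(recs)) {
    recs$adjusted_p <- stats::p.adjust(recs$p, method = "BH")
    recs$significant <- recs$adjusted_p < fdr_threshold & recs$k >= 2
  } else {
    recs$adjusted_p <- numeric(0)
    recs$significant <- logical(0)
  }
  recs
}

hypergeom_records <- function(label, genes, annotations) {
  N <- length(annotations$universe)
  if (N == 0) stop("empty annotation universe")
  outside <- setdiff(genes, annotations$universe)
  if (length(outside)) {
    stop("module genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  n <- length(genes)
  rows <- lapply(names(annotations$term_genes), function(term) {
    K <- length(annotations$term_genes[[term]])
    k <- length(intersect(genes, annotations$term_genes[[term]]))
    if (k == 0) return(NULL)  # p would be ~1; not tested
    data.frame(module = label, term = term, k = k, n = n, K = K, N = N,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(module = character(0), term = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0))
  }
  out
}

#' Harmonic-mean F-measure of specificity and sensitivity
#'
#' `F = 2 s1 s2 / (s1 + s2)`, defined as 0 when both are 0.
#'
#' @param specificity,sensitivity Fractions in \[0, 1\].
#' @return F in \[0, 1\].
#' @export
f_measure <- function(specificity, sensitivity) {
  if (specificity + sensitivity == 0) return(0)
  2 * specificity * sensitivity / (specificity + sensitivity)
}

#' Partition-level enrichment quality
#'
#' Specificity: fraction of retained modules with at least one significant
#' term. Sensitivity: fraction of the annotation map's terms significant in
#' at least one module. F-measure: their harmonic mean (0 when a
#' denominator is 0). This is a clustering-quality score, not a classifier
#' metric.
#'
#' @param partition A `module_partition`.
#' @param enrichments Output of [enrich_partition()] on this partition.
#' @param annotations The [annotation_map()] used.
#' @return List `inflation`, `specificity`, `sensitivity`, `f_measure`.
#' @export
cluster_quality <- function(partition, enrichments, annotations) {
  n_modules <- length(partition$modules)
  n_terms <- length(annotations$term_genes)
  if (n_modules == 0 || n_terms == 0) {
    return(list(inflation = partition$inflation_used,
                specificity = 0, sensitivity = 0, f_measure = 0))
  }
  sig <- enrichments[enrichments$significant, , drop = FALSE]
  specificity <- length(unique(sig$module)) / n_modules
  sensitivity <- length(unique(sig$term)) / n_terms
  list(inflation = partition$inflation_used,
       specificity = specificity, sensitivity = sensitivity,
       f_measure = f_measure(specificity, sensitivity))
}
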