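#' Expression matrix with sample design
#'
#' A light container for a genes x samples matrix of log2 expression values
#' together with its sample design (condition, replicate).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids), log2 scale.
#' @param design data.frame with columns `sample`, `condition`, `replicate`;
#'   every column of `values` must appear in `design$sample`.
#' @param log2_transform Set `TRUE` if `values` are on the raw scale; they
#'   are then transformed as `log2(x + 1)`.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, design, log2_transform = FALSE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)),
            all(c("sample", "condition", "replicate") %in% names(design)))
  if (anyDuplicated(rownames(values))) {
    stop("duplicated gene ids in expression matrix")
  }
  missing <- setdiff(colnames(values), design$sample)
  if (length(missing)) {
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  }
  if (log2_transform) values <- log2(values + 1)
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(values = values, design = design), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, %d conditions\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$design$condition))))
  invisible(x)
}

#' Read an expression TSV and design TSV into an expr_matrix
#'
#' Expression file: first column gene ids, remaining columns samples, header
#' row. Design file: columns `sample`, `condition`, `replicate`.
#'
#' @param expression_path,design_path File paths.
#' @param log2_transform Passed to [expr_matrix()].
#' @return An [expr_matrix()].
#' @export
read_expression <- function(expression_path, design_path,
                            log2_transform = FALSE) {
  df <- read_tsv(expression_path)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  design <- read_tsv(design_path)
  expr_matrix(values, design, log2_transform = log2_transform)
}

#' Collapse probe-level rows to gene-level rows
#'
#' Genes measured by several probes get the unweighted per-sample mean of
#' their probe rows; genes with a single probe are copied unchanged.
#' Probes absent from the mapping are dropped (their count is reported via
#' a message).
#'
#' @param probe_matrix [expr_matrix()] whose rows are probes.
#' @param mapping Two-column data.frame (`probe`, `gene`) or a named
#'   character vector probe -> gene.
#' @return [expr_matrix()] with one row per mapped gene.
#' @export
collapse_probes <- function(probe_matrix, mapping) {
  stopifnot(inherits(probe_matrix, "expr_matrix"))
  if (is.data.frame(mapping)) {
    stopifnot(all(c("probe", "gene") %in% names(mapping)))
    mapping <- stats::setNames(as.character(mapping$gene),
                               as.character(mapping$probe))
  }
  if (length(mapping) == 0) stop("empty probe-to-gene mapping")
  absent <- setdiff(names(mapping), rownames(probe_matrix$values))
  if (length(absent)) {
    stop("mapped probes absent from the matrix: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  unmapped <- setdiff(rownames(probe_matrix$values), names(mapping))
  if (length(unmapped)) {
    message(length(unmapped), " unmapped probes dropped")
  }
  keep <- intersect(rownames(probe_matrix$values), names(mapping))
  sub <- probe_matrix$values[keep, , drop = FALSE]
  genes <- mapping[keep]
  collapsed <- rowsum(sub, group = genes) / as.vector(table(genes)[
    sort(unique(genes))])
  collapsed <- collapsed[sort(rownames(collapsed)), , drop = FALSE]
  expr_matrix(collapsed, probe_matrix$design)
}

#' Call differentially expressed genes between two conditions
#'
#' Per-gene two-sample t-test of treatment vs control replicates on the
#' log2 matrix, Benjamini-Hochberg adjustment across genes, and the joint
#' rule: a gene is differentially expressed iff
#' `|log2FC| >= fc_threshold` and adjusted p < `p_threshold`. The pooled
#' (equal-variance) t-test is the default: with the 2-3 replicates typical
#' of these compendia the Welch degrees-of-freedom penalty costs real
#' power, and the replicate noise model is homoscedastic on the log2
#' scale; set `var_equal = FALSE` for the Welch variant. Genes with zero
#' variance in both groups have no defined test; they are flagged not-DE
#' with reason `"zero_variance"`.
#'
#' @param matrix An [expr_matrix()].
#' @param control,treatment Condition labels in the design.
#' @param fc_threshold Minimum absolute log2 fold change (default 1.5).
#' @param p_threshold Adjusted-p cutoff (default 0.05).
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return data.frame with columns `gene`, `log2fc` (treatment - control
#'   means), `p`, `adj_p`, `is_de`, `direction` (+/-/NA), `reason`.
#' @export
call_degs <- function(matrix, control, treatment,
                      fc_threshold = 1.5, p_threshold = 0.05,
                      var_equal = TRUE) {
  stopifnot(inherits(matrix, "expr_matrix"))
  des <- matrix$design
  ctrl_cols <- des$sample[des$condition == control]
  trt_cols <- des$sample[des$condition == treatment]
  if (length(ctrl_cols) < 2 || length(trt_cols) < 2) {
    stop("need >= 2 replicates per condition")
  }
  x <- matrix$values[, trt_cols, drop = FALSE]
  y <- matrix$values[, ctrl_cols, drop = FALSE]
  lfc <- rowMeans(x) - rowMeans(y)
  vx <- apply(x, 1, stats::var)
  vy <- apply(y, 1, stats::var)
  p <- rep(NA_real_, nrow(x))
  testable <- vx + vy > 0
  p[testable] <- vapply(which(testable), function(i) {
    stats::t.test(x[i, ], y[i, ], var.equal = var_equal)$p.value
  }, numeric(1))
  adj <- stats::p.adjust(p, method = "BH")
  is_de <- !is.na(adj) & abs(lfc) >= fc_threshold & adj < p_threshold
  data.frame(
    gene = rownames(matrix$values),
    log2fc = unname(lfc),
    p = p,
    adj_p = adj,
    is_de = is_de,
    direction = ifelse(is_de, ifelse(lfc > 0, "+", "-"), NA_character_),
    reason = ifelse(testable, NA_character_, "zero_variance"),
    stringsAsFactors = FALSE
  )
}
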