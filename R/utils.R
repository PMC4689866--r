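#' Percentage of retained items
#'
#' Share of an input set surviving a filtering step, as a percentage rounded
#' to two decimals (the convention used for reporting how many genes a
#' correlation cutoff keeps in the network).
#'
#' @param n_retained Number of items surviving.
#' @param n_total Number of items going in.
#' @return Percentage in \[0, 100\], rounded to 2 decimal places.
#' @examples
#' retention_pct(146, 219)
#' @export
retention_pct <- function(n_retained, n_total) {
  stopifnot(n_total > 0, n_retained >= 0, n_retained <= n_total)
  round(100 * n_retained / n_total, 2)
}

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement between a recovered partition and a reference
#' (e.g. planted) partition. Labels are compared on the common names when both
#' vectors are named, otherwise positionally.
#'
#' @param labels_a,labels_b Vectors of cluster labels; factors, characters or
#'   integers. If both are named, they are aligned on the intersection of
#'   their names.
#' @return ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
partition_ari <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    if (length(common) == 0L) stop("no common names between labelings")
    labels_a <- labels_a[common]
    labels_b <- labels_b[common]
  }
  stopifnot(length(labels_a) == length(labels_b))
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Flatten a module partition to a per-gene label vector
#'
#' @param partition A `module_partition` (see [run_mcl()]).
#' @param include_unassigned Label unassigned genes as their own singleton
#'   communities (`"u<gene>"`); if `FALSE`, they are dropped.
#' @return Named character vector gene -> module label.
#' @export
partition_labels <- function(partition, include_unassigned = TRUE) {
  labs <- unlist(lapply(names(partition$modules), function(m) {
    stats::setNames(rep(m, length(partition$modules[[m]])),
                    partition$modules[[m]])
  }))
  if (is.null(labs)) labs <- character(0)
  if (include_unassigned && length(partition$unassigned)) {
    labs <- c(labs, stats::setNames(paste0("u", partition$unassigned),
                                    partition$unassigned))
  }
  labs
}

# write a data.frame as a headered, unquoted TSV
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
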