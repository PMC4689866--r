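#' Default MYB cis-element dictionary
#'
#' The six concrete MYB-binding elements scanned in 1 kb promoters:
#' CAACGG (CCAAT-box, MYBHv1 binding site), AACCTAA (MRE, light
#' responsiveness), AAAAGTTAGTTA (MBSII, flavonoid biosynthetic gene
#' regulation), TAACTG and CAACTG (MBS, drought-inducibility) and CGGTCA
#' (generic MYB binding site).
#'
#' @return data.frame `id`, `consensus`, `category`, `description`.
#' @export
default_motif_dictionary <- function() {
  data.frame(
    id = c("MYBHV1_CAACGG", "MRE_AACCTAA", "MBSII_AAAAGTTAGTTA",
           "MBS_TAACTG", "MBS_CAACTG", "MBS_CGGTCA"),
    consensus = c("CAACGG", "AACCTAA", "AAAAGTTAGTTA",
                  "TAACTG", "CAACTG", "CGGTCA"),
    category = c("ccaat_box", "light", "flavonoid",
                 "drought_mbs", "drought_mbs", "generic_mbs"),
    description = c("CCAAT-box; MYBHv1 binding site",
                    "MRE; MYB binding site, light responsiveness",
                    "MBSII; MYB binding site, flavonoid gene regulation",
                    "MBS; MYB binding site, drought-inducibility",
                    "MBS; MYB binding site, drought-inducibility",
                    "MBS; MYB binding site"),
    stringsAsFactors = FALSE
  )
}

#' Read a motif dictionary TSV
#'
#' @param path TSV with header columns `id`, `consensus`, `category`,
#'   `description`.
#' @return Validated dictionary data.frame.
#' @export
read_motif_dictionary <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("id", "consensus", "category") %in% names(df)))
  validate_dictionary(df)
  df
}

validate_dictionary <- function(dictionary) {
  stopifnot(!anyDuplicated(dictionary$id),
            all(nchar(dictionary$consensus) >= 4),
            all(grepl("^[ACGT]+$", dictionary$consensus)))
  invisible(dictionary)
}

# reverse complement of a plain ACGTN string
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

is_palindromic <- function(s) identical(s, revcomp(s))

#' Scan promoters for cis-element occurrences on both strands
#'
#' Exact-string search of each consensus (reported strand `+`) and of its
#' reverse complement (reported strand `-`); positions are the 1-based
#' index of the hit's leftmost base in the promoter string, which is
#' written 5'->3' on the coding strand ending at the translational start
#' codon. Overlapping hits are all reported; `N` never matches. A
#' palindromic consensus is reported once per position with strand `+`.
#'
#' @param promoters Named `DNAStringSet` or named character vector of
#'   promoter sequences.
#' @param dictionary Motif dictionary (default
#'   [default_motif_dictionary()]).
#' @return data.frame `gene`, `motif`, `consensus`, `strand`, `position`,
#'   `width`, `category`, sorted by gene, position.
#' @export
scan_promoters <- function(promoters,
                           dictionary = default_motif_dictionary()) {
  validate_dictionary(dictionary)
  if (is.character(promoters)) {
    promoters <- Biostrings::DNAStringSet(promoters)
  }
  if (is.null(names(promoters))) stop("promoters must be named by gene id")
  empty <- sum(Biostrings::width(promoters) == 0)
  if (empty) message(empty, " empty promoters produce no hits")

  one_strand <- function(pattern, strand, motif_row) {
    m <- Biostrings::vmatchPattern(pattern, promoters, fixed = TRUE)
    st <- Biostrings::startIndex(m)
    rows <- lapply(seq_along(st), function(i) {
      if (is.null(st[[i]]) || length(st[[i]]) == 0) return(NULL)
      data.frame(gene = names(promoters)[i],
                 motif = motif_row$id,
                 consensus = motif_row$consensus,
                 strand = strand,
                 position = st[[i]],
                 width = nchar(motif_row$consensus),
                 category = motif_row$category,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  hits <- lapply(seq_len(nrow(dictionary)), function(j) {
    row <- dictionary[j, ]
    plus <- one_strand(row$consensus, "+", row)
    minus <- if (is_palindromic(row$consensus)) NULL else
      one_strand(revcomp(row$consensus), "-", row)
    rbind(plus, minus)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), motif = character(0),
                      consensus = character(0), strand = character(0),
                      position = integer(0), width = integer(0),
                      category = character(0))
  }
  out <- out[order(out$gene, out$position, out$motif, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes with at least one MYB-binding hit in their promoter
#'
#' @param hits Hit table from [scan_promoters()].
#' @param genes Gene set to filter (e.g. the first-neighbour targets of a
#'   guide network).
#' @param dictionary Dictionary used for the scan (drives the drought-MBS
#'   category).
#' @return List with `myb_targets` (genes with any hit) and
#'   `drought_targets` (genes with a drought-MBS hit); both subsets of
#'   `genes`.
#' @export
putative_target_filter <- function(hits, genes,
                                   dictionary = default_motif_dictionary()) {
  hits <- hits[hits$gene %in% genes, , drop = FALSE]
  list(
    myb_targets = sort(unique(hits$gene)),
    drought_targets = sort(unique(hits$gene[hits$category == "drought_mbs"]))
  )
}

#' Composition-based enrichment of one motif across a promoter set
#'
#' The expected hit count under the null of iid bases at the observed
#' composition: for each promoter of length L and motif width w there are
#' `L - w + 1` positions per strand; a position matches the plus strand
#' with probability `prod(comp[consensus letters])`, the minus strand with
#' the reverse-complement probability. The p-value is the upper binomial
#' tail on the total position count at the mean per-position probability.
#'
#' @param hits Hit table from [scan_promoters()] over the same promoters.
#' @param promoters The scanned promoters (named `DNAStringSet` or
#'   character vector).
#' @param motif Motif id to test.
#' @param dictionary Motif dictionary.
#' @return List `observed`, `expected`, `p_value`, `n_positions`.
#' @export
motif_enrichment <- function(hits, promoters, motif,
                             dictionary = default_motif_dictionary()) {
  row <- dictionary[dictionary$id == motif, , drop = FALSE]
  if (nrow(row) == 0) stop("motif not in dictionary: ", motif)
  if (is.character(promoters)) {
    promoters <- Biostrings::DNAStringSet(promoters)
  }
  comp_counts <- colSums(Biostrings::letterFrequency(promoters,
                                                     c("A", "C", "G", "T")))
  comp <- comp_counts / sum(comp_counts)
  site <- strsplit(row$consensus, "")[[1]]
  p_plus <- prod(comp[site])
  p_minus <- prod(comp[strsplit(revcomp(row$consensus), "")[[1]]])
  w <- nchar(row$consensus)
  pos_per_strand <- pmax(Biostrings::width(promoters) - w + 1, 0)
  n_positions <- 2 * sum(pos_per_strand)
  expected <- sum(pos_per_strand) * (p_plus + p_minus)
  observed <- sum(hits$motif == motif)
  p_bar <- if (n_positions > 0) expected / n_positions else 0
  p_value <- if (n_positions == 0) 1 else
    stats::pbinom(observed - 1, n_positions, p_bar, lower.tail = FALSE)
  list(observed = observed, expected = expected, p_value = p_value,
       n_positions = n_positions)
}

#' Proximal/distal classification of hits relative to the promoter anchor
#'
#' The promoter string ends at its anchor (the translational start codon,
#' used as a TSS proxy); a hit is proximal iff its leftmost position lies
#' within `window` bases of that end (`position > L - window`).
#'
#' @param hits Hit table from [scan_promoters()].
#' @param promoter_length Promoter length L (default 1000).
#' @param window Proximity window in bases (default 200).
#' @return List `proximal_fraction`, `distal_fraction`, `n_proximal`,
#'   `n_distal`; fractions are `NA` for an empty hit table.
#' @export
proximal_distal_split <- function(hits, promoter_length = 1000L,
                                  window = 200L) {
  if (nrow(hits) == 0) {
    return(list(proximal_fraction = NA_real_, distal_fraction = NA_real_,
                n_proximal = 0L, n_distal = 0L))
  }
  proximal <- hits$position > promoter_length - window
  list(proximal_fraction = mean(proximal),
       distal_fraction = mean(!proximal),
       n_proximal = sum(proximal),
       n_distal = sum(!proximal))
}

#' Count hits per cis-element category
#'
#' @param hits Hit table from [scan_promoters()].
#' @param dictionary Dictionary defining valid motif ids and categories.
#' @return List with `overall` (named count per category) and `per_gene`
#'   (data.frame `gene`, `category`, `count`).
#' @export
categorize_hits <- function(hits, dictionary = default_motif_dictionary()) {
  unknown <- setdiff(unique(hits$motif), dictionary$id)
  if (length(unknown)) {
    stop("unknown motif ids in hits: ", paste(unknown, collapse = ", "))
  }
  cats <- sort(unique(dictionary$category))
  overall <- stats::setNames(rep(0L, length(cats)), cats)
  if (nrow(hits)) {
    tab <- table(hits$category)
    overall[names(tab)] <- as.integer(tab)
    per_gene <- as.data.frame(table(gene = hits$gene,
                                    category = hits$category),
                              stringsAsFactors = FALSE)
    names(per_gene)[3] <- "count"
  } else {
    per_gene <- data.frame(gene = character(0), category = character(0),
                           count = integer(0))
  }
  list(overall = overall, per_gene = per_gene)
}

#' Read promoters from FASTA (record id = gene id)
#'
#' @param path FASTA path.
#' @return Named `DNAStringSet`.
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}
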