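test_that("scanner finds planted sites on both strands at exact coordinates", {
  base <- strrep("A", 1000)
  p1 <- base
  substr(p1, 521, 526) <- "TAACTG"
  p2 <- base
  substr(p2, 100, 105) <- "CAGTTG"  # revcomp of CAACTG
  proms <- c(geneA = p1, geneB = p2, geneC = base)
  hits <- scan_promoters(proms)
  a <- hits[hits$gene == "geneA", ]
  expect_equal(a$motif, "MBS_TAACTG")
  expect_equal(a$strand, "+")
  expect_equal(a$position, 521)
  b <- hits[hits$gene == "geneB", ]
  expect_equal(b$motif, "MBS_CAACTG")
  expect_equal(b$strand, "-")
  expect_equal(b$position, 100)
  # all-A promoter has zero hits for every default motif
  expect_false("geneC" %in% hits$gene)
})

test_that("overlapping occurrences are all reported and N never matches", {
  # TAACTGTAACTG gives TAACTG at 1 and 7; CAACTGN blocked by N
  proms <- c(g1 = paste0("TAACTGTAACTG", strrep("G", 20)),
             g2 = paste0("CAACTN", strrep("G", 20)))
  hits <- scan_promoters(proms)
  g1 <- hits[hits$gene == "g1" & hits$motif == "MBS_TAACTG" &
               hits$strand == "+", ]
  expect_equal(g1$position, c(1, 7))
  expect_false("g2" %in% hits$gene)
})

test_that("reverse-complement round trip reflects the hit set", {
  set.seed(19)
  cfg <- synthetic_config(n_genes = 6, module_sizes = integer(0),
                          promoter_length = 400, seed = 19)
  sim <- generate_expression(cfg)
  pr <- generate_promoters(sim$truth, cfg)
  hits <- scan_promoters(pr$promoters)
  rc <- Biostrings::reverseComplement(pr$promoters)
  names(rc) <- names(pr$promoters)
  hits_rc <- scan_promoters(rc)
  # reflect coordinates and swap strands: must give back the same multiset
  L <- 400
  reflected <- data.frame(
    gene = hits_rc$gene,
    motif = hits_rc$motif,
    strand = ifelse(hits_rc$strand == "+", "-", "+"),
    position = L - hits_rc$width - hits_rc$position + 2)
  key <- function(d) sort(paste(d$gene, d$motif, d$strand, d$position))
  expect_equal(key(reflected),
               key(hits[, c("gene", "motif", "strand", "position")]))
})

test_that("every planted motif is recovered and targets filter correctly", {
  plants <- data.frame(
    gene = c("gene0001", "gene0002", "gene0002", "gene0003"),
    motif = c("MBS_TAACTG", "MBS_CGGTCA", "MBS_CGGTCA", "MRE_AACCTAA"),
    strand = c("+", "+", "-", "+"),
    position = c(50L, 200L, 800L, 333L))
  cfg <- synthetic_config(n_genes = 8, module_sizes = integer(0),
                          planted_motifs = plants, seed = 23)
  sim <- generate_expression(cfg)
  pr <- generate_promoters(sim$truth, cfg)
  hits <- scan_promoters(pr$promoters)
  for (i in seq_len(nrow(plants))) {
    expect_true(any(hits$gene == plants$gene[i] &
                      hits$motif == plants$motif[i] &
                      hits$strand == plants$strand[i] &
                      hits$position == plants$position[i]))
  }
  sets <- putative_target_filter(hits, sprintf("gene%04d", 1:8))
  expect_true(all(c("gene0001", "gene0002", "gene0003") %in%
                    sets$myb_targets))
  expect_true("gene0001" %in% sets$drought_targets)  # TAACTG is drought MBS
  # category logic on a deterministic hit table: CGGTCA alone is a MYB
  # target but not a drought-MBS target
  manual <- data.frame(gene = c("gX", "gY", "gZ")[c(1, 2)],
                       motif = c("MBS_CGGTCA", "MBS_CAACTG"),
                       strand = "+", position = c(10L, 20L),
                       category = c("generic_mbs", "drought_mbs"))
  msets <- putative_target_filter(manual, c("gX", "gY", "gZ"))
  expect_setequal(msets$myb_targets, c("gX", "gY"))
  expect_setequal(msets$drought_targets, "gY")
})

test_that("target filter grows monotonically with the dictionary", {
  proms <- c(g1 = paste0(strrep("G", 100), "TAACTG", strrep("G", 100)),
             g2 = paste0(strrep("G", 100), "CGGTCA", strrep("G", 100)),
             g3 = strrep("G", 206))
  dict_full <- default_motif_dictionary()
  dict_small <- dict_full[dict_full$id == "MBS_TAACTG", ]
  hits_small <- scan_promoters(proms, dict_small)
  hits_full <- scan_promoters(proms, dict_full)
  small_set <- putative_target_filter(hits_small, names(proms), dict_small)
  full_set <- putative_target_filter(hits_full, names(proms), dict_full)
  expect_true(all(small_set$myb_targets %in% full_set$myb_targets))
  expect_false("g3" %in% full_set$myb_targets)
})

test_that("composition-based expected counts follow the closed form", {
  # uniform composition, w = 6, one 1000 bp promoter:
  # per-strand expectation 995 / 4^6
  set.seed(3)
  prom <- c(g = paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                      collapse = ""))
  hits <- scan_promoters(prom)
  e <- motif_enrichment(hits, prom, "MBS_TAACTG")
  # composition is estimated from the sequence, so compare to its own comp
  comp <- table(strsplit(prom, "")[[1]])[c("A", "C", "G", "T")] / 1000
  p_plus <- prod(comp[strsplit("TAACTG", "")[[1]]])
  p_minus <- prod(comp[strsplit("CAGTTA", "")[[1]]])
  expect_equal(e$expected, 995 * (p_plus + p_minus), tolerance = 1e-12)
  expect_equal(round(995 * (1 / 4)^6, 4), 0.2429)  # uniform closed form
  expect_equal(e$n_positions, 2 * 995)
  expect_error(motif_enrichment(hits, prom, "NOPE"), "not in dictionary")
})

test_that("planted excess is significant, absence is not", {
  set.seed(41)
  plants <- data.frame(
    gene = sprintf("gene%04d", 1:10),
    motif = "MBS_TAACTG", strand = "+",
    position = as.integer(seq(10, 900, length.out = 10)))
  # AT-skewed composition keeps spurious background sites rare, so the
  # planted excess dominates the binomial test
  cfg <- synthetic_config(n_genes = 20, module_sizes = integer(0),
                          planted_motifs = plants, seed = 41,
                          base_composition = c(A = 0.7, C = 0.1,
                                               G = 0.1, T = 0.1))
  sim <- generate_expression(cfg)
  pr <- generate_promoters(sim$truth, cfg)
  hits <- scan_promoters(pr$promoters)
  e <- motif_enrichment(hits, pr$promoters, "MBS_TAACTG")
  expect_gte(e$observed, 10)
  expect_lt(e$p_value, 0.001)

  empty_hits <- hits[hits$motif == "none", ]
  e0 <- motif_enrichment(empty_hits, pr$promoters, "MBS_CAACTG")
  expect_equal(e0$observed, 0)
  expect_equal(e0$p_value, 1)  # zero observed is left of the mean
})

test_that("proximal/distal split anchors at the promoter 3' end", {
  hits <- data.frame(gene = c("g", "g"), motif = "MBS_TAACTG",
                     strand = "+", position = c(990L, 521L))
  split <- proximal_distal_split(hits, promoter_length = 1000, window = 200)
  expect_equal(split$n_proximal, 1L)  # 990 > 800
  expect_equal(split$n_distal, 1L)    # 521 <= 800
  expect_equal(split$proximal_fraction, 0.5)

  # uniformly planted positions -> proximal fraction ~ window / L
  set.seed(61)
  pos <- sample.int(995, 4000, replace = TRUE)
  u <- data.frame(gene = "g", motif = "MBS_TAACTG", strand = "+",
                  position = pos)
  s <- proximal_distal_split(u, 1000, 200)
  p0 <- 195 / 995  # positions > 800 among 1..995
  sigma <- sqrt(p0 * (1 - p0) / 4000)
  expect_lt(abs(s$proximal_fraction - p0), 3 * sigma)
})

test_that("category counts are conserved and unknown motifs rejected", {
  hits <- data.frame(
    gene = c("g1", "g1", "g1"),
    motif = c("MBS_TAACTG", "MBS_TAACTG", "MBS_CGGTCA"),
    strand = "+", position = c(10L, 50L, 100L),
    category = c("drought_mbs", "drought_mbs", "generic_mbs"))
  cats <- categorize_hits(hits)
  expect_equal(unname(cats$overall["drought_mbs"]), 2L)
  expect_equal(unname(cats$overall["generic_mbs"]), 1L)
  expect_equal(sum(cats$overall), nrow(hits))

  empty <- hits[0, ]
  expect_equal(sum(categorize_hits(empty)$overall), 0L)

  bad <- hits
  bad$motif[1] <- "MYSTERY"
  expect_error(categorize_hits(bad), "unknown motif")
})
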