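test_that("zero-noise modules give |PCC| = 1 with sign symmetry", {
  cfg <- synthetic_config(n_genes = 20, module_sizes = c(5L, 5L),
                          noise_sd = 0, anticorrelated_fraction = 0,
                          n_conditions = 4, replicates_per_condition = 2,
                          seed = 3)
  sim <- generate_expression(cfg)
  members <- names(sim$truth$module_of_gene)[
    sim$truth$module_of_gene == "M01"]
  r <- stats::cor(t(sim$expr$values[members, ]))
  expect_equal(unname(r), matrix(1, 5, 5))

  cfg2 <- synthetic_config(n_genes = 10, module_sizes = c(6L),
                           noise_sd = 0, anticorrelated_fraction = 0.5,
                           n_conditions = 4, replicates_per_condition = 2,
                           seed = 3)
  sim2 <- generate_expression(cfg2)
  flipped <- names(sim2$truth$sign_of_gene)[sim2$truth$sign_of_gene == -1]
  straight <- setdiff(
    names(sim2$truth$module_of_gene)[sim2$truth$module_of_gene == "M01"],
    flipped)
  expect_equal(
    stats::cor(sim2$expr$values[flipped[1], ],
               sim2$expr$values[straight[1], ]),
    -1)
})

test_that("latent-factor loading calibrates within-module |PCC| to target", {
  # Monte-Carlo check of lambda^2 / (lambda^2 + sigma^2) = r over many pairs
  cfg <- synthetic_config(n_genes = 80, module_sizes = rep(8L, 10),
                          within_module_correlation = 0.9,
                          anticorrelated_fraction = 0,
                          n_conditions = 10, replicates_per_condition = 2,
                          seed = 11)
  pccs <- c()
  for (s in 1:4) {
    cfg$seed <- 10 + s
    sim <- generate_expression(cfg)
    for (m in sprintf("M%02d", 1:10)) {
      members <- names(sim$truth$module_of_gene)[
        sim$truth$module_of_gene == m]
      r <- stats::cor(t(sim$expr$values[members, ]))
      pccs <- c(pccs, abs(r[upper.tri(r)]))
    }
  }
  expect_gt(length(pccs), 1000)
  expect_gt(mean(pccs), 0.85)
  expect_lt(mean(pccs), 0.95)
})

test_that("generator is deterministic and validates its config", {
  cfg <- synthetic_config(seed = 42)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth$module_of_gene, b$truth$module_of_gene)

  expect_error(synthetic_config(module_sizes = c(2L, 10L)), "below 3")
  expect_error(synthetic_config(n_genes = 10, module_sizes = c(8L, 8L)),
               "exceeds")
  expect_equal(cfg$n_background_genes + sum(cfg$module_sizes), cfg$n_genes)
})

test_that("planted condition effect lands on the recorded genes", {
  cfg <- synthetic_config(n_genes = 50, module_sizes = integer(0),
                          n_conditions = 2, replicates_per_condition = 3,
                          noise_sd = 0.1, n_deg_genes = 5, deg_effect = 3,
                          seed = 9)
  sim <- generate_expression(cfg)
  expect_length(sim$truth$deg_genes, 5)
  des <- sim$expr$design
  trt <- des$sample[des$condition == sim$truth$deg_condition]
  ctl <- des$sample[des$condition != sim$truth$deg_condition]
  shift <- rowMeans(sim$expr$values[, trt]) -
    rowMeans(sim$expr$values[, ctl])
  expect_true(all(shift[sim$truth$deg_genes] > 2))
  expect_true(all(abs(shift[setdiff(names(shift), sim$truth$deg_genes)]) < 1))
})

test_that("annotations cover the configured module fraction", {
  cfg <- synthetic_config(n_genes = 40, module_sizes = c(10L, 10L),
                          annotation_coverage = 0.5, n_noise_terms = 0,
                          seed = 5)
  sim <- generate_expression(cfg)
  ann <- generate_annotations(sim$truth, cfg)
  expect_length(ann$annotations$term_genes, 2)  # no noise terms
  for (m in c("M01", "M02")) {
    term <- ann$truth$term_of_module[m]
    members <- names(sim$truth$module_of_gene)[
      sim$truth$module_of_gene == m]
    annotated <- ann$annotations$term_genes[[term]]
    expect_length(annotated, 5)  # coverage 0.5 of 10, forced count
    expect_true(all(annotated %in% members))
  }

  cfg$annotation_coverage <- 1.0
  full <- generate_annotations(sim$truth, cfg)
  members <- names(sim$truth$module_of_gene)[
    sim$truth$module_of_gene == "M01"]
  expect_setequal(
    full$annotations$term_genes[[full$truth$term_of_module["M01"]]],
    members)

  cfg$annotation_coverage <- 0.1
  expect_warning(generate_annotations(sim$truth, cfg), "at least two")
})

test_that("promoters carry planted motifs verbatim at recorded coordinates", {
  plants <- data.frame(
    gene = c("gene0001", "gene0002"),
    motif = c("MBS_TAACTG", "MBS_CAACTG"),
    strand = c("+", "-"),
    position = c(521L, 100L))
  cfg <- synthetic_config(n_genes = 10, module_sizes = integer(0),
                          planted_motifs = plants, seed = 2)
  sim <- generate_expression(cfg)
  pr <- generate_promoters(sim$truth, cfg)
  s1 <- as.character(pr$promoters[["gene0001"]])
  s2 <- as.character(pr$promoters[["gene0002"]])
  expect_equal(substr(s1, 521, 526), "TAACTG")
  expect_equal(substr(s2, 100, 105), "CAGTTG")  # reverse complement
  expect_equal(nrow(pr$truth$planted_hits), 2)
  expect_equal(Biostrings::width(pr$promoters),
               rep(1000L, 10), ignore_attr = TRUE)
})

test_that("overlapping or out-of-range plants are rejected", {
  bad_overlap <- data.frame(gene = c("gene0001", "gene0001"),
                            motif = c("MBS_TAACTG", "MBS_CAACTG"),
                            strand = c("+", "+"),
                            position = c(100L, 103L))
  cfg <- synthetic_config(n_genes = 5, module_sizes = integer(0),
                          planted_motifs = bad_overlap, seed = 2)
  sim <- generate_expression(cfg)
  expect_error(generate_promoters(sim$truth, cfg), "overlapping")

  bad_pos <- data.frame(gene = "gene0001", motif = "MBS_TAACTG",
                        strand = "+", position = 997L)
  cfg2 <- synthetic_config(n_genes = 5, module_sizes = integer(0),
                           planted_motifs = bad_pos, seed = 2)
  sim2 <- generate_expression(cfg2)
  expect_error(generate_promoters(sim2$truth, cfg2), "outside")
})

test_that("spurious background motif counts follow the binomial model", {
  # uniform composition, w = 6: per-strand expectation n_pos / 4^6
  cfg <- synthetic_config(n_genes = 10, module_sizes = integer(0),
                          promoter_length = 1000, seed = 31)
  sim <- generate_expression(cfg)
  pr <- generate_promoters(sim$truth, cfg)
  hits <- scan_promoters(pr$promoters)
  for (strand in c("+", "-")) {
    obs <- sum(hits$motif == "MBS_TAACTG" & hits$strand == strand)
    n_pos <- 10 * (1000 - 6 + 1)
    expected <- n_pos * (1 / 4)^6
    sigma <- sqrt(n_pos * (1 / 4)^6 * (1 - (1 / 4)^6))
    expect_lt(abs(obs - expected), 3 * sigma + 1e-9)
  }
})

test_that("written study files round-trip through the readers", {
  plants <- data.frame(gene = "gene0001", motif = "MBS_TAACTG",
                       strand = "+", position = 10L)
  cfg <- synthetic_config(n_genes = 12, module_sizes = c(6L),
                          planted_motifs = plants, seed = 8)
  sim <- generate_expression(cfg)
  ann <- generate_annotations(sim$truth, cfg)
  pr <- generate_promoters(ann$truth, cfg)
  bundle <- list(expr = sim$expr, truth = pr$truth,
                 annotations = ann$annotations, promoters = pr$promoters)
  dir <- withr::local_tempdir()
  write_synthetic(bundle, dir)
  expr2 <- read_expression(file.path(dir, "expression.tsv"),
                           file.path(dir, "design.tsv"))
  expect_equal(expr2$values, sim$expr$values, tolerance = 1e-12)
  ann2 <- read_annotations(file.path(dir, "annotations.tsv"),
                           universe = rownames(sim$expr$values))
  expect_equal(ann2$term_genes, bundle$annotations$term_genes)
  prom2 <- read_promoters(file.path(dir, "promoters.fasta"))
  expect_equal(as.character(prom2), as.character(bundle$promoters))
})
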