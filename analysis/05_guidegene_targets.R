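#!/usr/bin/env Rscript
# Guide-gene workflow: mutual-rank expansion (MR <= 5, r >= 0.6, two
# hierarchy levels) from one guide gene per planted module, promoter
# scanning of the expanded genes against the MYB cis-element dictionary,
# and nomination of first-neighbour putative targets, with the
# drought-inducibility MBS subset and proximal/distal summary.

suppressMessages(library(mybcoexp))
suppressMessages(library(jsonlite))

expr <- read_expression("results/data/expression.tsv",
                        "results/data/design.tsv")
promoters <- read_promoters("results/data/promoters.fasta")
truth <- fromJSON("results/data/truth.json")
module_truth <- unlist(truth$module_of_gene)

guides <- vapply(c("M01", "M02", "M03", "M04"), function(m) {
  names(module_truth)[module_truth == m][1]
}, character(1))
cat("guides:", paste(guides, collapse = ", "), "\n")

gg <- run_guidegene(expr, guides, promoters, outdir = "results/guidegene")
print(gg$guide_net)
cat(sprintf("putative targets: %d of %d first neighbours carry >= 1 MYB site; %d carry a drought MBS\n",
            gg$manifest$n_myb_targets, gg$manifest$n_first_neighbours,
            gg$manifest$n_drought_targets))
print(head(gg$targets, 8))

cats <- categorize_hits(gg$hits)
cat("cis-element category counts over the guide network promoters:\n")
print(cats$overall)

drought <- gg$hits[gg$hits$category == "drought_mbs", ]
split <- proximal_distal_split(drought, promoter_length = 1000)
cat(sprintf("drought MBS positions: %.0f%% distal (> 200 bp from the anchor), %.0f%% proximal\n",
            100 * split$distal_fraction, 100 * split$proximal_fraction))
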