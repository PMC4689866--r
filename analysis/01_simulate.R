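#!/usr/bin/env Rscript
# Generate the synthetic study all downstream analyses run on: a log2
# expression compendium (10 conditions x 3 replicates) with four planted
# co-expression modules (10/15/20/25 genes, target within-module |PCC| 0.9,
# 10% anti-correlated members) among 130 background genes, module-aligned
# annotation terms plus 10 noise terms, and 1 kb promoters with 30 MYB
# cis-elements planted in module genes at known positions/strands.

suppressMessages(library(mybcoexp))

seed <- 1L
out <- "results/data"

cfg <- synthetic_config(seed = seed)
sim <- generate_expression(cfg)
ann <- generate_annotations(sim$truth, cfg)

# plant motifs in module members so the guide-gene workflow has targets
set.seed(seed + 7L)
module_genes <- names(sim$truth$module_of_gene)[
  sim$truth$module_of_gene != "background"]
dict <- default_motif_dictionary()
plants <- data.frame(
  gene = sample(module_genes, 30),
  motif = sample(dict$id, 30, replace = TRUE),
  strand = sample(c("+", "-"), 30, replace = TRUE),
  position = sample(100:900, 30))
cfg$planted_motifs <- plants
pr <- generate_promoters(ann$truth, cfg)

write_synthetic(list(expr = sim$expr, truth = pr$truth,
                     annotations = ann$annotations,
                     promoters = pr$promoters), out)

cat(sprintf("simulated %d genes x %d samples; %d planted modules; %d terms; %d planted motifs\n",
            nrow(sim$expr$values), ncol(sim$expr$values),
            length(cfg$module_sizes),
            length(ann$annotations$term_genes), nrow(plants)))
cat("written to", out, "\n")

# companion two-condition study for the differential-expression analysis:
# 20 genes with a planted +2 log2 effect among 180 null genes, 3v3
cfg_deg <- synthetic_config(n_genes = 200, module_sizes = integer(0),
                            n_conditions = 2, replicates_per_condition = 3,
                            noise_sd = 0.2, n_deg_genes = 20,
                            deg_effect = 2.0, seed = seed + 100L)
sim_deg <- generate_expression(cfg_deg)
write_synthetic(list(expr = sim_deg$expr, truth = sim_deg$truth),
                "results/data_deg")
cat(sprintf("DEG study: %d planted effects among %d genes, written to results/data_deg\n",
            length(sim_deg$truth$deg_genes), nrow(sim_deg$expr$values)))
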