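#!/usr/bin/env Rscript
# Degree-based hub calling (degree >= 5) on the 0.85 network, the ego
# subnetwork of the best-connected hub, and a differential-expression
# overlay contrasting the first and last conditions of the design.

suppressMessages(library(mybcoexp))

expr <- read_expression("results/data/expression.tsv",
                        "results/data/design.tsv")
corr <- pearson_all_pairs(expr)
net <- build_network(corr, 0.85)

hubs <- find_hubs(net, min_hub_degree = 5)
write.table(hubs, "results/topdown/hubs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d hub genes (degree >= 5) among %d network genes\n",
            nrow(hubs), length(net$nodes)))
print(head(hubs, 5))

top <- hubs$gene[1]
ego <- ego_subnetwork(net, top)
cat(sprintf("top hub %s: degree %d (%d positive / %d negative edges), ego subnetwork %d genes\n",
            top, hubs$degree[1], hubs$positive_edges[1],
            hubs$negative_edges[1], length(ego$nodes)))
write_network(ego, graphml_path = "results/topdown/top_hub_ego.graphml")

# differential expression on the dedicated two-condition study
suppressMessages(library(jsonlite))
deg_expr <- read_expression("results/data_deg/expression.tsv",
                            "results/data_deg/design.tsv")
deg_truth <- fromJSON("results/data_deg/truth.json")
degs <- call_degs(deg_expr, "cond01", "cond02")
write.table(degs, "results/topdown/degs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
called <- degs$gene[degs$is_de]
cat(sprintf("DEG calling (cond02 vs cond01): %d called at |log2FC| >= 1.5 & adj p < 0.05; recall of %d planted effects = %.2f, false positives = %d\n",
            length(called), length(deg_truth$deg_genes),
            mean(deg_truth$deg_genes %in% called),
            sum(!called %in% deg_truth$deg_genes)))
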