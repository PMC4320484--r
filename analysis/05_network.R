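#!/usr/bin/env Rscript
## Relevance networks: sPLS-similarity bipartite network (predictors vs
## physiology) and the pairwise-correlation network at |r| >= 0.9, merged
## with per-edge provenance and exported as SIF and GraphML.

library(starveomics)
library(jsonlite)

study <- read_study("results/data")
truth <- read_json("results/data/truth.json", simplifyVector = TRUE)
design <- study$design
dir.create("results/network", showWarnings = FALSE, recursive = TRUE)

nsaf <- read_feature_tsv("results/quantified/nsaf_filtered.tsv")$values
met <- read_feature_tsv("results/quantified/metabolites_normalized.tsv")$values
phys <- read_feature_tsv("results/quantified/physiology_normalized.tsv")$values

pred <- merge_blocks(log_transform(nsaf), log_transform(met),
                     matrix(numeric(0), 0, nrow(design),
                            dimnames = list(NULL, design$sample_id)), design)
x_pred <- autoscale(t(pred$values))
phys_p <- phys
rownames(phys_p) <- paste0("physiology:", rownames(phys_p))
y_phys <- autoscale(t(phys_p))

model <- spls(x_pred, y_phys, ncomp = 3, keepX = 50)
blocks <- setNames(as.character(sub(":.*", "", c(rownames(pred$values),
                                                 rownames(phys_p)))),
                   c(rownames(pred$values), rownames(phys_p)))
sim <- spls_similarity(model, x_pred, y_phys)
net_spls <- threshold_network(sim, 0.9, blocks, provenance = "spls-similarity")

cc <- suppressWarnings(pairwise_correlation(t(x_pred)))
net_cor <- threshold_network(cc, 0.9, blocks)

combined <- merge_networks(net_spls, net_cor)
write_sif(combined, "results/network/network_edges.sif")
write_graphml(combined, "results/network/network.graphml")
write.table(combined$nodes, "results/network/node_attributes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("sPLS-similarity edges: %d; correlation edges (|r| >= 0.9): %d\n",
            nrow(net_spls$edges), nrow(net_cor$edges)))
cat(sprintf("Combined network: %d nodes, %d edges -> results/network/\n",
            nrow(combined$nodes), nrow(combined$edges)))
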