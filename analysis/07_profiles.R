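#!/usr/bin/env Rscript
## Functional-bin time profiles (percent of maximum) for the differential
## proteins, and biclustering of the bin means against the timepoints.

library(starveomics)
library(jsonlite)

study <- read_study("results/data")
truth_raw <- read_json("results/data/truth.json", simplifyVector = TRUE)
design <- study$design
dir.create("results/profiles", showWarnings = FALSE, recursive = TRUE)

nsaf <- read_feature_tsv("results/quantified/nsaf_filtered.tsv")$values
kw <- read.delim("results/stats/proteins_kruskal_wallis.tsv")
sig <- paste0("protein:", kw$feature_id[kw$p_adjusted <= 0.05])

prof <- percent_of_max(nsaf, design)
rownames(prof) <- paste0("protein:", rownames(prof))
write_feature_tsv(prof, "results/profiles/percent_of_max.tsv")

truth <- list(responders = truth_raw$responders,
              block_memberships = unlist(truth_raw$block_memberships),
              starved_timepoints = truth_raw$starved_timepoints)
binmap <- synthetic_bin_map(truth)
agg <- bin_aggregate(prof, binmap, significant = sig)
write.table(agg$profile, "results/profiles/bin_profiles.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

bm <- reshape(agg$profile[, c("bin", "timepoint", "mean")], idvar = "bin",
              timevar = "timepoint", direction = "wide")
rn <- bm$bin
bm <- as.matrix(bm[, -1])
dimnames(bm) <- list(rn, sort(unique(agg$profile$timepoint)))
heat <- bicluster_heatmap(bm)
write_feature_tsv(heat$matrix, "results/profiles/heatmap_matrix.tsv", "bin")
writeLines(c(as_newick(heat$row_hclust), as_newick(heat$col_hclust)),
           "results/profiles/dendrograms.nwk")

cl <- cutree(heat$col_hclust, k = 2)
grp <- ifelse(as.numeric(names(cl)) %in% truth$starved_timepoints,
              "starved", "replete")
cat(sprintf("%d differential proteins profiled into %d bins (%d unmapped)\n",
            length(intersect(rownames(prof), sig)),
            length(unique(agg$profile$bin)), length(agg$unmapped)))
cat("Timepoint clusters (k = 2):",
    paste(sprintf("%sh:%d", names(cl), cl), collapse = " "), "\n")
cat("Matches the planted starved/replete partition:",
    all(tapply(grp, cl, function(g) length(unique(g)) == 1)), "\n")
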