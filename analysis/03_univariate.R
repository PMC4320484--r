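#!/usr/bin/env Rscript
## Per-feature significance: Kruskal-Wallis on log2 NSAF for proteins;
## one-way ANOVA + Tukey HSD with compact letters for metabolites and
## physiology; BH adjustment within each block. Compares the flagged set
## against the planted responders.

library(starveomics)
library(jsonlite)

study <- read_study("results/data")
truth <- read_json("results/data/truth.json", simplifyVector = TRUE)
design <- study$design
groups <- factor(design$timepoint)
dir.create("results/stats", showWarnings = FALSE, recursive = TRUE)

nsaf <- read_feature_tsv("results/quantified/nsaf_filtered.tsv")$values
met <- read_feature_tsv("results/quantified/metabolites_normalized.tsv")$values
phys <- read_feature_tsv("results/quantified/physiology_normalized.tsv")$values

kw <- kruskal_wallis(log_transform(nsaf), groups)
write.table(kw, "results/stats/proteins_kruskal_wallis.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

met_stats <- anova_tukey(log_transform(met), groups)
write.table(met_stats, "results/stats/metabolites_anova_tukey.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
phys_stats <- anova_tukey(phys, groups)
write.table(phys_stats, "results/stats/physiology_anova_tukey.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

sig <- kw$feature_id[kw$p_adjusted <= 0.05]
resp <- truth$responders$feature_id
cat(sprintf("Proteins significant at BH 0.05: %d of %d tested\n",
            length(sig), nrow(kw)))
cat(sprintf("Planted responders recovered: %.0f%% (%d of %d)\n",
            100 * mean(resp %in% sig), sum(resp %in% sig), length(resp)))
cat(sprintf("Metabolites significant: %d of %d; physiology: %d of %d\n",
            sum(met_stats$p_adjusted <= 0.05), nrow(met_stats),
            sum(phys_stats$p_adjusted <= 0.05), nrow(phys_stats)))
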