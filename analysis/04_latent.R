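#!/usr/bin/env Rscript
## Multivariate stage: autoscaling, PCA of the merged blocks, PLS-DA on the
## timepoint classes, and sparse PLS in regression mode with proteins and
## metabolites as predictors of the physiological variables.

library(starveomics)
library(jsonlite)

study <- read_study("results/data")
truth <- read_json("results/data/truth.json", simplifyVector = TRUE)
design <- study$design
dir.create("results/latent", showWarnings = FALSE, recursive = TRUE)

nsaf <- read_feature_tsv("results/quantified/nsaf_filtered.tsv")$values
met <- read_feature_tsv("results/quantified/metabolites_normalized.tsv")$values
phys <- read_feature_tsv("results/quantified/physiology_normalized.tsv")$values

merged <- merge_blocks(log_transform(nsaf), log_transform(met), phys, design)
x_all <- autoscale(t(merged$values))

pca_model <- pca(x_all, ncomp = 3)
write_latent_model(pca_model, "results/latent")
plsda_model <- plsda(x_all, factor(design$timepoint), ncomp = 3)
write_latent_model(plsda_model, "results/latent")

pred <- merge_blocks(log_transform(nsaf), log_transform(met),
                     matrix(numeric(0), 0, nrow(design),
                            dimnames = list(NULL, design$sample_id)), design)
x_pred <- autoscale(t(pred$values))
phys_p <- phys
rownames(phys_p) <- paste0("physiology:", rownames(phys_p))
y_phys <- autoscale(t(phys_p))
spls_model <- spls(x_pred, y_phys, ncomp = 3, keepX = 50)
write_latent_model(spls_model, "results/latent")

sel <- rownames(spls_model$weights)[rowSums(spls_model$weights != 0) > 0]
planted <- names(truth$block_memberships)
planted <- planted[!grepl("^physiology", planted)]
cat(sprintf("PCA variance explained: %s\n",
            paste(sprintf("%.1f%%", 100 * pca_model$explained_variance),
                  collapse = ", ")))
cat(sprintf("sPLS selected %d predictors over 3 components; recovers %.0f%% of the planted predictive block\n",
            length(sel), 100 * mean(planted %in% sel)))
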