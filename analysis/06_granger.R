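#!/usr/bin/env Rscript
## Lag-1 Granger causality. First on the powered standalone series (T = 50)
## where the planted couplings are recoverable, then on replicate-mean
## series of the study itself (T = 6), where results rest on 2 residual
## degrees of freedom and must be treated carefully.

library(starveomics)
library(jsonlite)

study <- read_study("results/data")
truth <- read_json("results/data/truth.json", simplifyVector = TRUE)
dir.create("results/granger", showWarnings = FALSE, recursive = TRUE)

## powered series
res <- granger_all_pairs(study$series, lag = 1, alpha = 0.05)
write.table(res, "results/granger/series_T50.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_granger_sif(res, "results/granger/series_T50_edges.sif")
hits <- merge(truth$causal_pairs, res, by = c("driver", "target"))
cat(sprintf("T=50 series: %d ordered tests, %d BH-significant; %d/%d planted pairs recovered\n",
            sum(!res$degenerate), sum(res$significant),
            sum(hits$significant), nrow(hits)))

## study series (replicate means over 6 timepoints)
nsaf <- read_feature_tsv("results/quantified/nsaf_filtered.tsv")$values
kw <- read.delim("results/stats/proteins_kruskal_wallis.tsv")
sig <- kw$feature_id[kw$p_adjusted <= 0.05]
phys <- read_feature_tsv("results/quantified/physiology_normalized.tsv")$values
mat <- rbind(log_transform(nsaf[sig, , drop = FALSE]), phys)
series <- prepare_series(mat, study$design)
res6 <- withCallingHandlers(
  granger_all_pairs(series, lag = 1, alpha = 0.05),
  warning = function(w) { cat("note:", conditionMessage(w), "\n")
                          invokeRestart("muffleWarning") })
write.table(res6, "results/granger/study_T6.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Study series (T=6): %d tests, %d BH-significant\n",
            sum(!res6$degenerate), sum(res6$significant)))
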