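#!/usr/bin/env Rscript
## Generate the synthetic nitrogen-starvation/recovery study: spectral-count
## proteome, metabolite peak areas, physiology, standalone causal series,
## and the ground-truth record used by the later scripts.

library(starveomics)

params <- sim_params()           # study defaults; see ?sim_params
study <- simulate_study(params, seed = 1)
write_study(study, "results/data", params = params)

cat("Simulated study written to results/data/\n")
cat(sprintf("  %d proteins x %d samples (~%d PSM/sample)\n",
            nrow(study$proteome$counts), ncol(study$proteome$counts),
            round(mean(colSums(study$proteome$counts)))))
cat(sprintf("  %d metabolites (%d cells blanked), %d physiology variables\n",
            nrow(study$metabolites), sum(is.na(study$metabolites)),
            nrow(study$physio)))
cat(sprintf("  %d planted responders, %d latent-block members, %d causal pairs\n",
            nrow(study$truth$responders),
            length(study$truth$block_memberships),
            nrow(study$truth$causal_pairs)))
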