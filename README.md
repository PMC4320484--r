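# starveomics

Multi-omics quantification, integration and network inference for
nutrient-starvation/recovery time courses.

Experiments that starve a microalga of nitrogen and then replenish it
produce three small, linked data blocks — spectral-count proteomics, GC-MS
metabolite peak areas and physiological measurements (Fv/Fm, fresh weight,
lipids) — across a handful of timepoints with a few biological replicates.
`starveomics` implements the complete analysis chain for such designs, from
raw counts to networks, with a ground-truth synthetic-data generator so
every stage is validated by parameter recovery.

The core quantitation is the normalized spectral abundance factor: for
protein *k* with length *L<sub>k</sub>* and spectral count
*PSM<sub>ks</sub>* in sample *s*,

```
NSAF_ks = (PSM_ks / L_k) / Σ_i (PSM_is / L_i)
```

followed by a minimum-abundance filter (max NSAF ≥ 0.001) and a
replicate-presence rule (detected in all replicates of one timepoint, or in
≥ 5 distinct timepoints). Downstream stages: sample-centric metabolite
normalization with a strict >18-samples presence fallback, sequential
K-nearest-neighbour imputation, Kruskal–Wallis tests on log2 abundances,
one-way ANOVA + Tukey HSD with compact letter displays,
Benjamini–Hochberg correction, autoscaled PCA / PLS-DA / sparse PLS
(regression mode, proteins + metabolites predicting physiology),
relevance networks from sPLS similarities and pairwise correlations at a
|association| ≥ 0.9 cutoff, pairwise lag-1 Granger causality with an
F-test on nested autoregressions, and percent-of-maximum functional-bin
time profiles with Euclidean/complete biclustering.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated study (500 proteins, 50 metabolites, 5 physiology variables,
6 timepoints × 4 replicates) and narrate what they find. An end-to-end run:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_quantify_impute.R
Rscript analysis/03_univariate.R
Rscript analysis/04_latent.R
Rscript analysis/05_network.R
Rscript analysis/06_granger.R
Rscript analysis/07_profiles.R
```

prints, among other things:

```
Proteins: 500 input -> 366 above NSAF 0.001 -> 366 after presence rule
Metabolites: 50 retained; 60 missing cells imputed (sKNN, log scale)
Proteins significant at BH 0.05: 112 of 366 tested
Planted responders recovered: 91% (91 of 100)
sPLS selected 139 predictors over 3 components; recovers 100% of the planted predictive block
Combined network: 73 nodes, 122 edges -> results/network/
T=50 series: 380 ordered tests, 5 BH-significant; 5/5 planted pairs recovered
Study series (T=6): 13572 tests, 0 BH-significant
Timepoint clusters (k = 2): 0h:1 5h:1 24h:2 72h:2 77h:2 96h:1
```

Reading the output: the abundance filter keeps 366 of 500 proteins
(responders planted by the generator sit above the quantitation floor, so
91 of 100 are flagged at BH 0.05); the sparse-PLS predictor sets recover the
whole planted protein–metabolite block that drives physiology; the lag-1
Granger screen finds exactly the five planted causal pairs on powered
(T = 50) series while the 6-timepoint study series yield none — with two
residual degrees of freedom that screen is honest about being underpowered;
and biclustering splits the timepoints into deep-starvation (24, 72, 77 h)
versus control-like (0, 5, 96 h) groups, the structure the generator
plants. Equivalent single-call orchestration, with every intermediate table
and a JSON run log:

```r
library(starveomics)
report <- run_pipeline(list(seed = 1), outdir = "run1")
```

The methods vignette (`vignettes/starvation-recovery-workflow.Rmd`)
documents the models, parameter choices, evaluation design and known
limitations.

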