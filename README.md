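# blastoHet

Transcriptomic heterogeneity analysis of cleavage-stage blastomeres from
single-cell RNA-seq.

## What it is for

In 2- to 8-cell mouse embryos, lineage segregation begins when a minority of
blastomeres advance transcriptionally toward the next developmental state.
This package provides the full analysis chain used to detect that
subpopulation and to quantify how perturbations (e.g. knockout of a
regulator, or exposure to its agonist) suppress inter-blastomere
heterogeneity:

* **Synthetic blastomere counts** (`sim_config()`, `simulate_counts()`,
  `inject_variable_genes()`) — negative-binomial genes × cells matrices for
  a conditions × stages × embryos design, with planted stage programs, a
  differentiating subpopulation, marker genes, heterogeneity knobs and full
  ground truth.
* **QC and normalization** (`qc_filter_cells()`, `tpm_normalize()`,
  `expressed_gene_set()`) — detected-gene and MAD library-size filters; TPM
  (`1e6 · (counts/length)/Σ(counts/length)`) and `log2(TPM+1)`.
* **Correlation clustering** (`pearson_correlation_matrix()`,
  `hierarchical_cluster()` with `1 − r` distance, `cut_tree()`,
  `stage_similarity()`, `stage_similarity_permutation_test()`) — the
  cell–cell Pearson heterogeneity readout: the higher the between-stage
  correlation coefficient, the less heterogeneous the population.
* **Subpopulation classification** (`classify_blastomeres()`,
  `differentiating_fraction_test()`) — consensus of correlation-cluster
  membership and position along a fitted developmental axis labels each
  blastomere `embryonic`, `differentiating`, or `excluded` on mismatch;
  per-embryo fractions are compared across conditions by ANOVA with Welch
  post-hoc tests.
* **Variable genes** (`fit_cv2_trend()`, `call_variable_genes()`,
  `compare_hvg_counts()`) — the overdispersion trend **CV² = a₁/μ + a₀**
  fitted by gamma GLM; genes tested by `(n−1)·CV²obs/CV²trend ~ χ²(n−1)`
  and flagged at FDR < 0.1.
* **DE, overlap, enrichment** (`differential_expression()`,
  `overlap_test()`, `overrepresentation()`, `consensus_enrichment()`,
  `read_gmt()`) — Welch DE on log₂TPM, hypergeometric variable∩DE overlap,
  and GMT over-representation with a six-cutoff consensus rule.
* **Trajectory** (`estimate_size_factors()`, `build_trajectory()`,
  `branch_composition_test()`) — PCA + minimum-spanning-tree principal
  tree with pseudotime from a 2-cell root and hypergeometric branch
  composition tests.

Everything operates on a Bioconductor
`SingleCellExperiment` (assay `counts`, plus `tpm` / `logtpm` after
normalization; `condition`, `stage`, `embryo_id` in `colData`).

## Worked example

Simulate a wild-type vs knockout contrast (knockout heterogeneity scale
0.5, i.e. suppressed cell-to-cell variability; 25% differentiating 4-cell
subpopulation planted in WT only), then run the chain:

```r
library(blastoHet)
cfg <- sim_config(conditions = c("WT", "KO"),
                  heterogeneity_scale = c(WT = 1, KO = 0.5),
                  n_lowdepth_cells = 0, seed = 3)
sce  <- simulate_counts(cfg)          # 2000 genes x 144 cells
norm <- tpm_normalize(sce)
expressed <- expressed_gene_set(norm) # TPM >= 1

## classify blastomeres and compare per-embryo fractions
cls <- classify_blastomeres(norm)
ft  <- differentiating_fraction_test(
  cls, as.data.frame(SummarizedExperiment::colData(sce)))
subset(ft$counts, stage == 4)
#>   condition stage n_embryonic n_differentiating n_excluded percent_differentiating
#> 2        KO     4          32                 0          0                       0
#> 5        WT     4          15                 8          9                      25
ft$tests[["4"]]$posthoc$p
#> [1] 0.007220217

## heterogeneity: knockout 4-cell cells correlate more with 2-cell cells
stage_similarity_permutation_test(norm, expressed, 4, 2,
                                  n_perm = 199, seed = 0)
#>   condition    mean_r ref_mean_r      delta     p
#> 1        KO 0.7733666  0.7460122 0.02735444 0.005
```

The classification recovers the planted subpopulation exactly (8 of 8
differentiating WT 4-cell blastomeres; 25% of the group), calls none in the
knockout, and the embryo-level fraction test flags the difference
(p ≈ 0.007). The permutation test shows the knockout's higher between-stage
correlation (Δr ≈ +0.027, p = 0.005) — less heterogeneity when the
regulator is disrupted.

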