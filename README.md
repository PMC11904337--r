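# pbconsensus

Consensus pseudobulk differential expression for droplet scRNA-seq
case–control cohorts.

Multiplexed droplet studies of patient cohorts (e.g. PBMC profiling of
psoriatic-arthritis patients and healthy controls) need per-gene,
per-cell-type differential expression that respects the sample — not the
cell — as the unit of replication, and that is robust to the idiosyncrasies
of any single DE model and to ambient-RNA contamination. `pbconsensus`
implements that full path:

1. **Cell-level QC** — cells with `< 500` UMIs or `< 200` detected genes are
   removed; the per-sample mitochondrial cap is the 95th percentile of
   mitochondrial content rounded up to the nearest of 20/25/30/35%; cells
   with hemoglobin content `> 0.1%` are removed; within-sample doublets are
   flagged by an artificial-doublet kNN score at a fixed expected rate
   (default 2%).
2. **Ambient-RNA gene metric** — for each sequencing batch, per-gene counts
   are aggregated over barcodes with fewer than 100 total counts (non-viable
   droplets) and converted to within-batch percentile ranks.
3. **Pseudobulk aggregation** — raw counts are summed per (sample, cell
   type); zero-count units are dropped and, per cell type, genes kept only
   if some unit has ≥ 5 expressing cells.
4. **Three DE engines** per cell type and contrast, all returning
   (log2FC, p, BH-adjusted p):
   - `nb_wald` — NB GLM, log link, median-of-ratios size-factor offsets,
     Cox–Reid adjusted ML dispersions shrunk to a mean–dispersion trend,
     Wald test;
   - `nb_exact` — TMM-normalised effective library sizes, conditional-ML
     common + tagwise dispersions, exact NB test conditioning on the gene
     total;
   - `wlm_modt` — log-CPM with lowess mean–variance precision weights,
     weighted least squares, empirical-Bayes moderated t.
5. **Consensus rule** — a gene is significant when
   `|mean log2FC| > 0.5` **and** (adjusted `p < 0.05` in ≥ 2 engines
   **or** adjusted `p < 0.01` in ≥ 1 engine). Genes above the 75th ambient
   percentile are flagged and (by default) excluded from the final set.
6. **PC1 rank fusion** — the three log2FC vectors are column-centred and
   projected on their first principal component (sign-anchored to the mean
   log2FC); the scores rank genes for GSEA.
7. **Pre-ranked GSEA** — weighted Kolmogorov–Smirnov enrichment score,
   gene-sampling permutation null, sign-stratified NES, BH across sets,
   core-enrichment genes and the gene-set ratio (fraction of a pathway that
   is consensus-DEG).
8. **Cohort statistics** — Yates-corrected 2×2 chi-squared and one-way
   ANOVA baseline tables, and PCA of sample-level cell-type fractions.

A synthetic-cohort generator (`simulate_cohort()`) with planted effects,
doublets, empty droplets and batch-shared ambient contamination provides
ground truth for every stage.

## Worked example

Simulate a 3-group, 12-sample cohort (250 cells/sample, 3 cell types,
300 genes) with eight genes perturbed in cell type `CT01` of the `PsA-PsC`
group (six up at log2FC `+2.5`, two down at `−2.5`), then run the full
pipeline for the `PsA-PsC` vs `HC` contrast:

```r
library(pbconsensus)

cfg0 <- sim_config(n_samples_per_group = 4,
                   groups = c("HC", "PsA-only", "PsA-PsC"),
                   n_cell_types = 3, cells_per_sample = 250, n_genes = 300,
                   samples_per_batch = 4, seed = 2024)
mu <- sim_baseline_means(cfg0)
band <- rownames(mu)[rank(rowMeans(mu)) / nrow(mu) >= 0.4 &
                     rank(rowMeans(mu)) / nrow(mu) <= 0.6]
pe <- planted_effects("CT01", band[1:8], "PsA-PsC", "HC",
                      c(rep(2.5, 6), rep(-2.5, 2)))
cfg <- sim_config(n_samples_per_group = 4,
                  groups = c("HC", "PsA-only", "PsA-PsC"),
                  n_cell_types = 3, cells_per_sample = 250, n_genes = 300,
                  planted_effects = pe, samples_per_batch = 4, seed = 2024)
sim <- simulate_cohort(cfg)

run <- run_pipeline(pipeline_config(
  samples = sim$samples, output_dir = file.path(tempdir(), "demo"),
  contrasts = list(c("PsA-PsC", "HC")), seed = 42))
#> load: 6600 barcodes, 300 genes, 12 samples
#> qc: 2624 cells retained
#> pseudobulk: 36 units, 300 genes
#> PsA-PsC_vs_HC / CT01: 8 consensus DEGs
#> PsA-PsC_vs_HC / CT02: 0 consensus DEGs
#> PsA-PsC_vs_HC / CT03: 0 consensus DEGs

degs <- run$results$`PsA-PsC_vs_HC`$consensus
hits <- degs[degs$final_sig, c("cell_type", "gene", "mean_log2FC",
                               "min_adj_p", "pc1_score")]
head(hits[order(-abs(hits$pc1_score)), ], 6)
#>    cell_type     gene mean_log2FC min_adj_p pc1_score
#> 27      CT01 GENE0027        2.32 9.80e-254      3.96
#> 14      CT01 GENE0014        2.30 6.68e-306      3.94
#> 8       CT01 GENE0008        2.28 1.75e-202      3.90
#> 30      CT01 GENE0030        2.27 4.60e-298      3.89
#> 25      CT01 GENE0025        2.19 4.85e-288      3.75
#> 36      CT01 GENE0036       -1.98 1.37e-173     -3.47
```

All eight planted genes — and nothing else — pass the consensus rule, with
estimated fold changes mildly attenuated by the 10% ambient contamination
(planted `|log2FC| = 2.5`, recovered ≈ 2.2–2.3). The `mean_log2FC` column
is the cross-engine mean; `min_adj_p` the best adjusted p-value across
engines; `pc1_score` the PCA-fused ranking score used for GSEA. The output
directory holds headered TSVs per stage (QC report, ambient metric,
pseudobulk units, per-contrast DE/consensus/enrichment tables, RNK files)
and a JSON run manifest; reruns with the same seed are byte-identical.

Positive `log2FC` always means higher expression in the test group (first
element of the contrast) than in the reference.

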