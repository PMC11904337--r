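---
title: "Methods: consensus pseudobulk differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus pseudobulk differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models, the tunable parameters and
their defaults, the numerical choices, and the design decisions behind
`pbconsensus`, together with what the synthetic-data generator does and does
not emulate — and hence what the test suite does and does not demonstrate
about real data.

## The problem

Droplet scRNA-seq cohorts of patients and controls pose three coupled
inference problems. First, the unit of biological replication is the
*sample*, not the cell: cell-level tests treat thousands of correlated cells
as independent and wildly overstate significance. Summing raw counts per
(sample, cell type) — pseudobulk — restores sample-level replication and
makes bulk RNA-seq count models applicable. Second, no single
differential-expression model is uniformly reliable at cohort sample sizes;
requiring agreement among differently-behaved engines trades a little power
for substantial robustness. Third, droplets share a soup of cell-free
transcripts (ambient RNA), so an apparent group difference in a gene that
dominates the soup may be contamination rather than biology.

## Quality control

Per-cell filters, all strict inequalities (a cell exactly at a bound
survives; `qc_thresholds()`):

| parameter | default | meaning |
|---|---|---|
| `min_umi` | 500 | cells with `total_umi < 500` fail |
| `min_genes` | 200 | cells with fewer detected genes fail |
| `mito_cap_grid` | 0.20, 0.25, 0.30, 0.35 | admissible mitochondrial caps |
| `mito_percentile` | 0.95 | percentile defining the per-sample cap |
| `hemo_max` | 0.001 | hemoglobin count fraction above this fails |
| `expected_doublet_rate` | 0.02 | fraction of cells flagged as doublets |

The mitochondrial cap adapts to each sample: the 95th percentile of the
sample's mitochondrial fractions is rounded *up* to the nearest grid value.
Percentiles use the type-7 (linear interpolation) quantile — the most common
default — since the choice is otherwise arbitrary. A percentile above the
largest grid value is capped at 0.35 rather than excluding the sample:
whole-sample exclusion is an operator decision, supported by the per-sample
QC report (which also satisfies the accounting identity
`retained + removed = input`).

Within-sample doublets are scored by a single-pass artificial-nearest-
neighbour analogue: artificial doublets are averages of random pairs of
log-normalised profiles; real and artificial cells are embedded by PCA
(default 10 components); a cell's score is the fraction of artificial
doublets among its `k = 20` nearest neighbours; the top `expected_rate`
fraction of cells is flagged. There is deliberately no neighbourhood-size
sweep — the expected rate is fixed by configuration, and the scorer is a
removal device, not a doublet-biology tool. Counts are filtered before
doublet scoring; the reverse order is equally defensible and unspecified in
the conventions this pipeline follows.

## Ambient-RNA metric and filter

For each batch, counts of every gene are summed over barcodes with total
counts strictly below 100 — droplets too shallow to be viable cells — and
converted to within-batch percentile ranks. Two numerical choices matter:

* **Midranks for ties.** Most genes have zero ambient counts; averaging the
  rank over the zero block keeps it mid-distribution instead of flagging (or
  protecting) the entire block arbitrarily.
* **Exclusion versus annotation.** A consensus DEG whose maximum ambient
  rank across batches strictly exceeds 0.75 is flagged. By default flagged
  genes are excluded from the final significant set but retained in the
  table (`final_sig = FALSE`, `ambient_flag = TRUE`) so the action is
  auditable; `ambient_action = "annotate"` keeps them significant. Whether
  flagged genes should be removed or merely annotated is genuinely open —
  both are supported.

Because ambient counts are pooled expression, their ranks track overall
expression almost perfectly: the rule effectively declares the top
expression quartile untestable. That is inherent to the metric, not an
implementation artifact, and it shapes the recovery studies below.
"Batch" granularity is configurable (`batch_map`); the default is the batch
labels carried by the data, one per sample if unspecified.

## Pseudobulk

Counts are summed per (sample id, cell type); the aggregation conserves the
grand total exactly and is invariant to cell order. Units with zero total
counts are removed. The gene filter reads "observed in fewer than five cells
in such a combination" in its permissive form: a gene is retained for a cell
type if *any* unit of that cell type has ≥ 5 expressing cells. The strict
(every-unit) reading would discard most genes in rare cell types; the
threshold and the reading are both configurable (`min_cells`). Cell types
with fewer than two units in a contrast group are skipped for DE — a
two-sample test with one replicate per side has no residual degrees of
freedom for the moderated-t engine and no dispersion information for the NB
engines.

## The three engines

All engines share the contrast convention `contrast = c(test, reference)`
with `log2FC > 0` meaning higher in the test group, and BH adjustment within
(engine, cell type). They are archetype re-implementations — an NB Wald GLM,
an NB exact test, and a precision-weighted moderated-t — chosen to be
*differently behaved*, because the consensus layer is the point; they are
not bit-compatible clones of any released tool, and the tests validate them
by simulation properties (type-I control, parameter recovery, engine
agreement), not by equality with external software.

**`nb_wald`.** Median-of-ratios size factors (the factors absorb depth, so
the GLM offset is `log(size factor)` alone). Per gene, an NB log-link GLM is
fit by IRLS; the dispersion is estimated by Cox–Reid adjusted profile
likelihood — the adjustment term `½ log det(XᵀWX)` compensates the downward
bias of plain ML caused by estimating the mean parameters, which otherwise
makes the Wald test anti-conservative at n ≈ 8 per group. Gene-wise log
dispersions are shrunk halfway (`shrink_weight = 0.5`) toward a log-linear
mean–dispersion trend; the fixed weight replaces the full empirical-Bayes
machinery of the archetype and is config-exposed. The contrast coefficient
is tested by Wald z.

**`nb_exact`.** TMM factors (double-trimmed, precision-weighted mean of
log-ratios against the unit whose upper-quartile fraction is closest to the
mean; trims 30% on M, 5% on A) define effective library sizes; counts are
scaled to the geometric-mean depth (pseudo-counts). A common dispersion
maximises the conditional likelihood (conditioning on group sums) across
genes; gene-wise conditional-ML dispersions are shrunk toward it on the log
scale with fixed weight 0.5. The two-sided exact test conditions on the
gene's total: the conditional distribution of the test-group sum is computed
over a quantile window (tail mass below 1e−12 truncated; a normal
approximation guards pathologically wide windows), and the p-value sums the
probabilities of all splits at most as likely as the observed one. As the
dispersion approaches zero this reduces to the binomial-conditioned Poisson
exact test, which the suite verifies against a closed-form oracle. Fold
changes come from group mean CPM with a 0.5 prior count.

**`wlm_modt`.** `y = log2((count + 0.5) / (eff_lib + 1) · 10⁶)` with TMM
effective library sizes. A preliminary unweighted fit per gene yields
residual sds; a lowess of `sqrt(sd)` on mean log-count (span 0.5),
interpolated at each observation's predicted log-count, gives
inverse-fourth-power precision weights. Each gene is refit by weighted least
squares; residual variances are shrunk toward a scaled-inverse-chi-square
prior whose degrees of freedom and scale are estimated by moment matching on
the log variances (digamma/trigamma identities), giving moderated t with
augmented degrees of freedom. With weights off and moderation off the
engine is exactly the ordinary equal-variance t-test on log-CPM — the suite
checks this equivalence at 1e−8.

Multiple testing uses Benjamini–Hochberg throughout: it is the shared
default of all three archetypes, and the consensus rule only consumes
adjusted p-values.

## Consensus and PC1 ranking

A gene is consensus-significant when `|log2FC| > 0.5` *and* (adjusted
`p < 0.05` in at least two engines *or* adjusted `p < 0.01` in at least
one). The fold-change gate uses the cross-engine *mean* log2FC by default —
the mean is also the reported effect size — with `any`/`all` variants behind
`lfc_source`. Genes an engine filtered out are treated as non-significant
there and excluded from the PCA ranking, but stay in the table. The rule is
monotone in evidence: lowering any engine's adjusted p can only add genes.

For ranking, the genes × 3 matrix of engine log2FCs is column-centred (not
scaled — the columns share units; `scale_cols = TRUE` is available) and
projected on its first right singular vector. PC1 of a 3-column matrix
always explains ≥ 1/3 of the variance; when engines agree it explains
nearly all of it, and the score is then proportional to the shared centred
log2FC. The sign of a singular vector is arbitrary, so it is anchored by
requiring positive correlation with the mean log2FC; without that anchor,
enrichment directions downstream would flip at random.

## Pre-ranked GSEA

The enrichment score is the signed maximum deviation of the weighted
Kolmogorov–Smirnov running sum (hits weighted by `|score|`, exponent 1;
misses decrement `1/(N − Nh)`). The null is *gene-sampling*: for each set,
`n_perm = 1000` random same-size gene samples from the ranked universe —
phenotype labels no longer exist at the pre-ranked stage, so sample
permutation is not an option. NES normalises by the mean |null ES| of the
matching sign (sign-stratified, the standard convention), and
`p = (1 + #{same-sign nulls at least as extreme}) / (1 + #same-sign nulls)`
respects the `1/(n_perm + 1)` floor by construction. Core-enrichment genes
are the members at or before the peak (after it, for negative ES); the
gene-set ratio reports the fraction of the universe-clipped set that is
consensus-DEG. Set-size bounds default to [10, 500] after universe
intersection. The ranking input is *all* ranked genes by default — the
statistically sound choice, since restricting the universe to DEGs distorts
the null — with a DEG-only restriction available by subsetting the score
vector. Ties in scores are broken by gene id so results are reproducible.

## Cohort statistics

2×2 chi-squared tests apply the Yates continuity correction by default
(each |O − E| reduced by min(0.5, |O − E|)): the uncorrected test on the
canonical sex table `[[5,15],[12,7]]` gives p ≈ 0.016, the corrected one
0.038, and baseline-characteristics tables in this field report the
corrected value. Continuous variables are summarised as median [IQR]
(type-7 quantiles) and tested by classical one-way ANOVA; for two groups F
equals the squared equal-variance t statistic. The cell-type-fraction PCA
centres but does not scale the fraction matrix and guards the
constant-composition case.

## The synthetic cohort generator

`simulate_cohort()` emulates: several groups with equal sample counts;
per-cell-type NB counts (variance `μ + φμ²`, `dispersion` default 0.4) with
mean vectors built from a shared log-normal baseline (sdlog 1.2) plus
disjoint marker boosts (5% of genes, ×6) so cell types separate in PCA
space; planted per-cell-type group effects as `2^log2FC` multipliers;
doublets (default 5%, homotypic or heterotypic with equal probability) as
sums of two singlet draws; per-cell mitochondrial and hemoglobin count
fractions from Beta laws (defaults Beta(2.5, 30) ≈ 7.7% mean mito,
Beta(1, 3000) hemoglobin); per-batch ambient profiles equal to the
library-size-weighted mean of the batch's singlet expression, mixed into
every barcode by binomial thinning plus Poisson draws at `ambient_fraction`
(default 0.10, approximately preserving totals); and empty droplets (totals
strictly < 100 by construction) drawn from the same profile. Batches are
assigned round-robin over the group-ordered samples so each batch pools all
groups, as multiplexed designs do; single-group batches would let a planted
up-effect inflate its own ambient rank and self-exclude. Defaults of
1,000 genes and ≈ 1,500 counts per cell are deliberate desk-scale choices —
no public per-cell count statistics constrain them — and are config-exposed.

It does **not** emulate: UMI-level sequencing error, cell-hashing tags,
batch effects on biology beyond the shared ambient pool, cell-type-specific
dispersion, or realistic gene–gene correlation. Passing tests therefore
demonstrate correctness of the *algorithms* under a faithful NB data model
with known truth, not robustness to every artefact of real droplet data.

## Study designs used by the tests

Problem sizes are the package's own desk-scale choices: engine calibration
and recovery use 500- and 300-gene pseudobulk tables at 8 vs 8 units over
20 replicates; cohort-level recovery uses two 16-sample, 800-gene,
two-cell-type cohorts with 50 planted effects (|log2FC| 1.5–2.5, random
signs); GSEA calibration uses 200 random sets over a 1,000-gene ranking at
1,000 permutations. In the recovery studies, planted genes are drawn from
the mid-expression band (baseline-mean rank 0.40–0.60): effects planted on
essentially unexpressed genes are removed by the expressing-cell filter, and
the ambient rule excludes the top expression quartile by construction, so
recall is meaningful only on genes testable under the pipeline's own rules.
Those studies use batches of 8 samples, mirroring pooled multiplexed
sequencing runs.

## Degenerate inputs and numerical guards

Empty p-vectors, empty mito-fraction vectors, sets equal to the universe,
`n_perm = 0`, zero contingency marginals and empty groups raise errors; a
batch without low-count barcodes yields an all-zero ambient profile with a
warning; all-identical fold-change rows give a degenerate-PCA warning with
equal scores; genes whose GLM fails to converge are reported flat
(`log2FC = 0`, `p = 1`) and flagged; units with all-zero counts abort TMM
with an error; size factors fall back to library-size ratios (with a
warning) when no gene is positive in all units. IRLS clamps the linear
predictor to ±30; dispersions are bounded to [1e−6, 50].

## Known limitations

Two-group contrasts only — no covariates, batch terms or random effects;
quasi-likelihood F-tests and the archetypes' full empirical-Bayes dispersion
machinery are out of scope by design. The doublet scorer does not sweep
neighbourhood sizes and underestimates homotypic doublets (they sit inside
their own cluster). The ambient metric identifies contamination-prone genes;
it does not correct counts. The exact test's quantile-window truncation is
exact to ~1e−12 of conditional mass but switches to a normal approximation
for extremely deep units.
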