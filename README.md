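# methylotyper

Patient subtyping from labial salivary gland (LSG) DNA methylation
profiles. Sjögren's syndrome is clinically heterogeneous, and standard
classification criteria (2016 ACR/EULAR) do not separate disease
subgroups; this package implements, as a tested R workflow, a subtyping
analysis for mixed Illumina 450K/EPIC cohorts:

1. **QC** — platform probe intersection; removal of probes with detection
   p > 0.01 in > 5 % of samples, of samples with > 5 % failing probes,
   and of SNP-overlapping / cross-reactive probes; column quantile
   normalization of β-values (β = methylated / total intensity ∈ [0, 1]).
2. **Batch adjustment** — parametric empirical-Bayes (ComBat) removal of
   the 450K-vs-EPIC platform component from β, bracketed by per-CpG mean
   imputation and exact missingness restoration.
3. **Embedding** — a variational autoencoder maps each sample's β profile
   to a d = 10 Gaussian posterior; the posterior mean is the embedding.
   The ELBO is Bernoulli reconstruction plus the closed-form KL
   ½ Σ (σ² + μ² − 1 − log σ²).
4. **Clustering** — Ward minimum-variance hierarchical clustering of the
   embeddings (Euclidean), cut at k = 4; clusters renumbered by case
   proportion; cases in case-dominant clusters (> 50 % cases) form the
   *severe* subgroup, the rest the *mild* subgroup. A baseline clustering
   on mean absolute β differences is kept for comparison.
5. **Phenotype association** — chi-square tests of independence (Yates
   correction on 2×2) for categorical phenotypes, Wilcoxon / Kruskal-Wallis
   for ordinal and continuous ones, with the focus-score zeroing and
   tear-break-up truncation rules applied first.
6. **DMRs** — per-CpG regression M ~ subgroup + array type on M = log2
   (β/(1−β)) *without* batch correction; candidate regions are maximal
   runs of ≥ 2 CpGs within 500 bp gaps whose coefficients all exceed 1.0
   in one direction; the region statistic is the area Σ|coef|; a
   covariate-controlling bootstrap (B = 1000) yields `fwerArea`, the
   proportion of bootstraps whose maximum candidate area reaches the
   observed one; regions with fwerArea ≤ 0.05 are significant.
7. **Enrichment** — hypergeometric over-representation P(X ≥ k) of
   promoter/gene-body DMR genes, split by direction, with
   Benjamini-Hochberg FDR.

The cohort the workflow was designed around is access controlled, so the
package ships a synthetic-cohort generator (`simulate_cohort()`) planting
four latent clusters of unequal size, severe-vs-mild methylation blocks,
a global severity gradient, a platform shift, detection failures and
cluster-dependent phenotypes — every stage is validated against that
planted truth.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
default synthetic cohort (131 subjects — 26/17/52/36 per cluster, 28
samples on 450K — and 2,000 CpGs):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_batch_adjust.R
Rscript analysis/04_embed_cluster.R
Rscript analysis/05_phenotype_assoc.R
Rscript analysis/06_dmr.R
Rscript analysis/07_gsea.R
```

Selected output from one run (tables land under `results/`):

```
=== analysis/02_preprocess.R ===
platform intersection: 1900 of 2000 probes
detection filter removed 100 probes and 0 samples
flag filter removed 77 probes; retained 1723 CpGs x 131 subjects

=== analysis/03_batch_adjust.R ===
max batch R2 before: 0.903  after: 0.001

=== analysis/04_embed_cluster.R ===
cluster sizes: 26 17 36 52
case proportion by cluster: 1 1 0.417 0.25
severe cases: 43  mild cases: 28
ARI vs planted clusters: 1
baseline vs embedding agreement: 98.5 % (ARI 0.95)

=== analysis/06_dmr.R ===
candidate regions: 8
significant (fwerArea <= 0.05): 8 ( 3 hypo / 5 hyper )

=== analysis/07_gsea.R ===
== hypo query: 3 genes; top sets ==
           set  K k        p    adj_p
1 HYPO_PLANTED  6 3 7.59e-06 0.000395
```

Reading: the platform component dominated one principal coordinate before
adjustment (R² 0.90) and vanished after (0.001); the VAE + Ward clusters
reproduce the planted four-cluster structure exactly (adjusted Rand index
1.0) and agree 98.5 % with the baseline β-distance clustering; the two
case-dominant clusters define 43 severe vs 28 mild cases; the DMR stage
recovers the planted severe-vs-mild blocks, and the gene set concentrated
on planted hypomethylated genes ranks first with BH-adjusted p ≈ 4e-4.

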