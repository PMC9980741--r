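---
title: "Methylation-based patient subtyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-based patient subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Sjögren's syndrome is clinically heterogeneous, and classification criteria
do not distinguish disease subgroups. This package implements a workflow
that subtypes patients from genome-wide DNA methylation of labial salivary
gland tissue measured on Illumina 450K/EPIC arrays: quality control of
β-values, adjustment for array platform, non-linear embedding with a
variational autoencoder (VAE), Ward hierarchical clustering into patient
clusters, severe/mild case subgrouping by cluster case-dominance,
phenotype association testing, bump-hunting detection of differentially
methylated regions (DMRs) between the subgroups with bootstrap family-wise
error control, and hypergeometric over-representation of DMR genes.

Because the cohort data the workflow was designed around are access
controlled, the package ships a synthetic-cohort generator whose planted
structure mirrors the cohort's reported properties; every stage is tested
against that planted truth.

# Measurement scales

A β-value is the proportion of methylation at a CpG, in [0, 1]. The
M-value is `log2(beta / (1 - beta))`; it has milder heteroscedasticity and
is the scale for linear modelling. `beta_to_m()` clips β to
[1e-6, 1 − 1e-6] before the transform — the clip is far below array
quantization and keeps the transform finite. Conversions round-trip to
1e-9.

# Quality control

`filter_detection()` removes probes whose detection p-value exceeds 0.01 in
strictly more than 5% of samples, then samples in which strictly more than
5% of the retained probes fail. Strict inequalities are used; the filter
report records each removal and its reason. `filter_flagged()` then drops
probes with SNP overlap (any minor allele frequency above zero) or known
cross-reactivity. Only probes present on both the 450K and EPIC manifests
enter a joint mixed-platform analysis (`intersect_platforms()`).

`quantile_normalize()` is plain column quantile normalization: every
sample's sorted values are replaced by the across-sample mean of sorted
values; ties share the mean of their ranks' reference values so the result
is deterministic and permutation-invariant. The probe-type-stratified
variant used on raw array intensities needs Infinium chemistry information
that is not present once the pipeline's input is a β matrix; equalized
per-sample distributions are the preserved contract, and this divergence is
deliberate and documented here.

# Batch adjustment

Mixed-platform cohorts show an array-type component in the leading
principal coordinates. `eb_batch_adjust()` applies parametric empirical
Bayes (ComBat): probes are standardized, per-batch location and scale
effects are shrunk toward normal and inverse-gamma priors estimated by
method of moments with iterative conditional updates, and the data are
back-transformed and clipped to [0, 1], β being a proportion. Because the
algorithm needs complete data, callers bracket it with `mean_impute()` /
`restore_missing()`, which fill each missing entry with its probe mean and
later re-blank exactly the original mask — no imputed value survives into
downstream inference. No covariates are protected by default; whether case
status should be protected when it is partially confounded with platform
is exposed as an option (`covariates`) but off by default. The adjustment
is approximately, not exactly, mean-preserving per probe: the
back-transform uses a batch-size-weighted grand mean and shrunken scale
estimates, so probe means move by a small amount (empirically below 5e-3
mean absolute on cohort-sized fixtures), and a second application moves
values several-fold less than the first.

`batch_effect_report()` quantifies the adjustment: the R² of each of the
first five principal coordinates regressed on the batch factor, before and
after. On fixtures with a planted platform shift the dominant component's
batch R² falls from above 0.5 to below 0.1.

# The VAE embedding

The encoder maps a sample's β profile to a diagonal Gaussian posterior
(mean and log-variance); the decoder reconstructs the profile from a
latent draw. Training maximizes the ELBO — Bernoulli cross-entropy
reconstruction, natural for values in [0, 1], plus the closed-form KL
divergence from the standard normal prior — with the reparameterization
trick and Adam. The implementation is plain BLAS matrix algebra with
hand-derived gradients, so training is deterministic given a seed.

Defaults: two hidden layers (512, 64), latent dimension 10, ReLU, 200
epochs, minibatch 8, learning rate 2e-3, 20% validation split. Two
choices matter on cohort-sized data (roughly 100–200 samples):

* **Minibatch 8, learning rate 2e-3.** With ~100 training samples a batch
  of 16 yields so few gradient steps per epoch that the posterior
  intermittently collapses to the prior (embedding variance → 0) and
  clustering structure is lost. Halving the batch and raising the rate was
  robust across simulation seeds.
* **KL warm-up.** The KL weight anneals linearly from 0 to 1 over the
  first quarter of training (`kl_warmup`), the standard guard against
  early posterior collapse. Recorded loss histories always report the
  *unweighted* ELBO, so the reconstruction and KL columns sum exactly to
  the loss column at every epoch.

The embedding used downstream is the deterministic posterior mean — no
sampling — so clustering is reproducible. Per-epoch training and
validation losses are recorded; on structured data the training loss
decreases monotonically in median over the early epochs.

# Clustering and subgrouping

`ward_linkage()` performs agglomerative clustering with Ward's
minimum-variance criterion on Euclidean distances between latent
coordinates (`hclust`, `ward.D2`); merge heights are non-decreasing and
cuts nest. The baseline comparator clusters on the mean absolute β
difference between samples (`baseline_distance()`), with
pairwise-complete handling of missing values. `k` is a parameter with
default 4; the choice of 4 in the motivating study came from dendrogram
inspection, and no quantitative criterion is imposed here.

After cutting, clusters are renumbered by decreasing case proportion, ties
by decreasing size, which makes "clusters 1 and 2 are case-dominant"
reproducible on synthetic data. `define_subgroups()` calls a cluster
case-dominant when its case proportion is strictly above 50%; cases in
dominant clusters form the *severe* subgroup, the remaining cases the
*mild* subgroup. An exact 50% tie leaves subgrouping undefined and is
rejected with a diagnostic. `compare_clusterings()` matches labels by the
agreement-maximizing one-to-one assignment (exhaustive to k = 8) and also
reports the label-invariant adjusted Rand index.

# Phenotype association

Dispatch is fixed: binary/nominal variables use the Pearson chi-square
test of independence — Yates continuity correction on for 2×2 tables,
off for larger ones — and ordinal/continuous variables use the Wilcoxon
rank-sum test for two groups or the Kruskal-Wallis test for more. The
Wilcoxon uses the tie-corrected normal approximation (so its two-group χ²
equals the Kruskal-Wallis statistic exactly), with exact enumeration when
both groups have at most 10 untied observations. Two preprocessing rules
precede testing: a missing focus score is set to zero when the biopsy
diagnosis is within normal limits, non-specific chronic inflammation or
sclerosing chronic sialadenitis (the score is only measured when
lymphocytic foci are present); and tear break-up times of at least 10
seconds are truncated to 10, since longer times are considered healthy.
Constant variables (e.g. a lymphoma indicator with no events) are reported
with `NA` p-values rather than dropped. Raw p-values are reported at
α = 0.05 with no correction across phenotype rows, matching how such
tables are conventionally presented.

# DMR detection

Per CpG, ordinary least squares of the M-value on the severe/mild
indicator with array type as covariate: the DMR track deliberately uses
M-values *without* batch adjustment and models the platform instead, so
the two tracks (adjusted β for clustering, raw M for inference) coexist.
Probes on a chromosome separated by at most `max_gap` (default 500 bp, the
convention of the reference bump-hunting implementation; the motivating
analysis does not state its value) form clusters; maximal runs of at least
`min_cpgs = 2` consecutive probes with coefficients all ≥ +1.0 or all
≤ −1.0 (`cutoff`, the expected M-scale change between groups) are
candidates. No coefficient smoothing is applied before segmentation —
the per-CpG cutoff reading is deterministic; smoothing is a possible
extension but is not implemented.

A candidate's statistic is its *area*, the sum of absolute coefficients.
Significance comes from a bootstrap null that controls for the
covariates: the reduced model (intercept + covariates) is fitted per
probe, whole-subject residual columns are resampled with replacement and
added back to the reduced fitted values — preserving cross-probe
correlation — and the full model and bump search are re-run (B = 1000 by
default). `fwerArea` is the proportion of bootstraps whose *maximum*
candidate area reaches the observed area; `p_valueArea` is the proportion
of *pooled* null candidate areas reaching it. Counting uses ≥ (reaching,
not strictly exceeding), the conservative reading. Significant regions
have `fwerArea ≤ 0.05`. When a bootstrap produces no candidate its
maximum area is 0; when the pooled null is empty, `p_valueArea` is
reported as 1/B with a flag. Before fitting, remaining missing M-values
are mean-imputed per probe once, so observed and bootstrap statistics
share one scale.

Regions are annotated by majority vote over member probes (gene, gene
region, island relation), ties resolved to the first label by position.

# Gene-set over-representation

Query genes are the unique genes of significant DMRs of one direction
whose region class is Promoter or Body (directions are analysed
separately; a gene harbouring DMRs of both directions appears in both
queries). The background universe defaults to all genes represented by at
least one retained probe — the standard array-aware choice; the universe
is configurable since the appropriate background depends on the manifest.
Each set is tested with the one-sided hypergeometric tail P(X ≥ k), and
Benjamini-Hochberg adjustment controls the FDR. Gene symbols are matched
case-sensitively after whitespace trimming; alias resolution is out of
scope and a documented limitation.

# The synthetic cohort generator

`simulate_cohort()` draws per-CpG M-values as Gaussian noise (SD 0.8)
around probe baselines (spread SD 1.5, so the array covers the
methylated/unmethylated range) and adds three planted components:

* **Blocks** (`dmr_blocks`): contiguous runs of 8–10 CpGs shifted by ±2
  M-units in chosen cluster subsets. Blocks shared by clusters 1–2 are the
  severe-vs-mild differential truth; blocks private to cluster 2 and to
  cluster 4 make all four clusters separable. Within a block,
  inter-probe gaps are 50–400 bp so a block forms one max-gap cluster;
  elsewhere gaps are 50–10,000 bp, making the segmentation non-trivial.
* **A global severity gradient** (`global_fraction = 0.3`,
  `global_effect_sd = 1.0`, `severity = (0.6, 1, 0, 0.3)`): a random
  loading per selected probe multiplied by the cluster's severity score.
  This emulates cohorts in which clusters differ in global methylation
  level ordered by clinical severity (the first principal coordinate
  orders clusters by severity); planted blocks alone cannot produce that
  genome-scale signature. Block probes are excluded so block effect sizes
  stay exactly as configured.
* **A platform shift** (`batch_probe_fraction = 0.25`,
  `batch_effect_sd = 1.0`): per-probe N(0, 1) M-shifts added to the
  samples assigned to the 450K platform (a 28/131 fraction by default).

Cluster sizes default to 26/17/52/36 with per-cluster case probabilities
reproducing roughly 40 severe-side and 24 mild-side cases. Detection
failures are probe-level: 5% of probes fail in a random >5% subset of
samples, exercising the probe filter exactly; planted blocks are kept
clear of failed or flagged probes. Missingness is 1% per entry.
Phenotypes are generated conditionally on *cluster* (not case status), so
cluster-phenotype association is the planted signal; the defaults include
serology indicators, IgG, a focus score with the biopsy-diagnosis
missingness convention, and a tear-break-up time that exercises
truncation. Gene sets comprise one set per planted direction
(concentrated on planted-block genes) plus random decoys.

What the generator does **not** emulate: Infinium probe-type chemistry,
fluorescence intensities, cell-type composition, genomic dependence of
probe variance, and realistic linkage between phenotypes. Passing tests
therefore demonstrate correctness of the algorithms under the planted
model, not performance on real arrays.

Per-CpG variance and missingness rates are not reported for the
motivating cohort; the defaults above were chosen once for testability
and realism and are fixed.

# Numerical and degenerate-input choices

* Same seed + config ⇒ bit-identical simulation output; fixtures
  round-trip bit-identically through TSV at 17 significant digits.
* Ward merge ties are resolved by `hclust`'s deterministic ordering.
* An all-missing probe, a constant outcome, a single-sample batch, a
  zero contingency margin, or an empty group each raise an error naming
  the offending unit; an all-flagged probe set or an empty candidate list
  degrade with a warning or an empty result instead.
* The exact Wilcoxon path is disabled in the presence of ties (the normal
  approximation with tie correction is used instead).

# Problem sizes used by the test-suite and acceptance runs

Simulated cohorts use 131 subjects × 1,500–2,400 CpGs (full pipeline) and
200 × 2,000 (null calibration, 20 replicates, B = 200); the VAE runs with
hidden layers (128, 32) — narrower than the (512, 64) default but the
same in every other respect — and DMR bootstraps use B = 150–200 in tests
versus the B = 1000 default of the analysis drivers. These sizes are the
package's choice of desk-scale replication: they preserve every
qualitative property being asserted (cluster recovery, FWER control,
planted-block sensitivity, enrichment ranking) at a few minutes of
runtime.

# Known limitations

* Plain column quantile normalization stands in for probe-type-stratified
  normalization (see above).
* The VAE architecture of the motivating analysis is not fully specified
  there; defaults here are the package's own and exposed in
  `vae_config()`.
* `p_valueArea` and `fwerArea` implement the pooled-vs-maximum bootstrap
  semantics of the reference bump-hunting tool; the two coincide when at
  most one candidate arises per bootstrap.
* Genome-scale results from the motivating cohort (e.g. absolute DMR
  counts) are not reproducible without the controlled-access data and are
  out of scope; the acceptance checks substitute planted-truth
  properties.
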