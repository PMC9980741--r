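#' @title Synthetic methylation cohort generator
#'
#' @description
#' Generates cohorts with the statistical structure the subtyping pipeline
#' assumes: four latent patient clusters of unequal size, hypo- and
#' hypermethylated CpG blocks distinguishing the case-dominant clusters from
#' the rest, an additive platform (450K vs EPIC) shift on a subset of probes,
#' probe-level detection failures, per-entry missingness, and clinical
#' phenotypes whose distributions depend on cluster. M-values are the
#' generative scale; beta-values are derived as 2^M / (1 + 2^M).
#'
#' @name simulate
NULL

#' Default planted-block layout
#'
#' Hypo and hyper blocks shared by clusters 1-2 carry the severe-vs-mild
#' differential signal; additional blocks private to cluster 2 and cluster 4
#' make all four clusters separable.
#'
#' @param effect absolute M-scale effect size (default 2).
#' @return List of block descriptors (`clusters`, `length`, `effect`).
#' @export
default_dmr_blocks <- function(effect = 2) {
  c(
    lapply(1:3, function(i) list(clusters = c(1L, 2L), length = 10L, effect = -effect)),
    lapply(1:3, function(i) list(clusters = c(1L, 2L), length = 8L, effect = +effect)),
    lapply(1:2, function(i) list(clusters = 2L, length = 8L, effect = +effect)),
    lapply(1:2, function(i) list(clusters = 4L, length = 8L, effect = -effect))
  )
}

#' Default cluster-conditional phenotype specification
#'
#' Binary serology markers, continuous IgG, a focus score carrying the
#' missing-when-biopsy-benign convention, a tear-break-up time subject to
#' truncation at 10 s, and a nominal biopsy diagnosis. Parameters are indexed
#' by cluster (severity decreasing 2, 1, 4, 3).
#'
#' @return Named list of per-variable specs (`type`, `rule`, parameters).
#' @export
default_phenotype_spec <- function() {
  list(
    anti_ro      = list(type = "binary", probs = c(0.62, 0.94, 0.06, 0.14)),
    anti_la      = list(type = "binary", probs = c(0.50, 0.94, 0.06, 0.08)),
    rf           = list(type = "binary", probs = c(0.65, 0.94, 0.13, 0.17)),
    ana_1_320    = list(type = "binary", probs = c(0.73, 0.94, 0.19, 0.31)),
    gc_formation = list(type = "binary", probs = c(0.19, 0.29, 0.00, 0.00)),
    igg          = list(type = "continuous", mean = c(1370, 2131, 996, 1222),
                        sd = c(480, 598, 295, 851), min = 0),
    biopsy_diagnosis = list(
      type = "nominal",
      levels = c("focal lymphocytic sialadenitis", "within normal limits",
                 "non-specific chronic inflammation", "sclerosing chronic sialadenitis"),
      probs = rbind(c(0.85, 0.05, 0.07, 0.03),
                    c(0.95, 0.02, 0.02, 0.01),
                    c(0.25, 0.35, 0.30, 0.10),
                    c(0.40, 0.30, 0.20, 0.10))),
    focus_score  = list(type = "continuous", mean = c(3.0, 4.8, 1.0, 1.3),
                        sd = c(1.8, 2.0, 1.0, 1.5), min = 0,
                        rule = "focus_score_rule"),
    tbut_left    = list(type = "continuous", mean = c(4.9, 4.5, 7.7, 6.1),
                        sd = c(3.0, 2.8, 2.8, 3.2), min = 0,
                        rule = "tbut_truncation")
  )
}

#' Simulation configuration
#'
#' Defaults emulate the study cohort: 131 subjects in clusters of
#' 26/17/52/36, case probabilities reproducing 40 cases in clusters 1-2 and
#' 24 in clusters 3-4 in expectation, 28/131 of samples on the 450K platform.
#'
#' @param n_subjects,n_cpgs,n_chromosomes cohort dimensions.
#' @param cluster_sizes integer vector summing to `n_subjects`.
#' @param case_flag_per_cluster per-cluster probability of case status.
#' @param dmr_blocks list of planted blocks (see [default_dmr_blocks()]).
#' @param batch_fraction proportion of samples on platform "450K".
#' @param batch_effect_sd M-scale SD of the per-probe additive platform shift.
#' @param batch_probe_fraction fraction of probes receiving the shift.
#' @param baseline_m_mean,baseline_m_sd per-CpG Gaussian M-value noise
#'   parameters; `baseline_between_sd` spreads per-CpG baseline means so the
#'   array shows a range of methylation states.
#' @param global_fraction,global_effect_sd,severity a genome-wide severity
#'   gradient: `global_fraction` of probes receive an M-scale loading drawn
#'   from N(0, `global_effect_sd`), multiplied per subject by the cluster's
#'   `severity` score. This emulates cohorts where clusters differ in global
#'   methylation level ordered by phenotype severity (cluster order
#'   2 > 1 > 4 > 3 by default), on top of the discrete planted blocks.
#' @param missing_rate per-entry missingness probability.
#' @param failed_probe_fraction fraction of probes simulated as detection
#'   failures (failing in a random >5 percent subset of samples).
#' @param phenotype_spec see [default_phenotype_spec()].
#' @param n_decoy_sets,decoy_set_sizes decoy gene-set count and size range.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return Validated configuration list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 131L,
                              n_cpgs = 2000L,
                              n_chromosomes = 4L,
                              cluster_sizes = c(26L, 17L, 52L, 36L),
                              case_flag_per_cluster = c(23 / 26, 1, 11 / 52, 13 / 36),
                              dmr_blocks = default_dmr_blocks(),
                              batch_fraction = 28 / 131,
                              batch_effect_sd = 1.0,
                              batch_probe_fraction = 0.25,
                              baseline_m_mean = 0,
                              baseline_m_sd = 0.8,
                              baseline_between_sd = 1.5,
                              global_fraction = 0.3,
                              global_effect_sd = 1.0,
                              severity = c(0.6, 1, 0, 0.3),
                              missing_rate = 0.01,
                              failed_probe_fraction = 0.05,
                              phenotype_spec = default_phenotype_spec(),
                              n_decoy_sets = 50L,
                              decoy_set_sizes = c(5L, 50L),
                              seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_cpgs = as.integer(n_cpgs),
    n_chromosomes = as.integer(n_chromosomes),
    cluster_sizes = as.integer(cluster_sizes),
    case_flag_per_cluster = case_flag_per_cluster,
    dmr_blocks = dmr_blocks, batch_fraction = batch_fraction,
    batch_effect_sd = batch_effect_sd,
    batch_probe_fraction = batch_probe_fraction,
    baseline_m_mean = baseline_m_mean, baseline_m_sd = baseline_m_sd,
    baseline_between_sd = baseline_between_sd,
    global_fraction = global_fraction, global_effect_sd = global_effect_sd,
    severity = severity,
    missing_rate = missing_rate,
    failed_probe_fraction = failed_probe_fraction,
    phenotype_spec = phenotype_spec,
    n_decoy_sets = as.integer(n_decoy_sets),
    decoy_set_sizes = as.integer(decoy_set_sizes),
    seed = as.integer(seed)
  )
  if (sum(cfg$cluster_sizes) != cfg$n_subjects)
    stop("invalid config: sum(cluster_sizes) == n_subjects violated")
  probs <- c(cfg$case_flag_per_cluster, batch_fraction, batch_probe_fraction,
             missing_rate, failed_probe_fraction)
  if (any(probs < 0 | probs > 1))
    stop("invalid config: all probabilities in [0,1] violated")
  if (length(cfg$case_flag_per_cluster) != length(cfg$cluster_sizes))
    stop("invalid config: one case probability per cluster required")
  for (b in cfg$dmr_blocks) {
    if (b$length < 2) stop("invalid config: block lengths >= 2 violated")
    if (!is.finite(b$effect)) stop("invalid config: effect sizes finite violated")
    if (any(!b$clusters %in% seq_along(cfg$cluster_sizes)))
      stop("invalid config: block cluster index out of range")
  }
  if (cfg$baseline_m_sd <= 0) stop("invalid config: baseline_m_sd must be positive")
  if (cfg$global_fraction < 0 || cfg$global_fraction > 1)
    stop("invalid config: global_fraction must be in [0,1]")
  if (length(cfg$severity) != length(cfg$cluster_sizes))
    stop("invalid config: one severity score per cluster required")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a full synthetic cohort
#'
#' Draws M-values per CpG as Gaussian(baseline + planted cluster effect +
#' platform shift), converts to beta, plants probe-level detection failures
#' and missingness, builds a probe annotation with strictly increasing
#' positions per chromosome, tiles genes over probes, and assembles gene sets
#' concentrated on planted-block genes plus random decoys.
#'
#' @param config a [simulation_config()].
#' @return List with `beta`, `detp`, `samples` (sample sheet data.frame),
#'   `annotation`, `gene_sets` (list with `sets` and `universe`), `truth`
#'   (subject labels, planted intervals, enriched set names) and `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) config <- do.call(simulation_config, config)
  set.seed(config$seed)
  n <- config$n_subjects
  p <- config$n_cpgs
  k <- length(config$cluster_sizes)

  cluster <- rep(seq_len(k), times = config$cluster_sizes)
  case <- stats::rbinom(n, 1L, config$case_flag_per_cluster[cluster])
  n_450k <- round(config$batch_fraction * n)
  batch <- rep("EPIC", n)
  batch[sample.int(n, n_450k)] <- "450K"
  sample_ids <- sprintf("S%03d", seq_len(n))
  probe_ids <- sprintf("cg%06d", seq_len(p))

  # --- probe layout: chromosomes, planted blocks, positions ---------------
  chrom_sizes <- rep(p %/% config$n_chromosomes, config$n_chromosomes)
  chrom_sizes[config$n_chromosomes] <- p - sum(chrom_sizes[-config$n_chromosomes])
  chrom <- rep(sprintf("chr%d", seq_len(config$n_chromosomes)), times = chrom_sizes)
  chrom_start <- cumsum(c(1L, utils::head(chrom_sizes, -1L)))

  blocks <- config$dmr_blocks
  block_probes <- integer(0)
  block_info <- vector("list", length(blocks))
  if (length(blocks)) {
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      placed <- FALSE
      for (try in 1:1000) {
        ch <- sample.int(config$n_chromosomes, 1L)
        if (chrom_sizes[ch] < b$length) next
        start <- chrom_start[ch] + sample.int(chrom_sizes[ch] - b$length + 1L, 1L) - 1L
        idx <- start:(start + b$length - 1L)
        if (!any(idx %in% block_probes)) { placed <- TRUE; break }
      }
      if (!placed) stop("could not place planted blocks without overlap; reduce blocks or raise n_cpgs")
      block_probes <- c(block_probes, idx)
      block_info[[i]] <- list(idx = idx, clusters = b$clusters, effect = b$effect)
    }
  }

  # positions: cumulative jumps of 50-10,000 bp; planted blocks use short
  # jumps (50-400 bp) so they form single max-gap clusters downstream
  jump <- sample(50:10000, p, replace = TRUE)
  in_block_jump <- seq_len(p) %in% setdiff(block_probes,
                                           vapply(block_info, function(b) b$idx[1], 1L))
  jump[in_block_jump] <- sample(50:400, sum(in_block_jump), replace = TRUE)
  pos <- integer(p)
  for (ch in seq_len(config$n_chromosomes)) {
    sel <- which(chrom == sprintf("chr%d", ch))
    pos[sel] <- cumsum(jump[sel])
  }

  # --- M-value model ------------------------------------------------------
  baseline <- stats::rnorm(p, config$baseline_m_mean, config$baseline_between_sd)
  m <- matrix(stats::rnorm(p * n, 0, config$baseline_m_sd), p, n) + baseline
  for (b in block_info) {
    aff <- cluster %in% b$clusters
    m[b$idx, aff] <- m[b$idx, aff] + b$effect
  }
  # genome-wide severity gradient (kept off the planted blocks so their
  # effect sizes stay exactly as configured)
  global_idx <- integer(0)
  if (config$global_fraction > 0 && config$global_effect_sd > 0) {
    n_global <- round(config$global_fraction * p)
    global_idx <- sort(sample(setdiff(seq_len(p), block_probes), n_global))
    loading <- stats::rnorm(n_global, 0, config$global_effect_sd)
    m[global_idx, ] <- m[global_idx, ] +
      outer(loading, config$severity[cluster])
  }
  n_batch_probes <- round(config$batch_probe_fraction * p)
  batch_probe_idx <- sort(sample.int(p, n_batch_probes))
  if (n_batch_probes > 0 && config$batch_effect_sd > 0) {
    shift <- stats::rnorm(n_batch_probes, 0, config$batch_effect_sd)
    m[batch_probe_idx, batch == "450K"] <-
      m[batch_probe_idx, batch == "450K"] + shift
  }
  beta <- m_to_beta(m)
  dimnames(beta) <- list(probe_ids, sample_ids)

  # --- detection failures and QC flags (kept off planted blocks) ----------
  free <- setdiff(seq_len(p), block_probes)
  n_failed <- round(config$failed_probe_fraction * p)
  failed_probes <- sort(sample(free, n_failed))
  detp <- matrix(stats::runif(p * n, 0, 0.005), p, n, dimnames = dimnames(beta))
  min_fail <- floor(0.05 * n) + 1L  # strictly more than 5% of samples
  for (i in failed_probes) {
    nf <- max(min_fail, ceiling(stats::runif(1, 0.06, 0.40) * n))
    detp[i, sample.int(n, nf)] <- stats::runif(nf, 0.02, 1)
  }
  free2 <- setdiff(free, failed_probes)
  snp_flag <- cr_flag <- integer(p)
  snp_flag[sample(free2, round(0.02 * p))] <- 1L
  cr_flag[sample(free2, round(0.02 * p))] <- 1L
  on_450k <- rep(1L, p)
  on_450k[sample(free2, round(0.05 * p))] <- 0L  # EPIC-only probes

  # --- missingness --------------------------------------------------------
  miss <- matrix(stats::runif(p * n) < config$missing_rate, p, n)
  beta[miss] <- NA_real_

  # --- gene tiling and annotation -----------------------------------------
  genes_per_probe <- 8L
  gene_id <- integer(p)
  g <- 0L
  for (ch in seq_len(config$n_chromosomes)) {
    sel <- which(chrom == sprintf("chr%d", ch))
    gene_id[sel] <- g + ((seq_along(sel) - 1L) %/% genes_per_probe) + 1L
    g <- max(gene_id[sel])
  }
  gene <- sprintf("GENE%04d", gene_id)
  region <- sample(c("Promoter", "Body", "3'UTR", "Intergenic"), p,
                   replace = TRUE, prob = c(0.25, 0.45, 0.10, 0.20))
  region[block_probes] <- sample(c("Promoter", "Body"), length(block_probes),
                                 replace = TRUE)
  gene[region == "Intergenic"] <- ""
  island <- sample(c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea"),
                   p, replace = TRUE, prob = c(0.3, 0.1, 0.1, 0.05, 0.05, 0.4))
  annotation <- data.frame(
    probe_id = probe_ids, chrom = chrom, pos = pos, strand = "+",
    gene = gene, region = region, island = island,
    snp_flag = snp_flag, crossreactive_flag = cr_flag,
    on_450k = on_450k, on_epic = 1L, stringsAsFactors = FALSE
  )

  # --- gene sets: planted-DMR sets plus decoys ----------------------------
  universe <- sort(unique(gene[gene != ""]))
  sm_blocks <- vapply(block_info, function(b) identical(sort(b$clusters), c(1L, 2L)), TRUE)
  genes_of <- function(sel) sort(unique(gene[unlist(lapply(block_info[sel],
                                                           function(b) b$idx))]))
  hypo_genes <- genes_of(sm_blocks & vapply(block_info, function(b) b$effect < 0, TRUE))
  hyper_genes <- genes_of(sm_blocks & vapply(block_info, function(b) b$effect > 0, TRUE))
  sets <- list()
  if (length(hypo_genes)) sets$HYPO_PLANTED <- setdiff(hypo_genes, "")
  if (length(hyper_genes)) sets$HYPER_PLANTED <- setdiff(hyper_genes, "")
  if (config$n_decoy_sets > 0) {
    sizes <- sample(config$decoy_set_sizes[1]:config$decoy_set_sizes[2],
                    config$n_decoy_sets, replace = TRUE)
    decoys <- lapply(sizes, function(s) sample(universe, min(s, length(universe))))
    names(decoys) <- sprintf("DECOY%04d", seq_len(config$n_decoy_sets))
    sets <- c(sets, decoys)
  }

  # --- phenotypes ---------------------------------------------------------
  pheno <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  types <- character(0); rules <- character(0)
  for (v in names(config$phenotype_spec)) {
    sp <- config$phenotype_spec[[v]]
    val <- switch(sp$type,
      binary = stats::rbinom(n, 1L, sp$probs[cluster]),
      continuous = pmax(stats::rnorm(n, sp$mean[cluster], sp$sd[cluster]),
                        if (is.null(sp$min)) -Inf else sp$min),
      ordinal = {
        lv <- seq_len(ncol(sp$probs))
        vapply(cluster, function(cl) sample(lv, 1L, prob = sp$probs[cl, ]), 1L)
      },
      nominal = vapply(cluster, function(cl)
        sample(sp$levels, 1L, prob = sp$probs[cl, ]), ""),
      stop("unknown phenotype type: ", sp$type))
    pheno[[v]] <- val
    types[v] <- sp$type
    rules[v] <- if (is.null(sp$rule)) NA_character_ else sp$rule
  }
  # focus score is only measured when foci are present: benign biopsy
  # diagnoses leave it missing (re-zeroed later by the special rule)
  if (all(c("focus_score", "biopsy_diagnosis") %in% names(pheno))) {
    benign <- pheno$biopsy_diagnosis %in% c(
      "within normal limits", "non-specific chronic inflammation",
      "sclerosing chronic sialadenitis")
    pheno$focus_score[benign] <- NA_real_
  }

  samples <- data.frame(sample_id = sample_ids, platform = batch, case = case,
                        stringsAsFactors = FALSE)
  samples <- cbind(samples, pheno[, setdiff(names(pheno), "sample_id"), drop = FALSE])

  dmr_intervals <- do.call(rbind, lapply(seq_along(block_info), function(i) {
    b <- block_info[[i]]
    data.frame(
      block_id = i, chrom = chrom[b$idx[1]],
      start = pos[b$idx[1]], end = pos[b$idx[length(b$idx)]],
      n_cpgs = length(b$idx),
      direction = if (b$effect > 0) "hyper" else "hypo",
      effect = b$effect,
      clusters = paste(b$clusters, collapse = ","),
      severe_vs_mild = identical(sort(b$clusters), c(1L, 2L)),
      genes = paste(sort(unique(gene[b$idx][gene[b$idx] != ""])), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))

  truth <- list(
    cluster = stats::setNames(cluster, sample_ids),
    case = stats::setNames(case, sample_ids),
    batch = stats::setNames(batch, sample_ids),
    dmr_intervals = dmr_intervals,
    failed_probes = probe_ids[failed_probes],
    batch_probes = probe_ids[batch_probe_idx],
    global_probes = probe_ids[global_idx],
    enriched_sets = intersect(c("HYPO_PLANTED", "HYPER_PLANTED"), names(sets))
  )

  list(beta = beta, detp = detp, samples = samples, annotation = annotation,
       gene_sets = list(sets = sets, universe = universe),
       truth = truth, config = config,
       pheno_types = types, pheno_rules = rules)
}
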