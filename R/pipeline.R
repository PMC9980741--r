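#' Run the full methylation subtyping pipeline
#'
#' End-to-end driver over a cohort bundle (as produced by
#' [simulate_cohort()] or [read_fixture()]):
#' platform intersection, detection and SNP/cross-reactivity filters,
#' quantile normalization, empirical-Bayes platform adjustment (bracketed by
#' mean imputation and missingness restoration), VAE embedding, Ward
#' clustering cut at `k` with case-proportion renumbering, severe/mild
#' subgrouping, and — on cases only, using M-values *without* batch
#' adjustment and the array type as a model covariate — bump-hunting DMR
#' detection with bootstrap FWER, followed by direction-split
#' over-representation analysis.
#'
#' @param beta,detp probes x samples beta and detection p-value matrices.
#' @param samples sample sheet data.frame (`sample_id`, `platform`, `case`).
#' @param annotation probe annotation data.frame.
#' @param gene_sets list with `sets` (named list) and optional `universe`
#'   (defaults to genes on retained probes).
#' @param k number of patient clusters (default 4).
#' @param vae a [vae_config()].
#' @param dmr a [dmr_config()].
#' @param run_dmr set FALSE to stop after clustering (default TRUE).
#' @return List with the filtered/normalized/adjusted matrices, embedding,
#'   tree, cluster assignment, subgroups, DMR results and enrichment tables.
#' @export
run_pipeline <- function(beta, detp, samples, annotation, gene_sets = NULL,
                         k = 4, vae = vae_config(), dmr = dmr_config(),
                         run_dmr = TRUE) {
  shared <- intersect_platforms(annotation)
  keep <- rownames(beta) %in% shared
  if (!any(keep)) stop("no probes shared across platforms")
  beta <- beta[keep, , drop = FALSE]
  detp <- detp[keep, , drop = FALSE]

  fd <- filter_detection(beta, detp)
  beta_f <- filter_flagged(fd$beta, annotation)
  samples <- samples[samples$sample_id %in% colnames(beta_f), , drop = FALSE]
  ann_f <- annotation[match(rownames(beta_f), annotation$probe_id), , drop = FALSE]

  imp <- mean_impute(beta_f)
  beta_qn <- restore_missing(quantile_normalize(imp$beta), imp$mask)

  imp2 <- mean_impute(beta_qn)
  platform <- samples$platform[match(colnames(beta_qn), samples$sample_id)]
  beta_adj_complete <- eb_batch_adjust(imp2$beta, platform)
  beta_adj <- restore_missing(beta_adj_complete, imp2$mask)

  trained <- train_vae(beta_adj_complete, vae)
  case <- stats::setNames(samples$case, samples$sample_id)
  tree <- ward_linkage(trained$embedding$mu)
  assignment <- cut_tree(tree, k, case_status = case)
  subgroups <- define_subgroups(assignment, case)

  out <- list(beta_filtered = beta_f, beta_normalized = beta_qn,
              beta_adjusted = beta_adj, annotation = ann_f,
              samples = samples, removed_probes = fd$removed_probes,
              removed_samples = fd$removed_samples,
              model = trained$model, embedding = trained$embedding,
              tree = tree, assignment = assignment, subgroups = subgroups)

  if (run_dmr) {
    cases <- names(subgroups$subgroup)
    outcome <- as.integer(subgroups$subgroup[cases] == "severe")
    m <- beta_to_m(beta_qn[, cases, drop = FALSE])
    arr <- as.integer(platform[match(cases, colnames(beta_qn))] == "450K")
    out$dmr <- find_dmrs(m, outcome, covariates = cbind(arraytype = arr),
                         annotation = ann_f, config = dmr)
    if (!is.null(gene_sets)) {
      universe <- if (!is.null(gene_sets$universe)) gene_sets$universe
                  else gene_universe(ann_f)
      coll <- list(sets = gene_sets$sets, universe = universe)
      out$gsea <- list(hypo = run_gsea(out$dmr$dmrs, coll, "hypo"),
                       hyper = run_gsea(out$dmr$dmrs, coll, "hyper"))
    }
  }
  out
}
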