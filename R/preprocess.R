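#' @title Probe and sample quality control for methylation beta matrices
#'
#' @description
#' The preprocessing stage works on plain numeric matrices of beta-values
#' (probes in rows, samples in columns, `NA` marking missing entries, row
#' names carrying probe ids and column names sample ids). All filters are
#' strict-inequality rules: a probe is dropped when it fails detection in
#' *more than* `probe_frac` of samples, a sample when *more than*
#' `sample_frac` of retained probes fail in it.
#'
#' @name preprocess
NULL

# internal: assert a probes x samples matrix with unique dimnames
check_beta_matrix <- function(beta, what = "beta") {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop(what, " must be a numeric matrix (probes x samples)")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop(what, " must have probe row names and sample column names")
  if (anyDuplicated(rownames(beta)))
    stop(what, ": probe ids must be unique")
  if (anyDuplicated(colnames(beta)))
    stop(what, ": sample ids must be unique")
  rng <- range(beta, na.rm = TRUE)
  if (what == "beta" && (rng[1] < 0 || rng[2] > 1))
    stop("beta values must lie in [0, 1]")
  invisible(beta)
}

#' Probes present on both array platforms
#'
#' Returns, in annotation order, the probes flagged as present on both the
#' 450K and EPIC platforms; joint analysis of a mixed-platform cohort is
#' restricted to this intersection.
#'
#' @param annotation data.frame with columns `probe_id`, `on_450k`, `on_epic`
#'   (0/1 flags).
#' @return Character vector of probe ids on both platforms.
#' @export
intersect_platforms <- function(annotation) {
  stopifnot(all(c("probe_id", "on_450k", "on_epic") %in% names(annotation)))
  annotation$probe_id[annotation$on_450k == 1 & annotation$on_epic == 1]
}

#' Detection p-value filtering of probes, then samples
#'
#' A probe is removed when it has detection p-value above `p_thresh` in
#' strictly more than `probe_frac` of samples; afterwards a sample is removed
#' when strictly more than `sample_frac` of the retained probes fail in it.
#'
#' @param beta probes x samples beta matrix.
#' @param detp detection p-value matrix of identical shape and dimnames.
#' @param probe_frac,sample_frac,p_thresh filter thresholds (defaults 0.05,
#'   0.05 and 0.01).
#' @return List with elements `beta` (filtered matrix), `removed_probes`,
#'   `removed_samples`.
#' @export
filter_detection <- function(beta, detp, probe_frac = 0.05, p_thresh = 0.01,
                             sample_frac = 0.05) {
  check_beta_matrix(beta)
  if (!identical(dim(beta), dim(detp)) ||
      !identical(dimnames(beta), dimnames(detp)))
    stop("beta and detection p-value matrices must have identical shape and ids")
  fails <- detp > p_thresh
  fails[is.na(fails)] <- FALSE
  bad_probe <- rowMeans(fails) > probe_frac
  kept <- beta[!bad_probe, , drop = FALSE]
  fails_kept <- fails[!bad_probe, , drop = FALSE]
  bad_sample <- colMeans(fails_kept) > sample_frac
  list(
    beta = kept[, !bad_sample, drop = FALSE],
    removed_probes = rownames(beta)[bad_probe],
    removed_samples = colnames(beta)[bad_sample]
  )
}

#' Remove SNP-overlapping and cross-reactive probes
#'
#' Drops probes whose annotation carries a SNP flag (any minor allele
#' frequency above zero at the probe, interrogation or extension site) or a
#' cross-reactivity flag.
#'
#' @param beta probes x samples beta matrix.
#' @param annotation data.frame with `probe_id`, `snp_flag`,
#'   `crossreactive_flag`; must cover every probe of `beta`.
#' @return Filtered beta matrix (possibly zero rows, with a warning).
#' @export
filter_flagged <- function(beta, annotation) {
  check_beta_matrix(beta)
  idx <- match(rownames(beta), annotation$probe_id)
  if (anyNA(idx))
    stop("unannotated probe(s): ",
         paste(utils::head(rownames(beta)[is.na(idx)], 5), collapse = ", "))
  bad <- annotation$snp_flag[idx] == 1 | annotation$crossreactive_flag[idx] == 1
  out <- beta[!bad, , drop = FALSE]
  if (nrow(out) == 0) warning("all probes removed by SNP/cross-reactive flags")
  out
}

#' Column quantile normalization
#'
#' Forces every sample to share one empirical distribution: the across-sample
#' mean of the sorted values. Ranks within each sample are preserved; ties
#' share the mean of the reference values at the tied ranks, so the result is
#' invariant to sample order.
#'
#' @param beta probes x samples beta matrix without missing values.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(beta) {
  check_beta_matrix(beta)
  if (anyNA(beta)) stop("quantile_normalize requires a complete matrix; impute first")
  if (ncol(beta) < 2) return(beta)
  sorted <- apply(beta, 2, sort)
  ref <- rowMeans(sorted)
  out <- apply(beta, 2, function(col) {
    vals <- ref[rank(col, ties.method = "first")]
    # tied input values share the mean of their ranks' reference values
    stats::ave(vals, col, FUN = mean)
  })
  dimnames(out) <- dimnames(beta)
  out
}

#' Beta / M-value conversion
#'
#' M = log2(beta / (1 - beta)); beta-values are clipped to
#' \[eps, 1 - eps\] first so the transform stays finite. Missing values
#' propagate. `m_to_beta` is the exact inverse, 2^M / (1 + 2^M).
#'
#' @param beta,m numeric matrices (or vectors).
#' @param eps clipping bound (default 1e-6, below array quantization).
#' @return Matrix of the same shape on the other scale.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  x <- pmin(pmax(beta, eps), 1 - eps)
  log2(x / (1 - x))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  # stable logistic in base 2: avoids overflow for large |m|
  out <- ifelse(m > 0, 1 / (1 + 2^(-m)), 2^m / (1 + 2^m))
  out
}

#' Per-probe mean imputation with exact missingness restoration
#'
#' `mean_impute` replaces each missing entry by its probe's mean over
#' non-missing samples and returns the missingness mask; `restore_missing`
#' re-blanks exactly those entries. The pair brackets procedures that require
#' complete data (batch adjustment, normalization) without inventing data
#' downstream.
#'
#' @param beta probes x samples beta matrix; every probe needs at least one
#'   observed value.
#' @param mask logical matrix from `mean_impute`.
#' @return `mean_impute`: list with `beta` (complete matrix) and `mask`;
#'   `restore_missing`: matrix with original missingness.
#' @export
mean_impute <- function(beta) {
  check_beta_matrix(beta, what = "values")  # works for beta or M matrices
  mask <- is.na(beta)
  all_missing <- rowSums(!mask) == 0
  if (any(all_missing))
    stop("probe(s) with no observed values: ",
         paste(utils::head(rownames(beta)[all_missing], 5), collapse = ", "))
  if (any(mask)) {
    means <- rowMeans(beta, na.rm = TRUE)
    idx <- which(mask, arr.ind = TRUE)
    beta[idx] <- means[idx[, 1]]
  }
  list(beta = beta, mask = mask)
}

#' @rdname mean_impute
#' @export
restore_missing <- function(beta, mask) {
  stopifnot(identical(dim(beta), dim(mask)))
  beta[mask] <- NA_real_
  beta
}
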