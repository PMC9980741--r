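#' @title Empirical-Bayes platform batch adjustment
#'
#' @description
#' Mixed 450K/EPIC cohorts carry an additive array-type shift on a subset of
#' probes. Beta-values are adjusted with parametric empirical Bayes
#' (ComBat): per-probe standardization, method-of-moments normal and
#' inverse-gamma priors on batch location and scale, iterative conditional
#' shrinkage, then back-transformation. Adjustment operates on complete
#' matrices; callers bracket it with [mean_impute()] / [restore_missing()].
#'
#' @name batchcorrect
NULL

#' Adjust beta-values for a batch variable
#'
#' @param beta probes x samples beta matrix without missing values.
#' @param batch vector of batch labels, one per sample (>= 2 levels, each
#'   with >= 2 samples). A single level returns the input unchanged with a
#'   warning.
#' @param covariates optional model matrix of covariates to protect (default
#'   none).
#' @return Adjusted beta matrix, clipped to \[0, 1\].
#' @export
eb_batch_adjust <- function(beta, batch, covariates = NULL) {
  check_beta_matrix(beta)
  if (anyNA(beta))
    stop("eb_batch_adjust requires a complete matrix; use mean_impute()/restore_missing()")
  if (length(batch) != ncol(beta))
    stop("one batch label per sample required")
  batch <- factor(batch)
  if (nlevels(batch) < 2) {
    warning("single batch level: returning input unchanged")
    return(beta)
  }
  if (any(table(batch) < 2))
    stop("every batch level needs at least 2 samples")
  mod <- if (is.null(covariates)) NULL else stats::model.matrix(~., data = as.data.frame(covariates))
  # constant probes make ComBat's standardization degenerate; pass them through
  v <- apply(beta, 1, stats::var)
  keep <- v > 0
  out <- beta
  adj <- suppressMessages(
    sva::ComBat(dat = beta[keep, , drop = FALSE], batch = batch, mod = mod,
                par.prior = TRUE, prior.plots = FALSE)
  )
  out[keep, ] <- adj
  pmin(pmax(out, 0), 1)
}

#' Principal-coordinate batch variance report
#'
#' Quantifies how much of the leading principal components of the beta
#' matrix is explained by batch, before and after adjustment: the R-squared
#' of each of the first `n_pcs` sample-space principal coordinates regressed
#' on the batch factor.
#'
#' @param beta_before,beta_after matched probes x samples beta matrices.
#' @param batch batch label per sample.
#' @param n_pcs number of leading components to report (default 5).
#' @return data.frame with columns `pc`, `r2_before`, `r2_after`,
#'   `var_explained_before`, `var_explained_after`.
#' @export
batch_effect_report <- function(beta_before, beta_after, batch, n_pcs = 5) {
  if (!identical(dim(beta_before), dim(beta_after)))
    stop("matrices must have identical shape")
  batch <- factor(batch)
  pc_r2 <- function(beta) {
    x <- t(beta)
    x <- x[, apply(x, 2, stats::var) > 0, drop = FALSE]
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    m <- min(n_pcs, ncol(pc$x))
    r2 <- vapply(seq_len(m), function(i)
      summary(stats::lm(pc$x[, i] ~ batch))$r.squared, 0)
    ve <- (pc$sdev[seq_len(m)]^2) / sum(pc$sdev^2)
    list(r2 = r2, ve = ve)
  }
  a <- pc_r2(beta_before)
  b <- pc_r2(beta_after)
  m <- min(length(a$r2), length(b$r2))
  data.frame(pc = seq_len(m),
             r2_before = a$r2[seq_len(m)], r2_after = b$r2[seq_len(m)],
             var_explained_before = a$ve[seq_len(m)],
             var_explained_after = b$ve[seq_len(m)])
}
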