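#' @title Bump-hunting differentially methylated regions with bootstrap FWER
#'
#' @description
#' Differential methylation between the severe and mild case subgroups is
#' modelled per CpG by ordinary least squares on the M-value,
#' `M ~ outcome + array type`, on M-values *without* batch adjustment (array
#' type is a model covariate instead). Probes on one chromosome separated by
#' at most `max_gap` bp form clusters; within a cluster, a maximal run of at
#' least `min_cpgs` consecutive probes whose outcome coefficients all exceed
#' the cutoff in the same direction is a candidate region. Its test
#' statistic is the area, the sum of absolute coefficients. Significance is
#' assessed against a bootstrap null: residuals from the reduced model
#' (covariates only) are resampled subject-wise, the full model refitted,
#' and candidate areas recollected; `fwerArea` is the proportion of
#' bootstraps whose maximum candidate area reaches the observed area
#' (family-wise error control), `p_valueArea` the proportion of pooled null
#' candidate areas reaching it.
#'
#' @name dmr
NULL

#' DMR search configuration
#'
#' @param cutoff M-scale effect-size threshold per CpG (default 1.0).
#' @param min_cpgs minimum CpGs per candidate region (default 2).
#' @param max_gap maximum intra-cluster gap in bp (default 500).
#' @param B bootstrap replicates (default 1000).
#' @param fwer_threshold significance cutoff on fwerArea (default 0.05).
#' @param seed bootstrap RNG seed.
#' @return Configuration list of class `dmr_config`.
#' @export
dmr_config <- function(cutoff = 1.0, min_cpgs = 2L, max_gap = 500L,
                       B = 1000L, fwer_threshold = 0.05, seed = 1L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (min_cpgs < 2) stop("min_cpgs must be >= 2")
  if (B < 1) stop("B must be >= 1")
  structure(list(cutoff = cutoff, min_cpgs = as.integer(min_cpgs),
                 max_gap = as.integer(max_gap), B = as.integer(B),
                 fwer_threshold = fwer_threshold, seed = as.integer(seed)),
            class = "dmr_config")
}

#' Per-CpG linear model fits
#'
#' OLS of M on a binary outcome plus optional covariates; subjects with a
#' missing M-value at a probe are dropped probewise. Probes whose design is
#' rank-deficient after dropping get `NA` coefficients.
#'
#' @param m probes x samples M-value matrix.
#' @param outcome 0/1 vector (length = samples); severe = 1, mild = 0.
#' @param covariates optional numeric vector/matrix of per-sample
#'   covariates (e.g. an array-type indicator).
#' @return data.frame: probe_id, coef (outcome coefficient), se, n_used.
#' @export
fit_cpg_models <- function(m, outcome, covariates = NULL) {
  if (length(unique(stats::na.omit(outcome))) < 2)
    stop("outcome is constant; per-CpG model undefined")
  if (!all(stats::na.omit(outcome) %in% c(0, 1))) stop("outcome must be 0/1")
  n <- ncol(m)
  X <- cbind(`(Intercept)` = 1, outcome = outcome)
  if (!is.null(covariates)) X <- cbind(X, covariates)
  q <- ncol(X)
  coef <- se <- rep(NA_real_, nrow(m))
  n_used <- integer(nrow(m))
  complete <- !apply(is.na(m), 1, any)
  if (any(complete)) {
    XtXi <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
    if (is.null(XtXi)) stop("rank-deficient design (outcome confounded with covariates)")
    Y <- t(m[complete, , drop = FALSE])
    B <- XtXi %*% crossprod(X, Y)
    res <- Y - X %*% B
    sigma2 <- colSums(res^2) / (n - q)
    coef[complete] <- B[2, ]
    se[complete] <- sqrt(sigma2 * XtXi[2, 2])
    n_used[complete] <- n
  }
  for (i in which(!complete)) {
    ok <- !is.na(m[i, ])
    Xi <- X[ok, , drop = FALSE]
    if (qr(Xi)$rank < q || length(unique(Xi[, 2])) < 2) next  # unusable probe
    fit <- stats::lm.fit(Xi, m[i, ok])
    coef[i] <- fit$coefficients[2]
    rdf <- sum(ok) - q
    se[i] <- if (rdf > 0) sqrt(sum(fit$residuals^2) / rdf *
                                 solve(crossprod(Xi))[2, 2]) else NA_real_
    n_used[i] <- sum(ok)
  }
  data.frame(probe_id = rownames(m), coef = coef, se = se, n_used = n_used,
             stringsAsFactors = FALSE)
}

#' Max-gap probe clustering
#'
#' Consecutive probes on one chromosome separated by at most `max_gap` bp
#' share a cluster; clusters break at chromosome boundaries and larger gaps.
#' Positions are sorted internally (stable) if needed, with a message.
#'
#' @param annotation data.frame with `probe_id`, `chrom`, `pos`.
#' @param max_gap gap threshold in bp.
#' @return Integer cluster id per annotation row (in the input row order).
#' @export
cluster_probes <- function(annotation, max_gap = 500) {
  ord <- order(annotation$chrom, annotation$pos)
  if (is.unsorted(ord)) message("positions unsorted; sorting internally (stable)")
  chrom <- annotation$chrom[ord]
  pos <- annotation$pos[ord]
  new_cluster <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                         diff(pos) > max_gap)
  ids_sorted <- cumsum(new_cluster)
  ids <- integer(nrow(annotation))
  ids[ord] <- ids_sorted
  ids
}

#' Candidate bump detection
#'
#' Within each probe cluster (probes in genomic order), maximal runs of
#' consecutive probes with coefficient >= +cutoff, or all <= -cutoff, of
#' length >= `min_cpgs` become candidate regions.
#'
#' @param coef numeric coefficient vector, one per probe, genomic order
#'   within clusters (NA treated as below cutoff).
#' @param clusters integer cluster id per probe (as from
#'   [cluster_probes()]).
#' @param config a [dmr_config()].
#' @return data.frame: cluster, index_start, index_end, L, direction, value
#'   (mean coefficient), area (sum of |coefficients|). Zero rows when no
#'   candidate qualifies.
#' @export
find_bumps <- function(coef, clusters, config = dmr_config()) {
  cat_of <- ifelse(is.na(coef), 0L,
                   ifelse(coef >= config$cutoff, 1L,
                          ifelse(coef <= -config$cutoff, -1L, 0L)))
  # a run must stay within one probe cluster and one sign category
  key <- paste0(clusters, ":", cat_of)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cat_run <- cat_of[starts]
  keep <- cat_run != 0L & r$lengths >= config$min_cpgs
  if (!any(keep))
    return(data.frame(cluster = integer(0), index_start = integer(0),
                      index_end = integer(0), L = integer(0),
                      direction = character(0), value = numeric(0),
                      area = numeric(0), stringsAsFactors = FALSE))
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(
    cluster = clusters[starts],
    index_start = starts, index_end = ends, L = ends - starts + 1L,
    direction = ifelse(cat_run[keep] > 0, "hyper", "hypo"),
    value = mapply(function(s, e) mean(coef[s:e]), starts, ends),
    area = mapply(function(s, e) sum(abs(coef[s:e])), starts, ends),
    stringsAsFactors = FALSE
  )
}

#' Bootstrap null distribution of candidate areas
#'
#' Fits the reduced model (intercept + covariates, no outcome) per probe,
#' forms null datasets as reduced fitted values plus subject-resampled
#' residual columns, refits the full model and re-runs the bump search with
#' the observed cutoff.
#'
#' @param m complete probes x samples M-value matrix (impute first).
#' @param outcome,covariates as in [fit_cpg_models()].
#' @param clusters probe cluster ids aligned with `m` rows.
#' @param config a [dmr_config()]; `config$B` replicates, seeded by
#'   `config$seed`.
#' @return List with `max_areas` (length B; 0 where a bootstrap had no
#'   candidate) and `pooled_areas` (all null candidate areas).
#' @export
bootstrap_null <- function(m, outcome, covariates = NULL, clusters,
                           config = dmr_config()) {
  if (anyNA(m)) stop("bootstrap_null requires a complete M matrix; impute first")
  set.seed(config$seed)
  n <- ncol(m)
  X <- cbind(1, outcome)
  if (!is.null(covariates)) X <- cbind(X, covariates)
  X0 <- X[, -2, drop = FALSE]
  Y <- t(m)                               # samples x probes
  B0 <- solve(crossprod(X0), crossprod(X0, Y))
  fitted0 <- X0 %*% B0
  resid0 <- Y - fitted0
  XtXi <- solve(crossprod(X))
  H <- XtXi %*% t(X)                      # coef = H %*% Y
  max_areas <- numeric(config$B)
  pooled <- vector("list", config$B)
  for (b in seq_len(config$B)) {
    idx <- sample.int(n, n, replace = TRUE)
    Yb <- fitted0 + resid0[idx, , drop = FALSE]
    coef_b <- (H %*% Yb)[2, ]
    cand <- find_bumps(coef_b, clusters, config)
    max_areas[b] <- if (nrow(cand)) max(cand$area) else 0
    pooled[[b]] <- cand$area
  }
  list(max_areas = max_areas, pooled_areas = unlist(pooled))
}

#' Score candidate regions against the bootstrap null
#'
#' `fwerArea` counts bootstraps whose maximum null candidate area is at
#' least the observed area; `p_valueArea` counts pooled null candidate
#' areas at least the observed area. A region is significant when
#' `fwerArea <= fwer_threshold`.
#'
#' @param candidates data.frame from [find_bumps()].
#' @param null list from [bootstrap_null()].
#' @param config a [dmr_config()].
#' @return Candidates with `fwerArea`, `p_valueArea`, `significant` (and a
#'   `p_value_flag` column when the pooled null was empty).
#' @export
score_dmrs <- function(candidates, null, config = dmr_config()) {
  B <- length(null$max_areas)
  candidates$fwerArea <- vapply(candidates$area,
                                function(a) mean(null$max_areas >= a), 0)
  if (length(null$pooled_areas) == 0) {
    candidates$p_valueArea <- rep(1 / B, nrow(candidates))
    candidates$p_value_flag <- rep("<1/B (no null candidates)", nrow(candidates))
  } else {
    candidates$p_valueArea <- vapply(candidates$area,
                                     function(a) mean(null$pooled_areas >= a), 0)
  }
  candidates$significant <- candidates$fwerArea <= config$fwer_threshold
  candidates
}

majority_label <- function(x) {
  if (length(x) == 0) return("")
  tab <- table(factor(x, levels = unique(x)))  # first-by-position tie-break
  names(tab)[which.max(tab)]
}

#' Annotate regions with gene, region class and island relation
#'
#' Labels are the majority vote over member probes; ties resolve to the
#' first label by genomic position. Regions whose probes carry no gene keep
#' an empty gene field.
#'
#' @param records candidate/scored data.frame whose `index_start`/`index_end`
#'   index rows of `annotation`.
#' @param annotation probe annotation aligned with the coefficient order.
#' @return Records with `chrom`, `start`, `end`, `gene`, `region`,
#'   `island`, `probes` (comma-joined probe ids).
#' @export
annotate_dmrs <- function(records, annotation) {
  if (nrow(records) == 0) {
    for (col in c("chrom", "gene", "region", "island", "probes"))
      records[[col]] <- character(0)
    for (col in c("start", "end")) records[[col]] <- integer(0)
    return(records)
  }
  ann_of <- function(s, e, col) annotation[[col]][s:e]
  records$chrom <- mapply(function(s, e) annotation$chrom[s], records$index_start,
                          records$index_end)
  records$start <- mapply(function(s, e) min(ann_of(s, e, "pos")),
                          records$index_start, records$index_end)
  records$end <- mapply(function(s, e) max(ann_of(s, e, "pos")),
                        records$index_start, records$index_end)
  records$gene <- mapply(function(s, e) majority_label(ann_of(s, e, "gene")),
                         records$index_start, records$index_end)
  records$region <- mapply(function(s, e) majority_label(ann_of(s, e, "region")),
                           records$index_start, records$index_end)
  records$island <- mapply(function(s, e) majority_label(ann_of(s, e, "island")),
                           records$index_start, records$index_end)
  records$probes <- mapply(function(s, e)
    paste(ann_of(s, e, "probe_id"), collapse = ","),
    records$index_start, records$index_end)
  records
}

#' Full DMR pipeline
#'
#' Sorts probes genomically, mean-imputes remaining missing M-values (so
#' observed and bootstrap statistics share one scale), fits the per-CpG
#' models, finds candidate bumps, scores them against the bootstrap null
#' and annotates them.
#'
#' @param m probes x samples M-value matrix (uncorrected for batch; array
#'   type enters as a covariate).
#' @param outcome 0/1 severe/mild indicator per sample.
#' @param covariates per-sample covariates (e.g. array-type indicator).
#' @param annotation probe annotation covering the rows of `m`.
#' @param config a [dmr_config()].
#' @return List with `dmrs` (annotated scored candidates), `fit`, `null`,
#'   `clusters`, `annotation` (sorted).
#' @export
find_dmrs <- function(m, outcome, covariates = NULL, annotation,
                      config = dmr_config()) {
  ann <- annotation[match(rownames(m), annotation$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id)) stop("annotation must cover every probe of m")
  ord <- order(ann$chrom, ann$pos)
  ann <- ann[ord, , drop = FALSE]
  m <- m[ord, , drop = FALSE]
  if (anyNA(m)) m <- mean_impute(m)$beta
  fit <- fit_cpg_models(m, outcome, covariates)
  clusters <- cluster_probes(ann, config$max_gap)
  cand <- find_bumps(fit$coef, clusters, config)
  null <- bootstrap_null(m, outcome, covariates, clusters, config)
  scored <- score_dmrs(cand, null, config)
  list(dmrs = annotate_dmrs(scored, ann), fit = fit, null = null,
       clusters = clusters, annotation = ann)
}
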