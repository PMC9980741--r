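#' @title Ward clustering of latent embeddings and subgroup definition
#'
#' @description
#' Patients are clustered by agglomerative hierarchical clustering with
#' Ward's minimum-variance linkage, either on Euclidean distances between
#' VAE latent coordinates or on the baseline distance (mean absolute
#' beta-value difference between two samples). The tree is cut at a chosen
#' k (default 4), clusters are renumbered by decreasing case proportion
#' (ties by decreasing size) so that case-dominant clusters come first, and
#' cases are split into "severe" (members of case-dominant clusters) and
#' "mild" (the rest).
#'
#' @name cluster
NULL

#' Ward linkage tree
#'
#' @param points samples x d coordinate matrix (Euclidean distances are
#'   computed), or a precomputed `dist` object.
#' @return `hclust` tree (Ward's method on squared Euclidean distances via
#'   `ward.D2`; merge heights are non-decreasing).
#' @export
ward_linkage <- function(points) {
  if (inherits(points, "dist")) {
    d <- points
  } else {
    if (!is.matrix(points)) points <- as.matrix(points)
    if (nrow(points) < 2) stop("need at least 2 samples")
    if (anyNA(points) || any(!is.finite(points)))
      stop("non-finite coordinates")
    d <- stats::dist(points)
  }
  stats::hclust(d, method = "ward.D2")
}

#' Baseline inter-sample distance: mean absolute beta difference
#'
#' Entry (i, j) is the mean over probes of |beta_i - beta_j|, averaged over
#' pairwise-complete probes.
#'
#' @param beta probes x samples beta matrix (missing allowed).
#' @return `dist` object over samples.
#' @export
baseline_distance <- function(beta) {
  check_beta_matrix(beta)
  n <- ncol(beta)
  dmat <- matrix(0, n, n, dimnames = list(colnames(beta), colnames(beta)))
  for (i in seq_len(n - 1)) {
    xi <- beta[, i]
    for (j in (i + 1):n) {
      dif <- abs(xi - beta[, j])
      ok <- !is.na(dif)
      if (!any(ok))
        stop("samples ", colnames(beta)[i], " and ", colnames(beta)[j],
             " share no observed probes")
      dmat[i, j] <- dmat[j, i] <- mean(dif[ok])
    }
  }
  stats::as.dist(dmat)
}

#' Cut a linkage tree into k clusters
#'
#' Clusters are renumbered 1..k by decreasing case proportion (when case
#' status is supplied), ties broken by decreasing size; without case status
#' the ordering falls back to decreasing size.
#'
#' @param tree `hclust` object from [ward_linkage()].
#' @param k number of clusters (1 <= k <= n).
#' @param case_status optional 0/1 vector named by sample id.
#' @param provenance label recorded with the assignment.
#' @return Object of class `cluster_assignment`: list with `cluster` (named
#'   integer vector), `k`, `provenance`.
#' @export
cut_tree <- function(tree, k, case_status = NULL, provenance = "embedding") {
  stopifnot(inherits(tree, "hclust"))
  raw <- stats::cutree(tree, k = k)
  sizes <- table(raw)
  if (!is.null(case_status)) {
    cs <- case_status[names(raw)]
    prop <- tapply(cs, raw, mean)
  } else {
    prop <- rep(0, length(sizes))
  }
  ord <- order(-prop, -as.vector(sizes))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(sizes)
  structure(list(cluster = stats::setNames(relabel[raw], names(raw)),
                 k = as.integer(k), provenance = provenance),
            class = "cluster_assignment")
}

perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
  out
}

#' Compare two cluster assignments
#'
#' Labels of `b` are matched one-to-one to labels of `a` by the permutation
#' maximizing agreement (exhaustive for k <= 8, greedy above); agreement is
#' the percentage of samples whose matched labels coincide. The adjusted
#' Rand index is reported on the unmatched labels (it is label-invariant).
#'
#' @param a,b `cluster_assignment` objects over the same samples.
#' @return List with `agreement` (percent), `confusion` (table, b rows
#'   relabeled), `ari`.
#' @export
compare_clusterings <- function(a, b) {
  ca <- a$cluster
  cb <- b$cluster[names(ca)]
  if (anyNA(cb) || length(b$cluster) != length(ca))
    stop("assignments must cover the same sample set")
  k <- max(a$k, b$k)
  tab <- table(factor(cb, levels = 1:k), factor(ca, levels = 1:k))
  if (k <= 8) {
    best <- NULL; best_n <- -1
    for (p in perms(1:k)) {
      hits <- sum(diag(tab[p, , drop = FALSE]))
      if (hits > best_n) { best_n <- hits; best <- p }
    }
    # best[i] is the b-label matched to a-label i; invert to a relabel map
    relab_vec <- order(best)
  } else {
    relab_vec <- integer(k); avail <- 1:k
    for (lab in order(-rowSums(tab))) {
      pick <- avail[which.max(tab[lab, avail])]
      relab_vec[lab] <- pick; avail <- setdiff(avail, pick)
    }
  }
  relab <- stats::setNames(relab_vec, 1:k)
  cb_matched <- relab[as.character(cb)]
  list(agreement = 100 * mean(cb_matched == ca),
       confusion = table(matched_b = cb_matched, a = ca),
       ari = mclust::adjustedRandIndex(ca, cb))
}

#' Severe/mild subgrouping of cases
#'
#' Clusters with case proportion strictly above 50 percent are
#' "case-dominant"; cases in those clusters form the severe subgroup, the
#' remaining cases the mild subgroup. Defined for cases only.
#'
#' @param assignment `cluster_assignment`.
#' @param case_status 0/1 vector named by sample id covering the same
#'   samples.
#' @return List with `subgroup` (named character vector over case samples,
#'   values "severe"/"mild"), `case_proportion` (per cluster),
#'   `dominant_clusters`.
#' @export
define_subgroups <- function(assignment, case_status) {
  cl <- assignment$cluster
  cs <- case_status[names(cl)]
  if (anyNA(cs)) stop("case status must cover every clustered sample")
  prop <- tapply(cs, cl, mean)
  dominant <- as.integer(names(prop))[prop > 0.5]
  if (length(dominant) == 0)
    stop("no case-dominant cluster (all case proportions <= 0.5): ",
         "subgrouping undefined")
  cases <- names(cl)[cs == 1]
  sub <- ifelse(cl[cases] %in% dominant, "severe", "mild")
  if (all(sub == "severe"))
    warning("every case falls in a case-dominant cluster; mild subgroup empty")
  list(subgroup = stats::setNames(sub, cases),
       case_proportion = prop, dominant_clusters = dominant)
}

#' Two-dimensional principal-coordinate embedding
#'
#' Centered PCA of sample coordinates, returning the top-2 scores with a
#' deterministic sign convention: each component's largest-magnitude loading
#' is positive.
#'
#' @param points samples x d coordinate matrix.
#' @return List with `scores` (samples x 2), `var_explained` (all
#'   components' variance fractions).
#' @export
pca_embedding <- function(points) {
  if (!is.matrix(points)) points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 samples")
  pc <- stats::prcomp(points, center = TRUE, scale. = FALSE)
  m <- min(2L, ncol(pc$rotation))
  for (i in seq_len(m)) {
    j <- which.max(abs(pc$rotation[, i]))
    if (pc$rotation[j, i] < 0) {
      pc$rotation[, i] <- -pc$rotation[, i]
      pc$x[, i] <- -pc$x[, i]
    }
  }
  scores <- pc$x[, seq_len(m), drop = FALSE]
  if (m < 2) scores <- cbind(scores, PC2 = 0)
  list(scores = scores, var_explained = pc$sdev^2 / sum(pc$sdev^2))
}
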