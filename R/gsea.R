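#' @title Hypergeometric gene-set over-representation of DMR genes
#'
#' @description
#' Genes harbouring significant DMRs at the promoter or gene body are
#' tested, separately by methylation direction, for over-representation in
#' curated gene sets with the one-sided hypergeometric test against a
#' background universe (by default all genes represented by at least one
#' retained probe); the Benjamini-Hochberg procedure controls the FDR.
#'
#' @name gsea
NULL

#' Genes from significant DMRs of one direction
#'
#' @param records annotated, scored DMR data.frame (from [find_dmrs()]).
#' @param direction "hypo" or "hyper".
#' @param significant_only restrict to `fwerArea`-significant records
#'   (default TRUE).
#' @return Unique gene symbols whose region class is Promoter or Body.
#' @export
select_dmr_genes <- function(records, direction = c("hypo", "hyper"),
                             significant_only = TRUE) {
  direction <- match.arg(direction)
  if (nrow(records) == 0) return(character(0))
  sel <- records$direction == direction &
    records$region %in% c("Promoter", "Body") & records$gene != ""
  if (significant_only && "significant" %in% names(records))
    sel <- sel & records$significant
  sort(unique(records$gene[sel]))
}

#' One-sided hypergeometric over-representation p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing n query genes from a
#' universe of N containing K set members.
#'
#' @param k overlap count; `n` query size; `K` set size; `N` universe size.
#' @param n,K,N see above.
#' @return Upper-tail probability (computed via the stable distribution
#'   tail, exact for k = 0 at 1).
#' @export
hypergeom_overrep <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || k > min(n, K) || n > N || K > N)
    stop("inconsistent counts: need 0 <= k <= min(n, K) <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in \[0,1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Run over-representation analysis for one direction
#'
#' @param records annotated, scored DMR data.frame.
#' @param collection list with `sets` (named list of gene vectors) and
#'   `universe` (background gene symbols); set genes are restricted to the
#'   universe.
#' @param direction "hypo" or "hyper".
#' @return data.frame sorted by p: set, K (set size in universe), k
#'   (overlap), overlap_genes, n (query size), N (universe size), p, adj_p.
#'   An empty query yields all p = 1 with a note attribute.
#' @export
run_gsea <- function(records, collection, direction = c("hypo", "hyper")) {
  direction <- match.arg(direction)
  universe <- unique(collection$universe)
  if (length(universe) == 0) stop("empty background universe")
  query <- intersect(select_dmr_genes(records, direction), universe)
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(collection$sets), function(nm) {
    set_genes <- intersect(unique(trimws(collection$sets[[nm]])), universe)
    ov <- intersect(query, set_genes)
    k <- length(ov)
    data.frame(set = nm, K = length(set_genes), k = k,
               overlap_genes = paste(sort(ov), collapse = ","),
               n = n, N = N,
               p = if (length(set_genes) == 0) 1
                   else hypergeom_overrep(k, n, length(set_genes), N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(set = character(0), K = integer(0),
                                      k = integer(0), overlap_genes = character(0),
                                      n = integer(0), N = integer(0),
                                      p = numeric(0))
  out$adj_p <- if (nrow(out)) bh_adjust(out$p) else numeric(0)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  if (n == 0) attr(out, "note") <- "empty query: all p = 1"
  out
}

#' Background universe from retained probes
#'
#' @param annotation probe annotation restricted to the retained probe set.
#' @return Sorted unique gene symbols with at least one probe.
#' @export
gene_universe <- function(annotation) {
  sort(unique(annotation$gene[annotation$gene != ""]))
}
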