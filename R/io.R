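#' @title Plain-text fixture input/output
#'
#' @description
#' The pipeline's on-disk formats are deliberately plain: TSV matrices with a
#' probe-id first column and empty fields for missing values, a CSV sample
#' sheet, a TSV probe annotation and GMT gene sets. Numeric values are
#' written with 17 significant digits so write/read round-trips are
#' bit-identical.
#'
#' @name fixture-io
NULL

write_numeric_tsv <- function(mat, path, id_col = "probe_id") {
  df <- data.frame(rownames(mat),
                   apply(mat, 2, function(x) ifelse(is.na(x), "", sprintf("%.17g", x))),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c(id_col, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_numeric_tsv <- function(path, id_col = "probe_id") {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  mat <- apply(as.matrix(df[, -1, drop = FALSE]), 2,
               function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x))))
  rownames(mat) <- df[[id_col]]
  mat
}

#' Write a gene-set collection in GMT format
#'
#' One line per set: name, description, then member genes, tab-separated.
#' An empty collection produces a valid empty file.
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file; may be empty.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (file.size(path) == 0) return(stats::setNames(list(), character(0)))
  fgsea::gmtPathways(path)
}

#' Write a simulated cohort bundle to a directory
#'
#' Writes the beta and detection p-value matrices (TSV, missing as empty
#' field), the sample sheet (CSV), the probe annotation (TSV), gene sets
#' (GMT) and the ground-truth tables (TSV). Reading back with
#' [read_fixture()] round-trips bit-identically.
#'
#' @param bundle result of [simulate_cohort()].
#' @param directory output directory, created if needed.
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(bundle, directory) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok || file.access(directory, 2) != 0)
    stop("cannot write to directory: ", directory)
  paths <- c(
    beta = file.path(directory, "beta.tsv"),
    detp = file.path(directory, "detection_p.tsv"),
    samples = file.path(directory, "samples.csv"),
    annotation = file.path(directory, "annotation.tsv"),
    gene_sets = file.path(directory, "gene_sets.gmt"),
    truth_subjects = file.path(directory, "truth_subjects.tsv"),
    truth_dmrs = file.path(directory, "truth_dmrs.tsv")
  )
  write_numeric_tsv(bundle$beta, paths["beta"])
  write_numeric_tsv(bundle$detp, paths["detp"])
  utils::write.csv(bundle$samples, paths["samples"], row.names = FALSE)
  utils::write.table(bundle$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(bundle$gene_sets$sets, paths["gene_sets"])
  ts <- data.frame(sample_id = names(bundle$truth$cluster),
                   cluster = unname(bundle$truth$cluster),
                   case = unname(bundle$truth$case),
                   platform = unname(bundle$truth$batch),
                   stringsAsFactors = FALSE)
  utils::write.table(ts, paths["truth_subjects"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$truth$dmr_intervals, paths["truth_dmrs"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @rdname write_fixture
#' @param directory directory previously written by [write_fixture()].
#' @export
read_fixture <- function(directory) {
  list(
    beta = read_numeric_tsv(file.path(directory, "beta.tsv")),
    detp = read_numeric_tsv(file.path(directory, "detection_p.tsv")),
    samples = utils::read.csv(file.path(directory, "samples.csv"),
                              stringsAsFactors = FALSE),
    annotation = utils::read.delim(file.path(directory, "annotation.tsv"),
                                   stringsAsFactors = FALSE),
    gene_sets = read_gmt(file.path(directory, "gene_sets.gmt")),
    truth_subjects = utils::read.delim(file.path(directory, "truth_subjects.tsv"),
                                       stringsAsFactors = FALSE),
    truth_dmrs = utils::read.delim(file.path(directory, "truth_dmrs.tsv"),
                                   stringsAsFactors = FALSE)
  )
}
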