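#' @title Cluster- and subgroup-level clinical phenotype association
#'
#' @description
#' Phenotype testing follows a fixed dispatch: binary and nominal variables
#' are tested with the Pearson chi-square test of independence (Yates
#' continuity correction for 2x2 tables), ordinal and continuous variables
#' with the Wilcoxon rank-sum test for two groups or the Kruskal-Wallis test
#' for more. Two special preprocessing rules apply before testing: a missing
#' focus score is set to zero when the biopsy diagnosis shows no focal
#' lymphocytic sialadenitis (within normal limits, non-specific chronic
#' inflammation, or sclerosing chronic sialadenitis), and tear break-up
#' times of 10 seconds or more are truncated to 10.
#'
#' @name assoc
NULL

#' Construct a typed phenotype table
#'
#' @param data data.frame with a `sample_id` column and one column per
#'   phenotype.
#' @param types named character vector over phenotype columns, values in
#'   binary/nominal/ordinal/continuous.
#' @param rules optional named character vector of special-rule tags
#'   (`focus_score_rule`, `tbut_truncation`).
#' @return `phenotype_table` (a data.frame with type/rule attributes).
#' @export
phenotype_table <- function(data, types, rules = NULL) {
  stopifnot("sample_id" %in% names(data))
  vars <- setdiff(names(data), "sample_id")
  if (!all(vars %in% names(types)))
    stop("untyped variable(s): ",
         paste(setdiff(vars, names(types)), collapse = ", "))
  bad <- !types[vars] %in% c("binary", "nominal", "ordinal", "continuous")
  if (any(bad)) stop("unknown type for: ", paste(vars[bad], collapse = ", "))
  for (v in vars) {
    x <- data[[v]]
    if (types[v] == "binary" && !all(stats::na.omit(x) %in% c(0, 1)))
      stop("binary variable ", v, " must be coded {0,1}")
    if (types[v] %in% c("ordinal", "continuous") && !is.numeric(x))
      stop(types[v], " variable ", v, " must be numeric")
  }
  structure(data, types = types[vars],
            rules = if (is.null(rules)) stats::setNames(rep(NA_character_, length(vars)), vars)
                    else rules,
            class = c("phenotype_table", "data.frame"))
}

benign_biopsy_levels <- c("within normal limits",
                          "non-specific chronic inflammation",
                          "sclerosing chronic sialadenitis")

#' Apply the focus-score and tear-break-up special rules
#'
#' @param pheno a [phenotype_table()]; variables tagged `focus_score_rule`
#'   need a companion `biopsy_diagnosis` column.
#' @return The table with rules applied; all other values untouched.
#' @export
apply_special_rules <- function(pheno) {
  rules <- attr(pheno, "rules")
  types <- attr(pheno, "types")
  for (v in names(rules)[!is.na(rules)]) {
    if (!types[v] %in% c("continuous", "ordinal"))
      stop("rule ", rules[v], " on non-numeric variable ", v)
    if (rules[v] == "focus_score_rule") {
      if (!"biopsy_diagnosis" %in% names(pheno))
        stop("focus_score_rule requires a biopsy_diagnosis column")
      fix <- is.na(pheno[[v]]) & pheno$biopsy_diagnosis %in% benign_biopsy_levels
      pheno[[v]][fix] <- 0
    } else if (rules[v] == "tbut_truncation") {
      pheno[[v]][!is.na(pheno[[v]]) & pheno[[v]] >= 10] <- 10
    } else stop("unknown rule tag: ", rules[v])
  }
  pheno
}

#' Pearson chi-square test of independence
#'
#' Yates continuity correction defaults to on for 2x2 tables and off
#' otherwise.
#'
#' @param tab r x c matrix of non-negative integer counts.
#' @param yates logical; default `NULL` means "2x2 only".
#' @return List with `statistic`, `p`, `df`.
#' @export
chisq_independence <- function(tab, yates = NULL) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row/column margin")
  if (is.null(yates)) yates <- nrow(tab) == 2 && ncol(tab) == 2
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter))
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Tie-corrected normal approximation by default; exact enumeration when
#' both groups have at most 10 observations and no ties straddle the
#' groups.
#'
#' @param x,y numeric vectors (missing values dropped).
#' @return List with `statistic` (rank-sum W), `p`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  use_exact <- length(x) <= 10 && length(y) <= 10 &&
    !any(duplicated(c(x, y)))
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = FALSE))
  p <- res$p.value
  if (is.nan(p)) p <- 1  # all observations identical: no evidence either way
  list(statistic = unname(res$statistic), p = min(p, 1))
}

#' Kruskal-Wallis rank test
#'
#' @param groups list of numeric vectors (missing values dropped).
#' @return List with `statistic` (chi-square), `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0)) stop("empty group")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1)
    return(list(statistic = 0, p = 1, df = length(groups) - 1))
  res <- stats::kruskal.test(vals, factor(rep(seq_along(groups), lengths(groups))))
  list(statistic = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter))
}

#' Phenotype association table for a grouping
#'
#' For every typed phenotype: binary/nominal variables go to the chi-square
#' test of independence, ordinal/continuous variables to Wilcoxon (2 groups)
#' or Kruskal-Wallis (more). Missing values are dropped per variable.
#' Degenerate variables (constant, or all-missing) are kept in the output
#' with `NA` p-values and a note, matching how an invariant phenotype row is
#' reported.
#'
#' @param pheno a [phenotype_table()] (special rules should be applied
#'   first).
#' @param grouping a `cluster_assignment`, the result of
#'   [define_subgroups()], or a named vector of group labels over sample
#'   ids.
#' @param alpha significance level for the flag column (default 0.05).
#' @return data.frame: variable, type, test, per-group summary columns
#'   ("mean (SD)" or percent), statistic, p, significant, note.
#' @export
association_table <- function(pheno, grouping, alpha = 0.05) {
  if (inherits(grouping, "cluster_assignment")) grouping <- grouping$cluster
  if (is.list(grouping) && !is.null(grouping$subgroup)) grouping <- grouping$subgroup
  ids <- intersect(pheno$sample_id, names(grouping))
  if (length(ids) == 0) stop("grouping does not cover the phenotype samples")
  g <- factor(grouping[ids])
  df <- pheno[match(ids, pheno$sample_id), , drop = FALSE]
  types <- attr(pheno, "types")
  levs <- levels(g)
  out <- list()
  for (v in names(types)) {
    x <- df[[v]]
    type <- types[v]
    row <- list(variable = v, type = type, test = NA_character_,
                statistic = NA_real_, p = NA_real_,
                significant = NA, note = "")
    summ <- character(length(levs))
    for (i in seq_along(levs)) {
      xi <- x[g == levs[i]]
      xi <- xi[!is.na(xi)]
      summ[i] <- if (length(xi) == 0) "NA"
        else if (type == "binary") sprintf("%.2f", 100 * mean(xi))
        else if (type == "nominal") paste0(names(which.max(table(xi))), " (mode)")
        else sprintf("%.2f (%.2f)", mean(xi), stats::sd(xi))
    }
    names(summ) <- paste0("group_", levs)
    ok <- !is.na(x)
    if (!any(ok)) {
      row$note <- "all missing; skipped"
    } else if (length(unique(x[ok])) < 2) {
      row$note <- "constant across samples; NA"
    } else if (type %in% c("binary", "nominal")) {
      tab <- table(g[ok], x[ok])
      if (any(rowSums(tab) == 0)) {
        row$note <- "empty group after dropping missing"
      } else {
        res <- chisq_independence(tab)
        corr <- nrow(tab) == 2 && ncol(tab) == 2
        row$test <- if (corr) "chi-square (Yates)" else "chi-square"
        row$statistic <- res$statistic; row$p <- res$p
      }
    } else {
      gl <- split(x[ok], g[ok])
      if (length(gl) == 2) {
        res <- wilcoxon_ranksum(gl[[1]], gl[[2]])
        row$test <- "wilcoxon"
      } else {
        res <- kruskal_wallis(gl)
        row$test <- "kruskal-wallis"
      }
      row$statistic <- res$statistic; row$p <- res$p
    }
    row$significant <- if (is.na(row$p)) NA else row$p < alpha
    out[[v]] <- cbind(data.frame(row[c("variable", "type", "test")],
                                 stringsAsFactors = FALSE),
                      as.data.frame(as.list(summ), stringsAsFactors = FALSE,
                                    check.names = FALSE),
                      data.frame(row[c("statistic", "p", "significant", "note")],
                                 stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
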