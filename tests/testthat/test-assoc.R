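make_pheno <- function(df, types, rules = NULL) {
  phenotype_table(df, types, rules)
}

test_that("focus-score and tear-break-up special rules apply exactly", {
  df <- data.frame(
    sample_id = sprintf("S%d", 1:4),
    focus_score = c(NA, NA, 2.5, NA),
    biopsy_diagnosis = c("within normal limits", "focal lymphocytic sialadenitis",
                         "focal lymphocytic sialadenitis",
                         "sclerosing chronic sialadenitis"),
    tbut = c(12, 4.5, 10, 9.99),
    stringsAsFactors = FALSE)
  pt <- make_pheno(df,
    types = c(focus_score = "continuous", biopsy_diagnosis = "nominal",
              tbut = "continuous"),
    rules = c(focus_score = "focus_score_rule", tbut = "tbut_truncation"))
  out <- apply_special_rules(pt)
  expect_equal(out$focus_score, c(0, NA, 2.5, 0))
  expect_equal(out$tbut, c(10, 4.5, 10, 9.99))
  # rule on an incompatible type is rejected
  bad <- make_pheno(df["sample_id"] |> cbind(x = c("a", "b", "c", "d")),
                    types = c(x = "nominal"), rules = c(x = "tbut_truncation"))
  expect_error(apply_special_rules(bad), "non-numeric")
})

test_that("chi-square of independence matches the published contingency tests", {
  # severe/mild anti-Ro/SSA: 33.33% of 24 and 80.00% of 40, Yates-corrected
  ro <- rbind(c(8, 16), c(32, 8))
  expect_equal(signif(chisq_independence(ro)$p, 3), 5.27e-4)
  # four-cluster case-status table, no correction
  ss <- rbind(c(23, 3), c(17, 0), c(11, 41), c(13, 23))
  expect_equal(signif(chisq_independence(ss)$p, 3), 2.43e-11)
  # independence: statistic 0, p 1
  flat <- rbind(c(10, 10), c(10, 10))
  res <- chisq_independence(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(chisq_independence(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(chisq_independence(rbind(c(1.5, 2), c(1, 2))), "integers")
})

test_that("Yates correction never exceeds the uncorrected statistic", {
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 15) + 1, 2, 2)
    expect_lte(chisq_independence(tab, yates = TRUE)$statistic,
               chisq_independence(tab, yates = FALSE)$statistic)
  }
})

test_that("rank-sum test matches exhaustive enumeration for tiny groups", {
  # oracle: enumerate all C(6,3) = 20 rank assignments of {1..6}
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  combos <- combn(6, 3)
  obs_sum <- sum(rank(c(x, y))[1:3])
  # two-sided exact p: the rank-sum null is symmetric, so double one tail
  exact_p <- 2 * sum(colSums(combos) <= obs_sum) / ncol(combos)
  expect_equal(exact_p, 0.1)
  res <- wilcoxon_ranksum(x, y)
  expect_equal(res$p, 0.1)
  expect_equal(res$statistic, 0)  # minimal Mann-Whitney statistic
  # identical groups: no evidence
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(wilcoxon_ranksum(numeric(0), y), "empty group")
})

test_that("two-group Kruskal-Wallis equals the squared normal approximation", {
  set.seed(8)
  for (i in 1:10) {
    x <- sample(1:8, 25, replace = TRUE)  # heavy ties
    y <- sample(2:9, 30, replace = TRUE)
    kw <- kruskal_wallis(list(x, y))
    wl <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    z2 <- stats::qnorm(wl$p.value / 2)^2
    expect_equal(kw$statistic, z2, tolerance = 1e-9)
    expect_equal(kw$p, wl$p.value, tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis p-values are uniform under the null", {
  set.seed(42)
  pvals <- vapply(1:500, function(i) {
    g <- lapply(1:3, function(j) rnorm(15))
    kruskal_wallis(g)$p
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("association table dispatches by type and reproduces subgroup rows", {
  # reconstructed severe/mild binary phenotypes from the printed percentages
  n_mild <- 24; n_severe <- 40
  counts <- list(          #  mild+, severe+
    anti_ro = c(8, 32), anti_la = c(6, 29), rf = c(7, 32),
    ana_1_320 = c(11, 34), gc_formation = c(0, 10))
  expected_p <- c(anti_ro = 5.27e-4, anti_la = 5.90e-4, rf = 1.63e-4,
                  ana_1_320 = 2.38e-3, gc_formation = 2.08e-2)
  df <- data.frame(sample_id = sprintf("S%03d", 1:64), stringsAsFactors = FALSE)
  grp <- setNames(rep(c("mild", "severe"), c(n_mild, n_severe)), df$sample_id)
  for (v in names(counts)) {
    df[[v]] <- c(rep(c(1, 0), c(counts[[v]][1], n_mild - counts[[v]][1])),
                 rep(c(1, 0), c(counts[[v]][2], n_severe - counts[[v]][2])))
  }
  df$lymphoma <- 0
  df$igg <- c(rnorm(n_mild, 1350, 600), rnorm(n_severe, 1700, 600))
  types <- c(setNames(rep("binary", 6), c(names(counts), "lymphoma")),
             igg = "continuous")
  pt <- make_pheno(df, types)
  tab <- association_table(pt, grp)
  for (v in names(expected_p)) {
    row <- tab[tab$variable == v, ]
    expect_identical(row$test, "chi-square (Yates)")
    expect_equal(signif(row$p, 3), unname(expected_p[v]))
    expect_true(row$significant)
  }
  # constant variable (no lymphoma cases) reports NA like the published table
  lym <- tab[tab$variable == "lymphoma", ]
  expect_true(is.na(lym$p))
  expect_match(lym$note, "constant")
  # continuous variable uses the rank-sum test for two groups
  expect_identical(tab[tab$variable == "igg", "test"], "wilcoxon")
  # four groups dispatch to Kruskal-Wallis
  grp4 <- setNames(rep(1:4, each = 16), df$sample_id)
  tab4 <- association_table(pt, grp4)
  expect_identical(tab4[tab4$variable == "igg", "test"], "kruskal-wallis")
  expect_identical(tab4[tab4$variable == "anti_ro", "test"], "chi-square")
})

test_that("all-missing variables are skipped with a note", {
  df <- data.frame(sample_id = sprintf("S%d", 1:10), x = NA_real_,
                   y = rnorm(10))
  pt <- make_pheno(df, c(x = "continuous", y = "continuous"))
  grp <- setNames(rep(c("a", "b"), 5), df$sample_id)
  tab <- association_table(pt, grp)
  expect_match(tab[tab$variable == "x", "note"], "all missing")
  expect_true(is.na(tab[tab$variable == "x", "p"]))
  expect_false(is.na(tab[tab$variable == "y", "p"]))
})

test_that("untyped variables are rejected at construction", {
  df <- data.frame(sample_id = "S1", x = 1)
  expect_error(phenotype_table(df, c(y = "binary")), "untyped")
  expect_error(phenotype_table(data.frame(sample_id = "S1", x = 2),
                               c(x = "binary")), "coded \\{0,1\\}")
})
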