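test_that("per-CpG fits recover group differences and respect covariates", {
  m <- tiny_beta(rbind(c(0, 0, 2, 2), c(1, 1, 1, 1) * 0.5))
  fit <- fit_cpg_models(m, outcome = c(0, 0, 1, 1))
  expect_equal(fit$coef[1], 2)
  expect_equal(fit$coef[2], 0)
  # covariate orthogonal to the outcome leaves the coefficient unchanged
  set.seed(2)
  m2 <- tiny_beta(matrix(rnorm(8 * 40), 8, 40))
  outcome <- rep(c(0, 1), 20)
  cov_orth <- rep(c(-1, -1, 1, 1), 10)  # balanced within outcome groups
  f0 <- fit_cpg_models(m2, outcome)
  f1 <- fit_cpg_models(m2, outcome, covariates = cbind(cov_orth))
  expect_equal(f1$coef, f0$coef, tolerance = 1e-10)
  expect_error(fit_cpg_models(m2, rep(1, 40)), "constant")
  # probewise missing handling
  m3 <- m2; m3[1, 1:2] <- NA
  f3 <- fit_cpg_models(m3, outcome)
  expect_equal(f3$n_used[1], 38)
  expect_equal(f3$coef[-1], f0$coef[-1], tolerance = 1e-10)
})

test_that("max-gap probe clustering follows the gap and chromosome rules", {
  ann <- data.frame(probe_id = c("a", "b", "c"), chrom = "chr1",
                    pos = c(100, 400, 2000))
  expect_equal(cluster_probes(ann, 500), c(1, 1, 2))
  # chromosome break
  ann2 <- data.frame(probe_id = c("a", "b"), chrom = c("chr1", "chr2"),
                     pos = c(100, 150))
  expect_equal(cluster_probes(ann2, 500), c(1, 2))
  # duplicate coordinate shares a cluster; singleton chromosome is its own
  ann3 <- data.frame(probe_id = c("a", "b", "c"), chrom = c("chr1", "chr1", "chr2"),
                     pos = c(100, 100, 5))
  expect_equal(cluster_probes(ann3, 500), c(1, 1, 2))
})

test_that("bump detection matches the definition on worked examples", {
  cfg <- dmr_config(B = 1L)
  res <- find_bumps(c(0.2, 1.5, 1.7, 0.3), rep(1, 4), cfg)
  expect_equal(nrow(res), 1)
  expect_equal(res$L, 2)
  expect_equal(res$value, 1.6)
  expect_equal(res$area, 3.2)
  expect_identical(res$direction, "hyper")
  # a single probe above cutoff is not enough
  expect_equal(nrow(find_bumps(c(1.2), 1, cfg)), 0)
  # sign changes break runs
  expect_equal(nrow(find_bumps(c(1.5, -1.5, 1.5), rep(1, 3), cfg)), 0)
})

test_that("bump detection equals exhaustive run enumeration on random vectors", {
  set.seed(99)
  cfg <- dmr_config(B = 1L)
  for (i in 1:300) {
    n <- sample(2:20, 1)
    coef <- rnorm(n, 0, 1.2)
    coef[runif(n) < 0.1] <- NA
    clusters <- sort(sample(1:3, n, replace = TRUE))
    got <- find_bumps(coef, clusters, cfg)
    want <- bump_oracle(coef, clusters)
    got <- got[order(got$index_start), , drop = FALSE]
    expect_equal(got$index_start, want$index_start)
    expect_equal(got$index_end, want$index_end)
    expect_equal(got$value, want$value)
    expect_equal(got$area, want$area)
    expect_equal(got$direction, want$direction)
  }
})

test_that("raising the cutoff never increases the candidate count", {
  set.seed(12)
  coef <- rnorm(300, 0, 1.5)
  clusters <- sort(sample(1:30, 300, replace = TRUE))
  counts <- vapply(c(0.5, 1, 1.5, 2), function(co)
    nrow(find_bumps(coef, clusters, dmr_config(cutoff = co, B = 1L))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("region scoring counts bootstrap exceedances as stated", {
  cand <- data.frame(cluster = 1, index_start = 1, index_end = 2, L = 2,
                     direction = "hyper", value = 1.6, area = 3.2)
  null <- list(max_areas = c(1, 2, 3.5, 4), pooled_areas = c(1, 2, 3.5, 4, 0.5))
  cfg <- dmr_config(B = 4L)
  sc <- score_dmrs(cand, null, cfg)
  expect_equal(sc$fwerArea, 0.5)
  expect_equal(sc$p_valueArea, 2 / 5)
  # observed above all null maxima: fwer 0; below all: 1
  sc0 <- score_dmrs(transform(cand, area = 10), null, cfg)
  expect_equal(sc0$fwerArea, 0)
  sc1 <- score_dmrs(transform(cand, area = 0.5), null, cfg)
  expect_equal(sc1$fwerArea, 1)
  # empty pooled null flagged
  scf <- score_dmrs(cand, list(max_areas = rep(0, 4), pooled_areas = numeric(0)), cfg)
  expect_match(scf$p_value_flag, "1/B")
})

test_that("bootstrap null is reproducible and detects planted power", {
  set.seed(1)
  n <- 60; p <- 80
  outcome <- rep(c(0, 1), each = n / 2)
  m <- matrix(rnorm(p * n, 0, 0.8), p, n,
              dimnames = list(sprintf("cg%03d", 1:p), sprintf("S%03d", 1:n)))
  m[11:20, outcome == 1] <- m[11:20, outcome == 1] + 3  # 10-probe block, effect 3
  clusters <- rep(1:8, each = 10)
  cfg <- dmr_config(B = 200L, seed = 7L)
  fit <- fit_cpg_models(m, outcome)
  cand <- find_bumps(fit$coef, clusters, cfg)
  expect_true(any(cand$area >= 10 * 3 * 0.8))
  null <- bootstrap_null(m, outcome, NULL, clusters, cfg)
  expect_gt(max(cand$area), max(null$max_areas))
  # determinism with B = 1
  one <- dmr_config(B = 1L, seed = 5L)
  n1 <- bootstrap_null(m, outcome, NULL, clusters, one)
  n2 <- bootstrap_null(m, outcome, NULL, clusters, one)
  expect_identical(n1, n2)
})

test_that("observed statistics are exchangeable with the null on null data", {
  # noisy small-sample fixture so candidate bumps actually arise by chance
  set.seed(33)
  quantiles <- vapply(1:12, function(i) {
    n <- 40; p <- 60
    outcome <- rep(c(0, 1), each = n / 2)
    m <- matrix(rnorm(p * n, 0, 2), p, n,
                dimnames = list(sprintf("cg%03d", 1:p), sprintf("S%03d", 1:n)))
    clusters <- rep(1:6, each = 10)
    cfg <- dmr_config(B = 60L, seed = i)
    fit <- fit_cpg_models(m, outcome)
    cand <- find_bumps(fit$coef, clusters, cfg)
    obs <- if (nrow(cand)) max(cand$area) else 0
    null <- bootstrap_null(m, outcome, NULL, clusters, cfg)
    mean(null$max_areas <= obs)
  }, 0)
  expect_gte(mean(quantiles >= 0.01 & quantiles <= 0.99), 0.75)
})

test_that("annotation assigns majority labels with positional tie-breaks", {
  ann <- data.frame(probe_id = c("a", "b", "c"), chrom = "chr1",
                    pos = c(10, 20, 30), gene = c("G1", "G1", "G2"),
                    region = c("Body", "Promoter", "Body"),
                    island = c("Island", "Island", "OpenSea"))
  rec <- data.frame(cluster = 1, index_start = 1, index_end = 3, L = 3,
                    direction = "hypo", value = -1.5, area = 4.5)
  out <- annotate_dmrs(rec, ann)
  expect_identical(out$gene, "G1")
  expect_identical(out$region, "Body")  # 2 Body vs 1 Promoter
  expect_identical(out$island, "Island")
  expect_equal(out$start, 10)
  expect_equal(out$end, 30)
  # all probes intergenic: empty gene
  ann2 <- transform(ann, gene = "", region = "Intergenic")
  out2 <- annotate_dmrs(rec, ann2)
  expect_identical(out2$gene, "")
  expect_identical(out2$region, "Intergenic")
})

test_that("the full DMR pipeline recovers planted severe/mild blocks", {
  b <- small_cohort(seed = 41, n_cpgs = 800)
  truth_cl <- b$truth$cluster
  case <- b$truth$case
  # use the true clusters for the subgrouping to isolate the DMR stage
  cases <- names(case)[case == 1]
  outcome <- as.integer(truth_cl[cases] %in% c(1, 2))
  m <- beta_to_m(b$beta[, cases])
  arr <- as.integer(b$truth$batch[cases] == "450K")
  res <- find_dmrs(m, outcome, covariates = cbind(arr), annotation = b$annotation,
                   config = dmr_config(B = 150L, seed = 3L))
  d <- res$dmrs[res$dmrs$significant, ]
  tv <- b$truth$dmr_intervals[b$truth$dmr_intervals$severe_vs_mild, ]
  hit <- mapply(function(ch, s, e, dir)
    any(d$chrom == ch & d$start <= e & d$end >= s & d$direction == dir),
    tv$chrom, tv$start, tv$end, tv$direction)
  expect_gte(mean(hit), 0.8)
  # direction consistency: hypomethylated regions have negative values
  expect_true(all(d$value[d$direction == "hypo"] < 0))
  expect_true(all(d$value[d$direction == "hyper"] > 0))
  expect_true(all(d$area >= d$L * 1.0))
  # lowering the threshold never adds significant regions
  stricter <- score_dmrs(res$dmrs, res$null, dmr_config(fwer_threshold = 0.01, B = 150L))
  expect_lte(sum(stricter$significant), sum(res$dmrs$significant))
})
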