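test_that("Ward linkage reproduces the minimum-variance merge order", {
  # 1-D points {0, 1, 3}: merging {0,1} raises within-cluster variance least
  pts <- tiny_beta(cbind(c(0, 1, 3)))
  tree <- ward_linkage(pts)
  expect_identical(sort(tree$merge[1, ]), c(-2L, -1L))
  # exact duplicates merge first at height 0
  dup <- tiny_beta(cbind(c(0.5, 0.5, 2, 9)))
  tree2 <- ward_linkage(dup)
  expect_identical(sort(tree2$merge[1, ]), c(-2L, -1L))
  expect_equal(tree2$height[1], 0)
  # two well-separated pairs split at k = 2
  pairs <- tiny_beta(rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10)))
  cl <- stats::cutree(ward_linkage(pairs), 2)
  expect_equal(length(unique(cl[1:2])), 1)
  expect_equal(length(unique(cl[3:4])), 1)
  expect_false(cl[1] == cl[3])
  expect_error(ward_linkage(tiny_beta(cbind(c(NA, 1)))), "finite")
})

test_that("merge heights are non-decreasing and cuts nest", {
  set.seed(7)
  pts <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(sprintf("S%02d", 1:40), NULL))
  tree <- ward_linkage(pts)
  expect_true(all(diff(tree$height) >= -1e-10))
  for (k in 2:6) {
    fine <- stats::cutree(tree, k)
    coarse <- stats::cutree(tree, k - 1)
    # every fine cluster maps into exactly one coarse cluster
    expect_true(all(tapply(coarse, fine, function(x) length(unique(x))) == 1))
  }
})

test_that("baseline distance is the mean absolute beta difference", {
  b <- tiny_beta(cbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(as.vector(baseline_distance(b)), 1)
  b2 <- tiny_beta(cbind(c(0.2, 0.4), c(0.4, 0.8)))
  expect_equal(as.vector(baseline_distance(b2)), 0.3)
  same <- tiny_beta(cbind(c(0.3, 0.6), c(0.3, 0.6)))
  expect_equal(as.vector(baseline_distance(same)), 0)
  # pairwise-complete averaging; full disjoint missing is rejected
  miss <- tiny_beta(cbind(c(0.2, NA), c(NA, 0.4)))
  expect_error(baseline_distance(miss), "no observed probes")
})

test_that("cluster renumbering follows case proportion then size", {
  set.seed(1)
  pts <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 10), 10),
               matrix(rnorm(40, 20), 20))
  rownames(pts) <- sprintf("S%02d", 1:40)
  case <- setNames(c(rep(1, 9), 0, rep(0, 10), rep(1, 5), rep(0, 15)),
                   rownames(pts))
  asg <- cut_tree(ward_linkage(pts), 3, case_status = case)
  prop <- tapply(case[names(asg$cluster)], asg$cluster, mean)
  expect_true(all(diff(prop) <= 0))  # decreasing case proportion
  expect_equal(asg$k, 3L)
  # k = 1 and k = n degenerate cuts
  expect_equal(unique(cut_tree(ward_linkage(pts), 1)$cluster), 1L)
  expect_equal(sort(unique(cut_tree(ward_linkage(pts), 40)$cluster)), 1:40)
})

test_that("planted four-cluster structure is recovered from true coordinates", {
  b <- small_cohort(seed = 13, n_cpgs = 1000)
  adj <- eb_batch_adjust(mean_impute(b$beta)$beta, b$samples$platform)
  pc <- prcomp(t(beta_to_m(adj)))$x[, 1:10]
  asg <- cut_tree(ward_linkage(pc), 4,
                  case_status = setNames(b$samples$case, b$samples$sample_id))
  expect_gte(mclust::adjustedRandIndex(asg$cluster, b$truth$cluster), 0.9)
})

test_that("clustering comparison matches labels optimally", {
  a <- structure(list(cluster = setNames(rep(1:4, each = 25), sprintf("S%03d", 1:100)),
                      k = 4L, provenance = "a"), class = "cluster_assignment")
  b <- a
  expect_equal(compare_clusterings(a, b)$agreement, 100)
  # permuted labels still agree perfectly after matching
  b$cluster <- setNames(c(2:4, 1)[a$cluster], names(a$cluster))
  cmp <- compare_clusterings(a, b)
  expect_equal(cmp$agreement, 100)
  expect_equal(cmp$ari, 1)
  # one sample moved: 99%
  b2 <- a
  b2$cluster[1] <- 2L
  expect_equal(compare_clusterings(a, b2)$agreement, 99)
  bad <- a
  names(bad$cluster)[1] <- "X999"
  expect_error(compare_clusterings(a, bad), "same sample set")
})

test_that("severe/mild subgrouping follows case dominance", {
  cl <- setNames(c(rep(1L, 43), rep(2L, 88)), sprintf("S%03d", 1:131))
  case <- setNames(c(rep(1, 40), rep(0, 3), rep(1, 24), rep(0, 64)), names(cl))
  asg <- structure(list(cluster = cl, k = 2L, provenance = "x"),
                   class = "cluster_assignment")
  sub <- define_subgroups(asg, case)
  expect_equal(as.numeric(round(sub$case_proportion, 3)), c(0.930, 0.273))
  expect_equal(sum(sub$subgroup == "severe"), 40)
  expect_equal(sum(sub$subgroup == "mild"), 24)
  expect_identical(sub$dominant_clusters, 1L)
  # all clusters pure cases: everything severe, with warning
  allcase <- setNames(rep(1, 131), names(cl))
  expect_warning(sub2 <- define_subgroups(asg, allcase), "mild subgroup empty")
  expect_true(all(sub2$subgroup == "severe"))
  # exact tie at the 50% threshold: no dominant cluster, rejected
  tied <- structure(list(cluster = setNames(rep(1:2, each = 4), sprintf("T%d", 1:8)),
                         k = 2L, provenance = "x"), class = "cluster_assignment")
  halftie <- setNames(rep(c(1, 1, 0, 0), 2), names(tied$cluster))
  expect_error(define_subgroups(tied, halftie), "undefined")
})

test_that("PCA embedding behaves like a centered SVD projection", {
  # rank-1 data: PC1 explains everything
  v <- seq(-2, 2, length.out = 10)
  pts <- outer(v, c(1, 2, 3))
  rownames(pts) <- sprintf("S%02d", 1:10)
  pe <- pca_embedding(pts)
  expect_equal(pe$var_explained[1], 1)
  # orthogonal rotation leaves the spectrum unchanged
  set.seed(3)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  pe2 <- pca_embedding(pts %*% q)
  expect_equal(pe$var_explained, pe2$var_explained, tolerance = 1e-8)
})

test_that("severity-graded clusters order monotonically along PC1", {
  # nested planted blocks give cluster 2 > 1 > 4 > 3 global severity
  b <- simulate_cohort(simulation_config(
    n_cpgs = 700, global_fraction = 0.3, global_effect_sd = 1,
    severity = c(0.6, 1, 0, 0.3), missing_rate = 0,
    failed_probe_fraction = 0, seed = 17))
  m <- beta_to_m(b$beta)
  pe <- pca_embedding(t(m))
  means <- tapply(pe$scores[, 1], b$truth$cluster, mean)
  # PC1 sign is conventional, so severity must be monotone up or down
  sev_by_pc1 <- c(0.6, 1, 0, 0.3)[as.integer(names(sort(means)))]
  expect_true(identical(order(sev_by_pc1), 1:4) ||
                identical(order(sev_by_pc1), 4:1))
})

test_that("baseline and embedding clusterings agree on structured cohorts", {
  agreements <- vapply(c(19, 23, 29), function(seed) {
    b <- small_cohort(seed = seed, n_cpgs = 600, missing_rate = 0)
    case <- setNames(b$samples$case, b$samples$sample_id)
    m <- beta_to_m(b$beta)
    pc <- prcomp(t(m))$x[, 1:10]
    emb <- cut_tree(ward_linkage(pc), 4, case_status = case, provenance = "embedding")
    base <- cut_tree(ward_linkage(baseline_distance(b$beta)), 4,
                     case_status = case, provenance = "baseline")
    compare_clusterings(emb, base)$agreement
  }, 0)
  expect_gte(mean(agreements), 85)
})
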