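test_that("LD pruning removes correlated pairs and keeps independent ones", {
  set.seed(51)
  # duplicated column: exactly one survivor
  g <- rbinom(60, 2, 0.4)
  G <- cbind(g, g, rbinom(60, 2, 0.4))
  expect_equal(length(ld_prune(G)), 2)

  # independent variants all retained
  G2 <- matrix(rbinom(60 * 30, 2, 0.4), nrow = 60)
  expect_equal(ld_prune(G2, r2_max = 0.9), seq_len(30))

  # 3-variant fixture traced by hand: v1 ~ v2 (r2 = 1), v3 independent;
  # v2 has the lower MAF so it is the one removed
  v1 <- rep(c(0L, 1L, 2L), each = 20)
  v2 <- v1; v2[v2 == 2L] <- 1L   # correlated with v1, lower MAF
  stopifnot(cor(v1, v2)^2 > 0.2)
  v3 <- rep(c(0L, 1L), 30)
  keep <- ld_prune(cbind(v1, v2, v3))
  expect_equal(keep, c(1, 3))
})

test_that("PCA matches a dense eigendecomposition oracle up to sign", {
  set.seed(52)
  G <- matrix(rbinom(40 * 100, 2, 0.35), nrow = 40)
  pr <- eigen_pca(G, k = 5, weighting = "none")
  # oracle: prcomp on the centered matrix
  X <- scale(G, center = TRUE, scale = FALSE)
  oracle <- stats::prcomp(X, center = FALSE)
  for (i in 1:5) {
    cosine <- abs(sum(pr$scores[, i] * oracle$x[, i])) /
      (sqrt(sum(pr$scores[, i]^2)) * sqrt(sum(oracle$x[, i]^2)))
    expect_gt(cosine, 1 - 1e-8)
  }
  # eigenvalues non-increasing, PVE in [0,1] summing to <= 1
  expect_true(all(diff(pr$eigenvalues) <= 1e-10))
  expect_true(all(pr$pve >= 0 & pr$pve <= 1))
  expect_lte(sum(pr$pve), 1 + 1e-12)
  # distinct components orthogonal
  cp <- crossprod(pr$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-8)
})

test_that("PC1 separates two differentiated populations", {
  ch <- fixture_two_pop(n_per_pop = 50, m = 500, fst = 0.3)
  pr <- eigen_pca(ch$genotypes, k = 2)
  lab <- as.integer(factor(ch$sample_metadata$region))
  expect_gt(abs(cor(pr$scores[, 1], lab)), 0.9)
})

test_that("single-variant PCA returns the standardized dosage vector", {
  g <- c(0L, 1L, 2L, 1L, 0L, 2L)
  pr <- eigen_pca(matrix(g, ncol = 1), k = 1, weighting = "none")
  centered <- g - mean(g)
  cosine <- abs(sum(pr$scores[, 1] * centered)) /
    (sqrt(sum(pr$scores[, 1]^2)) * sqrt(sum(centered^2)))
  expect_gt(cosine, 1 - 1e-12)
  expect_equal(pr$pve, 1)
})

test_that("frequency weighting is a no-op when every variant has the same MAF", {
  # balanced dosage columns: identical allele frequencies, permuted order
  base <- rep(c(0L, 1L, 2L), each = 10)
  set.seed(53)
  G <- sapply(1:8, function(i) sample(base))
  p1 <- eigen_pca(G, k = 3, weighting = "af")
  p2 <- eigen_pca(G, k = 3, weighting = "none")
  # constant weights rescale eigenvalues but not the score directions
  for (i in 1:3) {
    cosine <- abs(sum(p1$scores[, i] * p2$scores[, i])) /
      (sqrt(sum(p1$scores[, i]^2)) * sqrt(sum(p2$scores[, i]^2)))
    expect_gt(cosine, 1 - 1e-8)
  }
  expect_equal(p1$pve, p2$pve, tolerance = 1e-10)
})

test_that("PC-by-region ANOVA behaves at its extremes and equals t^2 for 2 regions", {
  regions <- rep(c("a", "b"), each = 20)
  # region-constant scores with distinct values: overwhelming significance
  res <- pc_region_anova(rep(c(0, 1), each = 20) + rnorm(40, sd = 1e-4), regions)
  expect_lt(res$p, 1e-20)
  # 2-region F equals the squared pooled-variance t statistic
  set.seed(54)
  x <- rnorm(40)
  res2 <- pc_region_anova(x, regions)
  tt <- stats::t.test(x[1:20], x[21:40], var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_warning(pc_region_anova(rnorm(41), c(regions, "c")), "excluded")
})

test_that("PC cross-correlation: self-R2 is 1, cumulative dominates single", {
  ch <- fixture_two_pop(n_per_pop = 40, m = 300, fst = 0.2)
  pr <- eigen_pca(ch$genotypes, k = 10)
  self <- pc_cross_correlation(pr, pr, n_pcs = 2, top_k = 10)
  expect_equal(unname(diag(self$single)), c(1, 1), tolerance = 1e-8)
  expect_equal(unname(self$cumulative), c(1, 1), tolerance = 1e-8)

  # against an independent random PCA, cumulative >= best single (projection
  # optimality), and cumulative is non-decreasing in top_k
  set.seed(55)
  other <- eigen_pca(matrix(rbinom(80 * 300, 2, 0.3), nrow = 80), k = 10)
  cc <- pc_cross_correlation(pr, other, n_pcs = 2, top_k = 10)
  expect_gte(cc$cumulative[1] + 1e-12, max(cc$single[1, ]))
  cums <- sapply(1:10, function(k)
    pc_cross_correlation(pr, other, n_pcs = 1, top_k = k)$cumulative[1])
  expect_true(all(diff(cums) >= -1e-12))

  # orthogonal, uncorrelated vector: R2 ~ 0
  v <- rnorm(80)
  v <- v - pr$scores[, 1] * sum(v * pr$scores[, 1]) / sum(pr$scores[, 1]^2)
  expect_lt(cor(pr$scores[, 1], v)^2, 1e-10)
})

test_that("disjoint-subset PCs recover strong structure and are seed-stable", {
  ch <- fixture_two_pop(n_per_pop = 60, m = 1200, fst = 0.3)
  st <- disjoint_subset_stability(ch$genotypes, n_subsets = 2,
                                  subset_size = 500, seed = 9, k = 4)
  pc1 <- st$r2[st$r2$pc == 1, ]
  expect_gt(pc1$r2_single[1], 0.8)
  st2 <- disjoint_subset_stability(ch$genotypes, n_subsets = 2,
                                   subset_size = 500, seed = 9, k = 4)
  expect_identical(st$partition, st2$partition)
  expect_error(disjoint_subset_stability(ch$genotypes, 4, 500), "exceed")
})

test_that("supervised ancestry recovers the source region under structure", {
  cfg <- sim_config(n_regions = 3, samples_per_region = 120,
                    n_variants = c(common = 800), fst = 0.2, seed = 56)
  ch <- simulate_cohort(cfg)
  meta <- ch$sample_metadata
  is_ref <- meta$cohort == "C1"
  anc <- supervised_ancestry(ch$genotypes$dosages[is_ref, ], meta$region[is_ref],
                             ch$genotypes$dosages[!is_ref, ], max_iter = 2000)
  expect_true(all(abs(rowSums(anc$Q) - 1) < 1e-9))
  expect_true(all(anc$Q >= 0))
  sm <- summarize_assignment(anc, meta$region[!is_ref])
  expect_gt(sm$fraction_correct_argmax, 0.95)
})

test_that("single-region ancestry is the degenerate unit assignment", {
  set.seed(57)
  G <- matrix(rbinom(200, 2, 0.3), nrow = 10)
  anc <- supervised_ancestry(G, rep("only", 10), G)
  expect_true(all(anc$Q == 1))
  expect_true(all(anc$assignment == "only"))
})

test_that("assignment summaries count posterior exceedances correctly", {
  Q <- rbind(c(0.9, 0.05, 0.05),
             c(1 / 3, 1 / 3, 1 / 3),
             c(0.2, 0.6, 0.2))
  colnames(Q) <- c("r1", "r2", "r3")
  sm <- summarize_assignment(Q, c("r1", "r2", "r2"))
  expect_equal(sm$n_correct_confident, 2)   # rows 1 and 3 exceed 0.5 at truth
  expect_equal(sm$n_correct_argmax, 2)      # row 2 is a tie resolved to r1
  sm_uniform <- summarize_assignment(matrix(1 / 12, 5, 12,
                                            dimnames = list(NULL, paste0("R", 1:12))),
                                     rep("R3", 5))
  expect_equal(sm_uniform$n_correct_confident, 0)
})
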