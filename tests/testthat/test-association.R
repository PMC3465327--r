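test_that("trend test matches hand computation and degenerates gracefully", {
  res <- armitage_trend(c(2, 2, 0, 0), c(1, 1, 0, 0))
  expect_equal(res$statistic, 4)
  expect_equal(armitage_trend(rep(1, 10), rep(0:1, 5))$statistic, 0)
  expect_equal(armitage_trend(rep(1, 10), rep(0:1, 5))$p, 1)
  # vectorized scan agrees with the scalar version under missingness
  set.seed(61)
  G <- matrix(sample(c(0L, 1L, 2L, NA), 200 * 10, TRUE,
                     prob = c(0.4, 0.3, 0.25, 0.05)), nrow = 200)
  y <- rbinom(200, 1, 0.5)
  scan <- trend_scan(G, y)
  for (j in c(1, 4, 10)) {
    expect_equal(scan$statistic[j], armitage_trend(G[, j], y)$statistic,
                 tolerance = 1e-12)
  }
})

test_that("trend statistics are chi-square calibrated under the null", {
  set.seed(62)
  G <- matrix(rbinom(300 * 20000, 2, 0.3), nrow = 300)
  y <- rbinom(300, 1, 0.5)
  scan <- trend_scan(G, y)
  expect_lt(abs(lambda_gc(scan$statistic) - 1), 0.06)
  expect_lt(abs(mean(scan$p < 0.05) - 0.05), 0.01)
})

test_that("PC adjustment removes confounded structure", {
  # two populations, phenotype proportional to membership: raw inflated,
  # adjusted calibrated
  ch <- fixture_two_pop(n_per_pop = 100, m = 2000, fst = 0.1, seed = 63)
  G <- ch$genotypes$dosages
  pop <- as.integer(factor(ch$sample_metadata$region)) - 1L
  set.seed(64)
  y <- rbinom(200, 1, 0.3 + 0.4 * pop)
  pr <- eigen_pca(G, k = 5)
  raw <- trend_scan(G, y)
  adj <- pcadj_scan(G, y, pr$scores, k = 2)
  expect_gt(lambda_gc(raw$statistic), 1.2)
  expect_lt(abs(lambda_gc(adj$statistic) - 1), 0.1)
})

test_that("k = 0 PC adjustment equals the trend test up to N/(N-1)", {
  set.seed(65)
  g <- rbinom(100, 2, 0.3); y <- rbinom(100, 1, 0.5)
  a <- armitage_trend(g, y)
  e <- eigenstrat_adjusted(g, y, NULL)
  expect_equal(e$statistic, a$statistic * (100 - 1) / 100, tolerance = 1e-12)
  # y residualized orthogonal to g by construction -> statistic 0
  pcs <- matrix(g - mean(g), ncol = 1)
  expect_equal(eigenstrat_adjusted(g, y, pcs)$statistic, 0, tolerance = 1e-20)
  # collinear PCs dropped with a warning
  expect_warning(eigenstrat_adjusted(g, y, cbind(g, g)), "collinear")
})

test_that("CMH equals its closed form, combines strata, and permutes correctly", {
  set.seed(66)
  g <- rbinom(200, 2, 0.3); y <- rbinom(200, 1, 0.5)
  # single stratum: closed-form contingency oracle
  one <- cmh_test(g, y, rep(1, 200))
  expect_equal(one$statistic, cmh_table_oracle(list(allele_table_2x2(g, y == 1))),
               tolerance = 1e-10)
  # multi-stratum: independent oracle from stats::mantelhaen.test
  st <- rep(c("s1", "s2", "s3"), length.out = 200)
  arr <- array(0, dim = c(2, 2, 3))
  for (k in 1:3) {
    idx <- st == paste0("s", k)
    arr[, , k] <- allele_table_2x2(g[idx], y[idx] == 1)
  }
  mt <- stats::mantelhaen.test(arr, correct = FALSE)
  expect_equal(cmh_test(g, y, st)$statistic, unname(mt$statistic),
               tolerance = 1e-10)
  # same-direction association in both strata: combined exceeds each alone
  g2 <- c(rep(2L, 20), rep(0L, 20), rep(2L, 25), rep(0L, 15))
  y2 <- c(rep(1L, 15), rep(0L, 5), rep(1L, 5), rep(0L, 15),
          rep(1L, 20), rep(0L, 5), rep(1L, 3), rep(0L, 12))
  st2 <- rep(c("a", "b"), each = 40)
  comb <- cmh_test(g2, y2, st2)$statistic
  s_a <- cmh_test(g2[1:40], y2[1:40], rep(1, 40))$statistic
  s_b <- cmh_test(g2[41:80], y2[41:80], rep(1, 40))$statistic
  expect_gt(comb, max(s_a, s_b))
  # permutation p close to asymptotic p for a common null variant; genotype
  # counts at exact HWE proportions so the allele-count variance matches the
  # phenotype-permutation null up to O(1/n)
  set.seed(67)
  gh <- sample(rep(c(0L, 1L, 2L), c(294, 252, 54)))
  yh <- rbinom(600, 1, 0.5)
  sth <- rep(c("s1", "s2", "s3"), each = 200)
  res <- cmh_test(gh, yh, sth, n_perm = 1500, seed = 8)
  se <- sqrt(res$p * (1 - res$p) / 1500)
  expect_lt(abs(res$p_permutation - res$p), 3 * se + 1 / 1501)
  expect_warning(cmh_test(rep(0, 10), rep(0:1, 5), rep(1, 10)), "no informative")
})

test_that("GRM has the construction identities", {
  set.seed(67)
  G <- matrix(rbinom(30 * 400, 2, 0.3), nrow = 30)
  G <- rbind(G, G[1, ])              # duplicated individual
  K <- grm(G)
  expect_equal(K, t(K))
  expect_equal(K[31, 1], K[1, 1], tolerance = 1e-10)
  # permutation equivariance
  perm <- sample(31)
  K2 <- grm(G[perm, ])
  expect_equal(K2, K[perm, perm], tolerance = 1e-12)
  # unstructured cohort: off-diagonal mean near 0
  expect_lt(abs(mean(K[upper.tri(K)])), 0.05)
})

test_that("EMMAX with identity kinship equals ordinary regression", {
  set.seed(68)
  G <- matrix(rbinom(120 * 30, 2, 0.3), nrow = 120)
  y <- rnorm(120)
  em <- suppressWarnings(emmax_scan(y, diag(120), G))
  ols_p <- sapply(seq_len(30), function(j)
    summary(stats::lm(y ~ G[, j]))$coefficients[2, 4])
  expect_lt(max(abs(em$scan$p - ols_p) / ols_p), 1e-6)
  # REML optimum dominates the bracket endpoints
  expect_gte(em$reml_loglik + 1e-6, max(em$reml_loglik_bounds))
})

test_that("EMMAX absorbs kinship-shaped confounding", {
  ch <- fixture_two_pop(n_per_pop = 80, m = 1500, fst = 0.1, seed = 69)
  G <- ch$genotypes$dosages
  pop <- as.integer(factor(ch$sample_metadata$region)) - 1L
  set.seed(70)
  y <- rbinom(160, 1, 0.3 + 0.4 * pop)
  K <- grm(G)
  em <- emmax_scan(y, K, G)
  raw <- trend_scan(G, y)
  expect_lt(lambda_gc(em$scan$p, input = "p"), lambda_gc(raw$statistic))
  expect_false(em$boundary_ols)
})

test_that("lambda_gc has its analytic properties", {
  med1 <- qchisq(0.5, 1)
  expect_equal(lambda_gc(rep(med1, 5)), 1)
  expect_equal(lambda_gc(rep(2 * med1, 5)), 2)
  set.seed(71)
  expect_lt(abs(lambda_gc(rchisq(1e5, 1)) - 1), 0.02)
  # p-value input path inverts to the same scale
  stats <- rchisq(999, 1)
  p <- pchisq(stats, 1, lower.tail = FALSE)
  expect_equal(lambda_gc(p, input = "p"), lambda_gc(stats), tolerance = 1e-10)
})

test_that("scan_and_summarize produces a coherent lambda grid", {
  cfg <- sim_config(n_regions = 2, samples_per_region = c(80, 120),
                    n_variants = c(common = 1500, lowfreq = 400, rare = 3000),
                    fst = 0.05, private_rare_fraction = 0.2, seed = 72)
  ch <- simulate_cohort(cfg)
  phen <- assign_case_control(ch, scenario_config(c(R1 = 0.4, R2 = 0.55), seed = 72))
  y <- phenotype01(phen)
  G <- ch$genotypes$dosages
  vt <- build_variant_table(G[y == 0, , drop = FALSE])
  pr <- eigen_pca(G[, which(vt$category == "common"), drop = FALSE], k = 10)
  K <- grm(G[, which(vt$category == "common"), drop = FALSE])
  summ <- scan_and_summarize(G, y, ch$sample_metadata$region, vt,
                             pc_sets = list(common = pr),
                             pc_counts = c(2, 10),
                             kinships = list(common = K))
  expect_s3_class(summ, "association_summary")
  expect_setequal(rownames(summ$grid),
                  c("CMH", "Raw", "common.2", "common.10", "EMMAX.common"))
  expect_equal(colnames(summ$grid),
               c("common", "lowfreq", "rare", "rare_maf_le_0.005", "rare_maf_gt_0.005"))
  expect_true(all(is.finite(summ$grid[, "common"])))
  # an empty category yields NA, not an error
  vt2 <- vt; vt2$category[vt2$category == "lowfreq"] <- "common"
  summ2 <- scan_and_summarize(G, y, ch$sample_metadata$region, vt2,
                              pc_sets = list(), kinships = list())
  expect_true(all(is.na(summ2$grid[, "lowfreq"])))
})
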