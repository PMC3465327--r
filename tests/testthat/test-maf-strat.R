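test_that("MAF categorization applies the copy-count and frequency rules", {
  maf    <- c(0.3,   0.008, 0.0003, 0.05,  0.01,  0.004, 0.01)
  copies <- c(1000L, 3L,    2L,     50L,   10L,   5L,    2L)
  cats <- categorize_variants(maf, copies)
  expect_equal(cats$category,
               c("common", "rare", "others", "common", "lowfreq", "rare", "others"))
  expect_equal(cats$rare_subcategory,
               c(NA, "less_rare", NA, NA, NA, "very_rare", NA))
  # categories partition the variant set
  expect_false(anyNA(cats$category))
  expect_error(categorize_variants(0.7, 10), "invalid input")
})

test_that("rare-allele burden counts minor copies and tests regions", {
  # 3 variants, individual dosages known by hand; minor allele = allele2
  G <- fixture_matrix(c(1, 0, 0, 0,  2, 0, 1, 0,  0, 0, 1, 1), 4)
  b <- rare_allele_burden(G)
  expect_equal(unname(b$burden), c(3, 0, 2, 1))
  # missing contributes 0
  G[1, 1] <- NA
  expect_equal(unname(rare_allele_burden(G)$burden)[1], 2)

  # Kruskal-Wallis against the direct rank formula for {1,2,3} vs {11,12,13}
  burdens <- c(1, 2, 3, 11, 12, 13)
  regions <- rep(c("a", "b"), each = 3)
  Gb <- matrix(as.integer(burdens), ncol = 1)
  out <- rare_allele_burden(Gb, regions = regions)
  n <- 6; ranks <- rank(burdens)
  oracle <- 12 / (n * (n + 1)) *
    sum(tapply(ranks, regions, function(r) length(r) * mean(r)^2)) - 3 * (n + 1)
  expect_equal(out$kw_statistic, oracle, tolerance = 1e-12)
  expect_message(rare_allele_burden(Gb, regions = rep("a", 6)), "single region")
})

test_that("region sharing counts match brute-force carrier placement", {
  # 6 samples in 3 regions of 2; carriers placed by hand
  regions <- rep(c("r1", "r2", "r3"), each = 2)
  G <- fixture_matrix(c(1, 0, 0, 0, 0, 0,    # only r1
                        1, 0, 1, 0, 0, 1,    # r1, r2, r3
                        0, 0, 2, 1, 0, 0),   # only r2
                      6)
  sh <- region_sharing(G, regions)
  expect_equal(unname(sh$sharing_counts), c(1, 3, 1))
  expect_equal(unname(sh$histogram), c(0, 2, 0, 1))  # bins 0,1,2,3
  expect_equal(sh$proportion_all_regions, 1 / 3)
  # a common variant across well-sampled regions reaches every region
  set.seed(41)
  Gc <- matrix(rbinom(600, 2, 0.4), ncol = 1)
  expect_equal(unname(region_sharing(Gc, rep(paste0("R", 1:12), each = 50))$sharing_counts),
               12)
})

test_that("expected sharing: pigeonhole, limit, and exact-vs-MC agreement", {
  expect_equal(expected_sharing_proportion(1, rep(10, 12)), 0)
  expect_gt(expected_sharing_proportion(500, rep(50, 3)), 0.999999)
  e_exact <- expected_sharing_proportion(4, c(10, 10, 10), method = "exact")
  n_mc <- 1e5
  e_mc <- expected_sharing_proportion(4, c(10, 10, 10), method = "montecarlo",
                                      n_mc = n_mc, seed = 7)
  se <- sqrt(e_exact * (1 - e_exact) / n_mc)
  expect_lt(abs(e_exact - e_mc), 3 * se)
  # mixed copy counts average the per-variant probabilities
  e1 <- expected_sharing_proportion(3, c(5, 5), method = "exact")
  e2 <- expected_sharing_proportion(6, c(5, 5), method = "exact")
  expect_equal(expected_sharing_proportion(c(3, 6), c(5, 5), method = "exact"),
               (e1 + e2) / 2)
})

test_that("heterogeneity test matches the textbook chi-square and its null", {
  # 2-region allele table (10,90 | 90,10): hand Pearson statistic
  g <- c(rep(2L, 5), rep(0L, 45), rep(2L, 45), rep(0L, 5))
  regions <- rep(c("a", "b"), each = 50)
  out <- region_heterogeneity_test(g, regions)
  tab <- rbind(c(10, 90), c(90, 10))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(out$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_equal(out$df, 1)

  # permutation p within binomial error of asymptotic p for a common variant;
  # genotype counts at exact HWE proportions so the allele-count chi-square
  # null matches the individual-label permutation null
  set.seed(42)
  g0 <- rep(c(0L, 1L, 2L), c(490, 420, 90))
  r0 <- sample(rep(c("a", "b"), each = 500))
  res <- region_heterogeneity_test(g0, r0, n_perm = 2000, seed = 5)
  se <- sqrt(res$p_asymptotic * (1 - res$p_asymptotic) / 2000)
  expect_lt(abs(res$p_permutation - res$p_asymptotic), 3 * se + 1 / 2001)

  expect_warning(region_heterogeneity_test(rep(0L, 10), rep(c("a", "b"), 5)),
                 "degenerate")

  # the vectorized scan agrees with the single-variant test
  G <- cbind(g, g0[1:100])
  scan <- heterogeneity_scan(G[1:100, ], regions[1:100])
  one <- region_heterogeneity_test(G[1:100, 1], regions[1:100])
  expect_equal(scan$statistic[1], one$statistic, tolerance = 1e-12)
})

test_that("null heterogeneity statistics are chi-square distributed", {
  set.seed(43)
  G <- matrix(rbinom(500 * 5000, 2, 0.25), nrow = 500)
  regions <- rep(paste0("R", 1:5), each = 100)
  scan <- heterogeneity_scan(G, regions)
  expect_true(all(scan$df == 4))
  # mean of a chi-square_4 is 4; Kolmogorov-ish sanity via mean and median
  expect_lt(abs(mean(scan$statistic) - 4), 0.2)
  expect_lt(abs(lambda_r(scan$p) - 1), 0.06)
})

test_that("Mantel-extension test reduces to the allelic chi-square for one stratum", {
  set.seed(44)
  g <- rbinom(200, 2, 0.3)
  cohort <- rep(c("A", "B"), 100)
  res <- mantel_extension_test(matrix(g, ncol = 1), cohort, rep(1, 200))
  oracle <- cmh_table_oracle(list(allele_table_2x2(g, cohort == "B")))
  expect_equal(res$statistic, oracle, tolerance = 1e-10)

  # two-stratum fixture equals the closed-form CMH combination
  strata <- rep(c("s1", "s2"), each = 100)
  res2 <- mantel_extension_test(matrix(g, ncol = 1), cohort, strata)
  oracle2 <- cmh_table_oracle(list(
    allele_table_2x2(g[1:100], cohort[1:100] == "B"),
    allele_table_2x2(g[101:200], cohort[101:200] == "B")))
  expect_equal(res2$statistic, oracle2, tolerance = 1e-10)

  # identical counts in both cohorts in every stratum -> statistic 0
  gg <- rep(c(0L, 1L, 2L, 0L, 1L, 2L), 10)
  ch <- rep(c("A", "A", "A", "B", "B", "B"), 10)
  expect_equal(mantel_extension_test(matrix(gg, ncol = 1), ch, rep(1, 60))$statistic, 0)
})

test_that("lambda_r has its analytic values and null calibration", {
  expect_equal(lambda_r(rep(0.5, 7)), 1.0)
  expect_equal(lambda_r(rep(0.25, 7)), 2.0)
  set.seed(45)
  expect_lt(abs(lambda_r(runif(1e5)) - 1), 0.02)
  expect_warning(out <- lambda_r(c(0.5, 0)), "clipped")
  expect_true(is.finite(out))
  expect_error(lambda_r(numeric(0)), "invalid input")
})

test_that("unique-region concordance matches brute-force set logic", {
  # identical cohorts: concordance 100%
  A <- matrix(c(TRUE, FALSE, FALSE,
                FALSE, TRUE, FALSE,
                TRUE, TRUE, FALSE), nrow = 3, byrow = TRUE)
  res <- unique_region_concordance(A, A)
  expect_equal(res$n_unique_both, 2)
  expect_equal(res$fraction_same_region, 1)
  # disjoint private regions: concordance 0
  B <- A[, c(2, 1, 3)]
  res2 <- unique_region_concordance(A, B)
  expect_equal(res2$n_unique_both, 2)
  expect_equal(res2$n_same_region, 0)
  # randomized fixture vs brute force
  set.seed(46)
  PA <- matrix(runif(300) < 0.3, ncol = 3)
  PB <- matrix(runif(300) < 0.3, ncol = 3)
  res3 <- unique_region_concordance(PA, PB)
  brute <- 0; same <- 0
  for (i in 1:100) {
    if (sum(PA[i, ]) == 1 && sum(PB[i, ]) == 1) {
      brute <- brute + 1
      if (which(PA[i, ]) == which(PB[i, ])) same <- same + 1
    }
  }
  expect_equal(res3$n_unique_both, brute)
  expect_equal(res3$n_same_region, same)
})
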