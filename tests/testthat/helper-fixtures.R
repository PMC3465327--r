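# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk.

# small genotype matrix with known dosages (rows samples, cols variants)
fixture_matrix <- function(values, n_samples) {
  matrix(as.integer(values), nrow = n_samples)
}

# structured two-population cohort for quick structure-detection checks
fixture_two_pop <- function(n_per_pop = 50, m = 500, fst = 0.3, seed = 99) {
  cfg <- sim_config(n_regions = 2, samples_per_region = n_per_pop,
                    n_variants = c(common = m), fst = fst, seed = seed)
  simulate_cohort(cfg)
}

# exhaustive-enumeration HWE oracle: full conditional distribution of the
# heterozygote count given n diploids and n_minor minor alleles
hwe_enumeration_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (naa > nAA) { tmp <- nAA; nAA <- naa; naa <- tmp }
  n_minor <- 2 * naa + nAa
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  probs <- vapply(hets, function(h) {
    a <- (n_minor - h) / 2
    A <- n - h - a
    # multinomial genotype-configuration count x 2^h over allele pairings
    exp(lfactorial(n) - lfactorial(A) - lfactorial(h) - lfactorial(a) +
          h * log(2) + lfactorial(n_minor) + lfactorial(2 * n - n_minor) -
          lfactorial(2 * n))
  }, numeric(1))
  probs <- probs / sum(probs)
  p_obs <- probs[match(nAa, hets)]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# closed-form 2x2xK Cochran-Mantel-Haenszel statistic from count tables:
# tables is a list of 2x2 matrices (rows: groups, cols: alleles)
cmh_table_oracle <- function(tables) {
  num <- 0; den <- 0
  for (tb in tables) {
    n <- sum(tb)
    if (n < 2) next
    E <- sum(tb[1, ]) * sum(tb[, 1]) / n
    V <- sum(tb[1, ]) * sum(tb[2, ]) * sum(tb[, 1]) * sum(tb[, 2]) / (n^2 * (n - 1))
    num <- num + tb[1, 1] - E
    den <- den + V
  }
  num^2 / den
}

# allele-count 2x2 table for a dosage vector split by a binary grouping
allele_table_2x2 <- function(g, grp) {
  ok <- !is.na(g)
  g <- g[ok]; grp <- grp[ok]
  rbind(c(sum(g[grp]), 2 * sum(grp) - sum(g[grp])),
        c(sum(g[!grp]), 2 * sum(!grp) - sum(g[!grp])))
}
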