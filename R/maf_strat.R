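#' Categorize variants by minor allele frequency
#'
#' Variants whose minor allele is present in at most `copy_threshold` copies
#' are set aside as "others" (singleton/doubleton signals are the most prone
#' to genotyping artifacts). The remainder are split into common
#' (MAF >= 0.05), low-frequency (0.01 <= MAF < 0.05) and rare (MAF <= 0.01
#' with more than `copy_threshold` copies). Rare variants are further
#' subdivided at MAF 0.005 into very rare and less rare.
#'
#' @param maf Numeric vector of minor allele frequencies in [0, 0.5].
#' @param copies Integer vector of minor-allele copy counts.
#' @param copy_threshold Copy count at or below which a variant is "others".
#' @return Data frame with columns `category` (common/lowfreq/rare/others)
#'   and `rare_subcategory` (very_rare/less_rare/NA).
#' @export
categorize_variants <- function(maf, copies, copy_threshold = 2) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE)) {
    stop_invalid("invalid input: maf outside [0, 0.5]")
  }
  category <- ifelse(is.na(maf), NA_character_,
              ifelse(copies <= copy_threshold, "others",
              ifelse(maf >= 0.05, "common",
              ifelse(maf >= 0.01, "lowfreq", "rare"))))
  rare_sub <- ifelse(!is.na(category) & category == "rare",
                     ifelse(maf <= 0.005, "very_rare", "less_rare"),
                     NA_character_)
  data.frame(category = category, rare_subcategory = rare_sub,
             stringsAsFactors = FALSE)
}

#' Build a per-variant annotation table
#'
#' Combines minor allele frequency, copy counts, the MAF category and
#' (when region labels are given) the number of regions in which each
#' variant is polymorphic.
#'
#' @param x Dosage matrix or `genotype_data`.
#' @param regions Optional character vector of per-sample region labels.
#' @param copy_threshold Passed to [categorize_variants()].
#' @return Data frame keyed by `variant_id`.
#' @export
build_variant_table <- function(x, regions = NULL, copy_threshold = 2) {
  mafs <- compute_maf(x)
  cats <- categorize_variants(mafs$maf, mafs$minor_copies, copy_threshold)
  out <- cbind(mafs, cats)
  if (!is.null(regions)) {
    pres <- region_presence(x, regions, maf_table = mafs)
    out$n_regions_polymorphic <- as.integer(rowSums(pres))
  }
  out
}

#' Per-variant region presence
#'
#' A variant is present in a region iff at least one minor-allele copy is
#' observed among that region's non-missing genotypes.
#'
#' @param x Dosage matrix or `genotype_data`.
#' @param regions Per-sample region labels.
#' @param maf_table Optional precomputed [compute_maf()] table.
#' @return Logical variants x regions matrix.
#' @export
region_presence <- function(x, regions, maf_table = NULL) {
  G <- dosage_matrix(x)
  if (length(regions) != nrow(G)) stop_invalid("invalid input: region labels incomplete")
  if (is.null(maf_table)) maf_table <- compute_maf(G)
  Gm <- minor_dosages(G, maf_table)
  Gm[is.na(Gm)] <- 0L
  counts <- rowsum(Gm, group = regions)        # regions x variants minor copies
  t(counts > 0)
}

#' Rare-allele burden per individual and its regional heterogeneity
#'
#' The burden is the number of minor-allele copies an individual carries
#' over the variants of one MAF category (missing genotypes contribute 0:
#' burden is a carrier count and imputation would manufacture rare alleles).
#' When at least two regions are present, regional differences are tested
#' with a Kruskal-Wallis rank test (tie-corrected).
#'
#' @param x Dosage matrix or `genotype_data`.
#' @param variant_subset Logical or integer index of the variants to sum
#'   over (e.g. `variant_table$category == "rare"`).
#' @param regions Optional per-sample region labels.
#' @return List with `burden` (named per-sample counts) and, when testable,
#'   `kw_statistic`, `kw_df`, `kw_p`.
#' @export
rare_allele_burden <- function(x, variant_subset = NULL, regions = NULL) {
  G <- dosage_matrix(x)
  if (!is.null(variant_subset)) G <- G[, variant_subset, drop = FALSE]
  Gm <- minor_dosages(G)
  Gm[is.na(Gm)] <- 0L
  burden <- rowSums(Gm)
  out <- list(burden = burden)
  if (!is.null(regions)) {
    if (length(unique(regions)) < 2) {
      message("single region: heterogeneity test undefined, burden only")
    } else {
      kw <- stats::kruskal.test(burden, factor(regions))
      out$kw_statistic <- unname(kw$statistic)
      out$kw_df <- unname(kw$parameter)
      out$kw_p <- kw$p.value
    }
  }
  out
}

#' Regional sharing summary for one variant category
#'
#' Counts, for each variant, the number of regions carrying at least one
#' minor-allele copy, and summarizes the distribution.
#'
#' @param x Dosage matrix or `genotype_data`.
#' @param regions Per-sample region labels.
#' @param variant_subset Optional logical/integer variant index.
#' @param expected Compute the expected all-region sharing proportion under
#'   homogeneous allocation (see [expected_sharing_proportion()])?
#' @param method,n_mc,seed Passed to [expected_sharing_proportion()].
#' @return An object of class `sharing_summary`: histogram over 0..n_regions,
#'   proportion of variants found in all regions, and optionally the
#'   expected such proportion under homogeneity.
#' @export
region_sharing <- function(x, regions, variant_subset = NULL,
                           expected = FALSE, method = "exact",
                           n_mc = 1e4, seed = 1L) {
  G <- dosage_matrix(x)
  if (!is.null(variant_subset)) G <- G[, variant_subset, drop = FALSE]
  maf_table <- compute_maf(G)
  pres <- region_presence(G, regions, maf_table)
  n_regions <- ncol(pres)
  counts <- rowSums(pres)
  hist <- tabulate(counts + 1L, nbins = n_regions + 1L)
  names(hist) <- as.character(0:n_regions)
  prop_all <- mean(counts == n_regions)
  out <- list(histogram = hist,
              n_regions = n_regions,
              n_variants = ncol(G),
              sharing_counts = stats::setNames(counts, colnames(G)),
              proportion_all_regions = prop_all)
  if (expected) {
    region_sizes <- as.integer(table(regions)[colnames(pres)])
    out$expected_all_regions <- expected_sharing_proportion(
      maf_table$minor_copies, region_sizes, method = method,
      n_mc = n_mc, seed = seed)
  }
  structure(out, class = "sharing_summary")
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("sharing over %d regions (%d variants): %.1f%% in all regions",
              x$n_regions, x$n_variants, 100 * x$proportion_all_regions))
  if (!is.null(x$expected_all_regions)) {
    cat(sprintf(" (%.1f%% expected under homogeneity)", 100 * x$expected_all_regions))
  }
  cat("\n")
  invisible(x)
}

#' Expected proportion of variants shared by all regions under homogeneity
#'
#' For a variant whose minor allele is carried by `c` individuals, the `c`
#' carriers are allocated at random without replacement over the full sample
#' (multivariate hypergeometric over the region sizes) and the probability
#' that every region receives at least one carrier is computed by
#' inclusion-exclusion (exact) or by simulation. The returned value is the
#' mean of this probability over the supplied copy counts.
#'
#' @param copy_counts Integer vector of minor-allele copy counts (one per
#'   variant); each copy is treated as a distinct carrier, the accurate
#'   reading for rare variants where homozygotes are negligible.
#' @param region_sizes Integer vector of region sample sizes.
#' @param method `"exact"` or `"montecarlo"`.
#' @param n_mc Monte-Carlo replicates per distinct copy count.
#' @param seed Seed for the Monte-Carlo path.
#' @return Scalar expected proportion in [0, 1].
#' @export
expected_sharing_proportion <- function(copy_counts, region_sizes,
                                        method = c("exact", "montecarlo"),
                                        n_mc = 1e4, seed = 1L) {
  method <- match.arg(method)
  if (any(region_sizes < 1)) stop_invalid("invalid input: region sizes must be >= 1")
  if (any(copy_counts < 1)) stop_invalid("invalid input: copy counts must be >= 1")
  N <- sum(region_sizes)
  R <- length(region_sizes)
  uc <- sort(unique(pmin(copy_counts, N)))
  probs <- stats::setNames(numeric(length(uc)), uc)
  if (method == "exact") {
    # signed subset-size polynomial: prod_r (1 - z^{n_r});
    # coef[t+1] = sum over region subsets S with total size t of (-1)^{|S|}
    coef <- c(1, rep(0, N))
    for (nr in region_sizes) {
      shifted <- c(rep(0, nr), coef[seq_len(N + 1 - nr)])
      coef <- coef - shifted
    }
    ts <- which(coef != 0) - 1L
    for (i in seq_along(uc)) {
      c_i <- uc[i]
      if (c_i < R) { probs[i] <- 0; next }
      lg <- lchoose(N - ts, c_i) - lchoose(N, c_i)
      probs[i] <- max(0, min(1, sum(coef[ts + 1L] * exp(lg))))
    }
  } else {
    region_of <- rep.int(seq_len(R), region_sizes)
    with_seed(derive_seed(seed, "sharing_mc"), {
      for (i in seq_along(uc)) {
        c_i <- uc[i]
        if (c_i < R) { probs[i] <- 0; next }
        hits <- 0L
        for (b in seq_len(n_mc)) {
          picked <- region_of[sample.int(N, c_i)]
          if (length(unique(picked)) == R) hits <- hits + 1L
        }
        probs[i] <- hits / n_mc
      }
    })
  }
  mean(probs[as.character(pmin(copy_counts, N))])
}

# allele-count 2 x R table (allele2 copies / allele1 copies per group)
allele_count_table <- function(g, groups) {
  called <- !is.na(g)
  a2 <- tapply(g[called], groups[called], sum)
  tot <- tapply(rep(2, sum(called)), groups[called], sum)
  a2[is.na(a2)] <- 0; tot[is.na(tot)] <- 0
  rbind(allele2 = a2, allele1 = tot - a2)
}

pearson_chisq <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0) || n == 0) return(NA_real_)
  e <- outer(rs, cs) / n
  sum((tab - e)^2 / e)
}

#' Regional allele-frequency heterogeneity test
#'
#' Pearson chi-square on the 2 x R allele-count table of a variant across
#' regions (df = R - 1; 11 df for 12 regions). Significance can additionally
#' be assessed by permuting region labels over individuals, with the
#' add-one correction (b + 1)/(n_perm + 1).
#'
#' @param g Dosage vector for one variant.
#' @param regions Per-sample region labels.
#' @param n_perm Number of label permutations (0 = asymptotic only).
#' @param seed Seed for the permutations.
#' @return List with `statistic`, `df`, `p_asymptotic` and (when requested)
#'   `p_permutation`. A degenerate table (zero margin) returns p = 1 with a
#'   warning.
#' @export
region_heterogeneity_test <- function(g, regions, n_perm = 0, seed = 1L) {
  regions <- factor(regions)
  tab <- allele_count_table(g, regions)
  stat <- pearson_chisq(tab)
  df <- ncol(tab) - 1
  if (is.na(stat)) {
    warning("degenerate allele-count table (zero margin): p = 1")
    return(list(statistic = 0, df = df, p_asymptotic = 1,
                p_permutation = if (n_perm > 0) 1 else NULL))
  }
  out <- list(statistic = stat, df = df,
              p_asymptotic = stats::pchisq(stat, df, lower.tail = FALSE))
  if (n_perm > 0) {
    b <- with_seed(derive_seed(seed, "het_perm"), {
      hits <- 0L
      for (i in seq_len(n_perm)) {
        s <- pearson_chisq(allele_count_table(g, sample(regions)))
        if (!is.na(s) && s >= stat - 1e-12) hits <- hits + 1L
      }
      hits
    })
    out$p_permutation <- (b + 1) / (n_perm + 1)
  }
  out
}

#' Vectorized heterogeneity scan across variants
#'
#' Asymptotic Pearson chi-square heterogeneity test per variant; degenerate
#' (monomorphic) variants get NA and should be excluded from downstream
#' overdispersion summaries.
#'
#' @param x Dosage matrix or `genotype_data`.
#' @param regions Per-sample region labels.
#' @return Data frame with `statistic`, `df`, `p` per variant.
#' @export
heterogeneity_scan <- function(x, regions) {
  G <- dosage_matrix(x)
  regions <- factor(regions)
  R <- nlevels(regions)
  called <- !is.na(G)
  Gz <- G; Gz[!called] <- 0L
  a2 <- rowsum_full(Gz, regions)               # R x m allele2 copies
  tot <- 2 * rowsum_full(called + 0L, regions) # R x m total alleles
  a1 <- tot - a2
  A2 <- colSums(a2); A1 <- colSums(a1); N <- colSums(tot)
  stat <- rep(NA_real_, ncol(G))
  ok <- A2 > 0 & A1 > 0 & N > 0
  if (any(ok)) {
    # sum over regions of (O - E)^2 / E for both allele rows
    e2 <- sweep(tot[, ok, drop = FALSE], 2, A2[ok] / N[ok], `*`)
    e1 <- sweep(tot[, ok, drop = FALSE], 2, A1[ok] / N[ok], `*`)
    zero_region <- tot[, ok, drop = FALSE] == 0
    t2 <- (a2[, ok, drop = FALSE] - e2)^2 / e2
    t1 <- (a1[, ok, drop = FALSE] - e1)^2 / e1
    t2[zero_region] <- 0; t1[zero_region] <- 0
    stat[ok] <- colSums(t2) + colSums(t1)
  }
  df <- R - 1
  data.frame(variant_id = colnames(G) %||% sprintf("var%06d", seq_len(ncol(G))),
             statistic = stat, df = df,
             p = stats::pchisq(stat, df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rowsum over a factor, with one row per level (absent levels filled with 0)
rowsum_full <- function(x, group) {
  group <- as.factor(group)
  r <- rowsum(x, group)
  out <- matrix(0, nrow = nlevels(group), ncol = ncol(x),
                dimnames = list(levels(group), colnames(x)))
  out[match(rownames(r), levels(group)), ] <- r
  out
}

# shared 2x2xK Cochran-Mantel-Haenszel core on allele counts.
# G: samples x variants dosages; group1: logical (the "exposed" row);
# strata: factor. Returns per-variant statistic (1 df, no continuity corr.).
cmh_allele_core <- function(G, group1, strata) {
  strata <- factor(strata)
  called <- !is.na(G)
  Gz <- G; Gz[!called] <- 0
  grp <- interaction(strata, factor(group1, levels = c(FALSE, TRUE)), drop = FALSE)
  a2 <- rowsum_full(Gz, grp)                   # (2K) x m
  al <- 2 * rowsum_full(called + 0L, grp)
  K <- nlevels(strata)
  # rows 1..K are group1=FALSE, rows K+1..2K are group1=TRUE
  a2_1 <- a2[K + seq_len(K), , drop = FALSE];  al_1 <- al[K + seq_len(K), , drop = FALSE]
  a2_0 <- a2[seq_len(K), , drop = FALSE];      al_0 <- al[seq_len(K), , drop = FALSE]
  col1 <- a2_1 + a2_0                          # allele2 margin per stratum
  n <- al_1 + al_0
  col2 <- n - col1
  informative <- n > 1 & col1 > 0 & col2 > 0 & al_1 > 0 & al_0 > 0
  E <- ifelse(informative, al_1 * col1 / n, 0)
  V <- ifelse(informative, al_1 * al_0 * col1 * col2 / (n^2 * (n - 1)), 0)
  num <- colSums(ifelse(informative, a2_1, 0) - E)
  den <- colSums(V)
  stat <- ifelse(den > 0, num^2 / den, NA_real_)
  stat
}

#' Mantel-extension test of cohort frequency differences within strata
#'
#' One-degree-of-freedom Cochran-Mantel-Haenszel statistic on the
#' cohort x allele tables stratified by region (no continuity correction):
#' tests whether two cohorts drawn from the same population differ in
#' allele frequency once region is conditioned on.
#'
#' @param x Dosage matrix or `genotype_data` over the pooled cohorts.
#' @param cohort Per-sample cohort labels (exactly two levels).
#' @param strata Per-sample stratum (region) labels.
#' @return Data frame with per-variant `statistic` and `p`; variants with no
#'   informative stratum get NA and a flag column `degenerate`.
#' @export
mantel_extension_test <- function(x, cohort, strata) {
  G <- dosage_matrix(x)
  cohort <- factor(cohort)
  if (nlevels(cohort) != 2) stop_invalid("invalid input: cohort must have two levels")
  stat <- cmh_allele_core(G, cohort == levels(cohort)[2], strata)
  if (all(is.na(stat))) warning("all strata degenerate: statistics undefined")
  data.frame(variant_id = colnames(G) %||% sprintf("var%06d", seq_len(ncol(G))),
             statistic = stat,
             p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
             degenerate = is.na(stat),
             stringsAsFactors = FALSE)
}

#' Overdispersion coefficient for homogeneity-test p-values
#'
#' Under the null of homogeneity, p-values are uniform and -2 ln(p) follows
#' a chi-square with 2 df. `lambda_r` is the ratio of the observed median of
#' -2 ln(p) to the chi-square-2 median, 2 ln 2; values above 1 indicate
#' overdispersion of the homogeneity statistics.
#'
#' @param pvalues Numeric vector of p-values in (0, 1]; exact zeros are
#'   clipped to the smallest representable positive double with a warning.
#' @return Scalar overdispersion coefficient.
#' @export
lambda_r <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues)) stop_invalid("invalid input: no p-values supplied")
  if (any(pvalues < 0 | pvalues > 1)) stop_invalid("invalid input: p-values outside [0, 1]")
  if (any(pvalues == 0)) {
    warning("p-values of 0 clipped to the smallest positive double")
    pvalues[pvalues == 0] <- .Machine$double.xmin
  }
  stats::median(-2 * log(pvalues)) / (2 * log(2))
}

#' Concordance of region-unique variants between two cohorts
#'
#' Among variants whose minor allele is confined to exactly one region in
#' each cohort separately, counts how many sit in the same region in both.
#'
#' @param presence_a,presence_b Logical variants x regions presence matrices
#'   (same variant and region order), e.g. from [region_presence()].
#' @return List: `n_unique_both`, `n_same_region`, `fraction_same_region`.
#' @export
unique_region_concordance <- function(presence_a, presence_b) {
  if (!identical(dim(presence_a), dim(presence_b))) {
    stop_invalid("invalid input: presence matrices must share variant and region space")
  }
  ua <- rowSums(presence_a) == 1
  ub <- rowSums(presence_b) == 1
  both <- ua & ub
  same <- both & (max.col(presence_a, ties.method = "first") ==
                  max.col(presence_b, ties.method = "first"))
  list(n_unique_both = sum(both),
       n_same_region = sum(same),
       fraction_same_region = if (sum(both)) sum(same) / sum(both) else NA_real_)
}
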