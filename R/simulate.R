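#' Simulation configuration for a region-structured cohort
#'
#' Describes a synthetic genotyping study: a population subdivided into
#' geographic regions whose allele frequencies have drifted apart from a
#' common ancestral frequency (Balding-Nichols model), genotyped on a panel
#' of variants spanning a chosen minor-allele-frequency spectrum.
#'
#' @param n_regions Number of geographic regions.
#' @param samples_per_region Integer vector of per-region sample sizes
#'   (recycled to `n_regions`).
#' @param n_variants Named integer vector giving the number of variants to
#'   simulate per target frequency stratum; names must be a subset of
#'   `c("common", "lowfreq", "rare")`.
#' @param maf_spectrum Named list mapping each stratum to the interval of
#'   ancestral allele frequencies to draw from (uniformly). Defaults follow
#'   the conventional MAF cut-offs: common >= 0.05, low-frequency
#'   0.01-0.05, rare below 0.01.
#' @param fst Balding-Nichols differentiation parameter; 0 means no
#'   population structure, otherwise must lie in (0, 1).
#' @param private_rare_fraction Fraction of rare-stratum variants restricted
#'   to a single (uniformly chosen) region: their regional frequency is
#'   zeroed everywhere else.
#' @param missing_rate Per-genotype missingness probability.
#' @param genotype_error_rate Probability that a genotype is perturbed to an
#'   adjacent dosage (0 <-> 1 <-> 2).
#' @param seed Integer seed; one global seed fans out to independent
#'   per-stage substreams.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_regions = 12,
                       samples_per_region = 100,
                       n_variants = c(common = 1000, lowfreq = 500, rare = 500),
                       maf_spectrum = NULL,
                       fst = 0.01,
                       private_rare_fraction = 0,
                       missing_rate = 0,
                       genotype_error_rate = 0,
                       seed = 1L) {
  if (n_regions < 1) stop_invalid("invalid configuration: n_regions must be positive")
  samples_per_region <- rep_len(as.integer(samples_per_region), n_regions)
  if (any(samples_per_region < 1)) {
    stop_invalid("invalid configuration: samples_per_region must be positive")
  }
  if (is.null(names(n_variants)) ||
      !all(names(n_variants) %in% c("common", "lowfreq", "rare"))) {
    stop_invalid("invalid configuration: n_variants must be named with common/lowfreq/rare")
  }
  if (any(n_variants < 0) || sum(n_variants) < 1) {
    stop_invalid("invalid configuration: variant counts must be non-negative and sum >= 1")
  }
  default_spectrum <- list(common  = c(0.05, 0.5),
                           lowfreq = c(0.01, 0.05),
                           rare    = c(0.001, 0.01))
  if (is.null(maf_spectrum)) maf_spectrum <- default_spectrum
  for (s in names(n_variants)) {
    if (is.null(maf_spectrum[[s]])) maf_spectrum[[s]] <- default_spectrum[[s]]
    b <- maf_spectrum[[s]]
    if (length(b) != 2 || b[1] > b[2] || b[1] <= 0 || b[2] >= 1) {
      stop_invalid("invalid configuration: maf_spectrum$%s bounds must lie inside (0, 1)", s)
    }
  }
  if (length(fst) != 1 || fst < 0 || fst >= 1) {
    stop_invalid("invalid configuration: fst must be 0 (no structure) or in (0, 1)")
  }
  check_fraction(private_rare_fraction, "private_rare_fraction")
  check_fraction(missing_rate, "missing_rate")
  check_fraction(genotype_error_rate, "genotype_error_rate")
  structure(list(n_regions = n_regions,
                 samples_per_region = samples_per_region,
                 n_variants = n_variants,
                 maf_spectrum = maf_spectrum,
                 fst = fst,
                 private_rare_fraction = private_rare_fraction,
                 missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Case-assignment scenario
#'
#' Parameterizes region-differential sampling of cases: the classic
#' confounding mechanism in which the case series over-represents some
#' regions relative to the control series.
#'
#' @param case_fraction_by_region Named numeric vector mapping region label
#'   to the fraction of that region's individuals assigned case status.
#' @param assignment_mode `"deterministic"` assigns exactly
#'   `round(fraction * region size)` cases per region; `"bernoulli"` flips a
#'   coin per individual.
#' @param seed Integer seed used to pick which individuals become cases.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(case_fraction_by_region,
                            assignment_mode = c("deterministic", "bernoulli"),
                            seed = 1L) {
  assignment_mode <- match.arg(assignment_mode)
  if (is.null(names(case_fraction_by_region))) {
    stop_invalid("invalid configuration: case_fraction_by_region must be named by region")
  }
  check_fraction(case_fraction_by_region, "case_fraction_by_region")
  structure(list(case_fraction_by_region = case_fraction_by_region,
                 assignment_mode = assignment_mode,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Draw ancestral allele frequencies from a spectrum specification
#'
#' @param spectrum Either a numeric length-2 interval or a list with elements
#'   `min` and `max`; a degenerate interval (`min == max`) is a point mass.
#' @param n Number of frequencies to draw.
#' @param seed Optional seed; when `NULL`, the current RNG stream is used.
#' @return Numeric vector of `n` frequencies inside the interval.
#' @export
draw_ancestral_frequencies <- function(spectrum, n, seed = NULL) {
  if (is.list(spectrum)) spectrum <- c(spectrum$min, spectrum$max)
  if (length(spectrum) != 2 || spectrum[1] > spectrum[2]) {
    stop_invalid("invalid configuration: spectrum must be an interval c(min, max)")
  }
  if (spectrum[1] <= 0 || spectrum[2] >= 1) {
    stop_invalid("invalid configuration: spectrum bounds must lie inside (0, 1)")
  }
  if (n < 1) stop_invalid("invalid input: n must be >= 1")
  draw <- function() {
    if (spectrum[1] == spectrum[2]) rep(spectrum[1], n)
    else stats::runif(n, spectrum[1], spectrum[2])
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Draw region-specific allele frequencies under the Balding-Nichols model
#'
#' Each regional frequency is drawn from a Beta distribution with mean `p`
#' and variance `fst * p * (1 - p)`, i.e. Beta(p (1-fst)/fst, (1-p)(1-fst)/fst).
#' `fst = 0` returns the ancestral frequency exactly for every region.
#'
#' @param p Ancestral allele frequency in (0, 1); may be a vector, in which
#'   case a variants x regions matrix is returned.
#' @param fst Differentiation parameter in [0, 1).
#' @param n_regions Number of regions.
#' @param seed Optional seed.
#' @return Numeric vector (or matrix for vector `p`) of per-region
#'   frequencies, clamped strictly inside (0, 1).
#' @export
draw_regional_frequencies <- function(p, fst, n_regions, seed = NULL) {
  if (any(p <= 0) || any(p >= 1)) stop_invalid("invalid input: p must lie in (0, 1)")
  if (fst < 0 || fst >= 1) stop_invalid("invalid input: fst must lie in [0, 1)")
  m <- length(p)
  draw <- function() {
    if (fst == 0) {
      out <- matrix(rep(p, n_regions), nrow = m)
    } else {
      scale <- (1 - fst) / fst
      out <- matrix(stats::rbeta(m * n_regions,
                                 shape1 = rep(p, n_regions) * scale,
                                 shape2 = rep(1 - p, n_regions) * scale),
                    nrow = m)
      # keep the support open so downstream binomial draws stay well defined
      out <- pmin(pmax(out, 1e-12), 1 - 1e-12)
    }
    out
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (m == 1) drop(out) else out
}

#' Simulate a region-structured genotype cohort
#'
#' Ancestral frequencies are drawn per stratum from the configured spectrum,
#' diversified across regions by the Balding-Nichols model, and genotypes of
#' individual i at variant j are Binomial(2, f[region(i), j]). A configurable
#' fraction of rare-stratum variants is made region-private by zeroing the
#' regional frequency outside one uniformly chosen region. Genotype errors
#' (perturbation to an adjacent dosage) and missingness are applied after
#' drawing. Identical configurations reproduce identical cohorts.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synthetic_cohort`: list with `genotypes`
#'   (a `genotype_data`), `sample_metadata` (sample_id, cohort, region,
#'   phenotype), `true_regional_frequencies` (variants x regions) and
#'   `variant_strata` (target stratum per variant).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_regions <- config$n_regions
  region_sizes <- config$samples_per_region
  n <- sum(region_sizes)
  regions <- rep(paste0("R", seq_len(n_regions)), region_sizes)
  sample_ids <- sprintf("S%04d", seq_len(n))
  # two interchangeable control cohorts, balanced within region
  cohort <- unlist(lapply(region_sizes, function(k) {
    rep_len(c("C1", "C2"), k)
  }), use.names = FALSE)

  strata <- names(config$n_variants)[config$n_variants > 0]
  anc <- list(); freqs <- list(); stratum_of <- character(0)
  for (s in strata) {
    m_s <- config$n_variants[[s]]
    anc[[s]] <- draw_ancestral_frequencies(config$maf_spectrum[[s]], m_s,
                                           seed = derive_seed(config$seed, paste0("anc_", s)))
    f <- draw_regional_frequencies(anc[[s]], config$fst, n_regions,
                                   seed = derive_seed(config$seed, paste0("reg_", s)))
    f <- matrix(f, nrow = m_s)
    if (s == "rare" && config$private_rare_fraction > 0) {
      n_priv <- round(config$private_rare_fraction * m_s)
      if (n_priv > 0) {
        with_seed(derive_seed(config$seed, "private"), {
          priv_idx <- seq_len(n_priv)          # first variants of the stratum
          home <- sample.int(n_regions, n_priv, replace = TRUE)
          for (ii in seq_len(n_priv)) {
            keep <- f[priv_idx[ii], home[ii]]
            f[priv_idx[ii], ] <- 0
            f[priv_idx[ii], home[ii]] <- keep
          }
        })
      }
    }
    freqs[[s]] <- f
    stratum_of <- c(stratum_of, rep(s, m_s))
  }
  F <- do.call(rbind, freqs)                    # variants x regions
  m <- nrow(F)
  variant_ids <- sprintf("%s_%06d", stratum_of, seq_len(m))

  region_index <- rep(seq_len(n_regions), region_sizes)
  G <- with_seed(derive_seed(config$seed, "genotypes"), {
    # draw per region in one block: samples x variants
    out <- matrix(0L, nrow = n, ncol = m)
    for (r in seq_len(n_regions)) {
      rows <- which(region_index == r)
      out[rows, ] <- matrix(stats::rbinom(length(rows) * m, 2L,
                                          rep(F[, r], each = length(rows))),
                            nrow = length(rows))
    }
    out
  })

  if (config$genotype_error_rate > 0) {
    G <- with_seed(derive_seed(config$seed, "errors"), {
      hit <- which(stats::runif(length(G)) < config$genotype_error_rate)
      if (length(hit)) {
        g <- G[hit]
        up <- stats::runif(length(hit)) < 0.5   # direction for heterozygotes
        G[hit] <- ifelse(g == 0L, 1L, ifelse(g == 2L, 1L, ifelse(up, 0L, 2L)))
      }
      G
    })
  }
  if (config$missing_rate > 0) {
    G <- with_seed(derive_seed(config$seed, "missing"), {
      G[stats::runif(length(G)) < config$missing_rate] <- NA_integer_
      G
    })
  }

  variants <- data.frame(variant_id = variant_ids,
                         chrom = 1L,
                         pos = seq_len(m),
                         allele1 = "A",
                         allele2 = "G",
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_ids,
                        cohort = cohort,
                        region = regions,
                        phenotype = NA_integer_,
                        stringsAsFactors = FALSE)
  dimnames(G) <- list(sample_ids, variant_ids)
  colnames(F) <- paste0("R", seq_len(n_regions))
  rownames(F) <- variant_ids
  structure(list(genotypes = genotype_data(G, variants, samples),
                 sample_metadata = samples,
                 true_regional_frequencies = F,
                 variant_strata = stats::setNames(stratum_of, variant_ids),
                 config = config),
            class = "synthetic_cohort")
}

#' Assign case/control status by region
#'
#' In deterministic-count mode each region receives exactly
#' `round(fraction * region size)` cases, chosen at random among its
#' individuals; in Bernoulli mode each individual is a case independently
#' with the region's probability. Regions absent from the scenario map are
#' all controls (with a message).
#'
#' @param cohort A `synthetic_cohort`, or a character vector of region labels.
#' @param scenario A [scenario_config()] object.
#' @return Integer phenotype vector in PLINK coding (1 = control, 2 = case),
#'   named by sample id when available.
#' @export
assign_case_control <- function(cohort, scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (inherits(cohort, "synthetic_cohort")) {
    regions <- cohort$sample_metadata$region
    ids <- cohort$sample_metadata$sample_id
  } else {
    regions <- as.character(cohort)
    ids <- names(cohort)
  }
  phen <- rep(1L, length(regions))
  fracs <- scenario$case_fraction_by_region
  missing_regions <- setdiff(unique(regions), names(fracs))
  if (length(missing_regions)) {
    message("regions absent from scenario map assigned all-control status: ",
            paste(missing_regions, collapse = ", "))
  }
  with_seed(derive_seed(scenario$seed, "case_assignment"), {
    for (r in intersect(names(fracs), unique(regions))) {
      rows <- which(regions == r)
      if (scenario$assignment_mode == "deterministic") {
        k <- round(fracs[[r]] * length(rows))
        if (k > 0) phen[sample(rows, k)] <- 2L
      } else {
        phen[rows[stats::runif(length(rows)) < fracs[[r]]]] <- 2L
      }
    }
  })
  if (!is.null(ids)) names(phen) <- ids
  phen
}

#' Convert PLINK-coded phenotypes to a 0/1 indicator
#'
#' @param phen Integer vector coded 1 = control, 2 = case (0/-9 = missing).
#' @return Numeric 0/1 vector with NA for missing phenotypes.
#' @export
phenotype01 <- function(phen) {
  out <- ifelse(phen == 2, 1, ifelse(phen == 1, 0, NA_real_))
  names(out) <- names(phen)
  out
}

#' Write a synthetic cohort to PLINK files plus a metadata table
#'
#' @param cohort A `synthetic_cohort`.
#' @param prefix Output path prefix.
#' @param dialect `"text"` (.ped/.map) or `"binary"` (.bed/.bim/.fam).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  paths <- write_plink(cohort$genotypes, prefix, dialect = dialect)
  meta_path <- paste0(prefix, ".samples.tsv")
  meta <- cohort$sample_metadata
  meta$phenotype[is.na(meta$phenotype)] <- -9L
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, metadata = meta_path))
}
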