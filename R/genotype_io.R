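#' Construct a genotype container
#'
#' Couples a samples x variants dosage matrix (0/1/2/NA, counting copies of
#' allele2) with per-variant records and per-sample metadata.
#'
#' @param dosages Integer matrix, samples in rows, variants in columns.
#' @param variants Data frame with columns variant_id, chrom, pos, allele1,
#'   allele2 (positions are 1-based, as in PLINK .map/.bim).
#' @param samples Data frame with at least a sample_id column.
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(dosages, variants = NULL, samples = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(variants)) {
    ids <- colnames(dosages)
    if (is.null(ids)) ids <- sprintf("var%06d", seq_len(ncol(dosages)))
    variants <- data.frame(variant_id = ids, chrom = 1L,
                           pos = seq_len(ncol(dosages)),
                           allele1 = "A", allele2 = "G",
                           stringsAsFactors = FALSE)
  }
  if (is.null(samples)) {
    ids <- rownames(dosages)
    if (is.null(ids)) ids <- sprintf("S%04d", seq_len(nrow(dosages)))
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(variants$variant_id)) stop_invalid("duplicated variant ids")
  if (anyDuplicated(samples$sample_id)) stop_invalid("duplicated sample ids")
  if (nrow(variants) != ncol(dosages) || nrow(samples) != nrow(dosages)) {
    stop_invalid("dimension mismatch between dosages and annotations")
  }
  if (any(variants$pos < 1)) stop_invalid("positions must be >= 1 (1-based)")
  dimnames(dosages) <- list(samples$sample_id, variants$variant_id)
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

# ---- PLINK text dialect -----------------------------------------------------

#' Write genotypes to PLINK files
#'
#' The text dialect writes .ped/.map; the binary dialect writes
#' .bed/.bim/.fam with the standard SNP-major 2-bit encoding
#' (00 = hom allele1, 01 = missing, 10 = het, 11 = hom allele2).
#'
#' @param x A `genotype_data` object.
#' @param prefix Output path prefix (extensions appended).
#' @param dialect `"binary"` or `"text"`.
#' @return Invisibly, a named character vector of written paths.
#' @export
write_plink <- function(x, prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "genotype_data"))
  if (dialect == "text") write_plink_text(x, prefix) else write_plink_bed(x, prefix)
}

#' Read genotypes from PLINK files
#'
#' @param prefix Path prefix of the fileset.
#' @param dialect `"auto"` (detect from files present), `"binary"` or
#'   `"text"`.
#' @param ref_alleles Optional data frame (variant_id, allele1, allele2)
#'   fixing the allele orientation of the text dialect, which does not store
#'   alleles itself. Without it, allele2 (the counted allele) is taken as
#'   the major allele observed in the file, ties broken by ASCII order.
#' @return A `genotype_data` object. Phenotype/sex columns of .fam/.ped are
#'   carried in the samples table.
#' @export
read_plink <- function(prefix, dialect = c("auto", "binary", "text"),
                       ref_alleles = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (file.exists(paste0(prefix, ".bed"))) "binary" else "text"
  }
  if (dialect == "text") read_plink_text(prefix, ref_alleles)
  else read_plink_bed(prefix)
}

write_plink_text <- function(x, prefix) {
  v <- x$variants
  map <- data.frame(v$chrom, v$variant_id, 0, v$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  G <- x$dosages
  n <- nrow(G); m <- ncol(G)
  a1 <- v$allele1; a2 <- v$allele2
  s <- x$samples
  phen <- if ("phenotype" %in% names(s)) ifelse(is.na(s$phenotype), -9L, s$phenotype) else rep(-9L, n)
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- G[i, ]
    first <- ifelse(is.na(g), "0", ifelse(g >= 1, a2, a1))
    second <- ifelse(is.na(g), "0", ifelse(g == 2, a2, a1))
    lines[i] <- paste(s$sample_id[i], s$sample_id[i], 0, 0, 0, phen[i],
                      paste(rbind(first, second), collapse = " "))
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

read_plink_text <- function(prefix, ref_alleles = NULL) {
  ped_path <- paste0(prefix, ".ped"); map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path)) {
    if (!file.exists(p)) stop_invalid("format-error: file not found: %s", p)
  }
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4) stop_invalid("format-error: %s: expected 4 columns", map_path)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  alleles <- matrix("0", nrow = n, ncol = 2 * m)
  ids <- character(n); phen <- integer(n)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(toks) != 6 + 2 * m) {
      stop_invalid("format-error: %s line %d: expected %d fields, found %d",
                   ped_path, i, 6 + 2 * m, length(toks))
    }
    ids[i] <- toks[2]
    phen[i] <- suppressWarnings(as.integer(toks[6]))
    alleles[i, ] <- toks[-(1:6)]
  }
  G <- matrix(NA_integer_, nrow = n, ncol = m)
  a1 <- character(m); a2 <- character(m)
  ref_map <- NULL
  if (!is.null(ref_alleles)) {
    ref_map <- ref_alleles[match(map$V2, ref_alleles$variant_id), , drop = FALSE]
  }
  for (j in seq_len(m)) {
    x1 <- alleles[, 2 * j - 1]; x2 <- alleles[, 2 * j]
    half_missing <- xor(x1 == "0", x2 == "0")
    if (any(half_missing)) {
      stop_invalid("format-error: %s line %d: half-missing genotype at variant %s",
                   ped_path, which(half_missing)[1], map$V2[j])
    }
    obs <- c(x1, x2); obs <- sort(unique(obs[obs != "0"]))
    if (length(obs) > 2) {
      stop_invalid("format-error: %s: variant %s has >2 alleles (%s)",
                   ped_path, map$V2[j], paste(obs, collapse = ","))
    }
    if (!is.null(ref_map) && !is.na(ref_map$allele2[j])) {
      a1[j] <- ref_map$allele1[j]; a2[j] <- ref_map$allele2[j]
      unknown <- setdiff(obs, c(a1[j], a2[j]))
      if (length(unknown)) {
        stop_invalid("format-error: %s: variant %s has allele %s not in reference",
                     ped_path, map$V2[j], unknown[1])
      }
    } else if (length(obs) == 0) {
      a1[j] <- "A"; a2[j] <- "G"     # all-missing column: placeholder alleles
    } else if (length(obs) == 1) {
      a1[j] <- "0"; a2[j] <- obs     # monomorphic: observed allele counted
    } else {
      # allele2 = major allele (ties broken toward ASCII-later symbol)
      cnt1 <- sum(x1 == obs[1]) + sum(x2 == obs[1])
      cnt2 <- sum(x1 == obs[2]) + sum(x2 == obs[2])
      if (cnt1 > cnt2) { a1[j] <- obs[2]; a2[j] <- obs[1] }
      else { a1[j] <- obs[1]; a2[j] <- obs[2] }
    }
    G[, j] <- ifelse(x1 == "0", NA_integer_,
                     (x1 == a2[j]) + (x2 == a2[j]))
  }
  variants <- data.frame(variant_id = map$V2, chrom = map$V1, pos = map$V4,
                         allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = ids, phenotype = phen,
                        stringsAsFactors = FALSE)
  genotype_data(G, variants, samples)
}

# ---- PLINK binary dialect ---------------------------------------------------

plink_magic <- as.raw(c(0x6c, 0x1b, 0x01))

write_plink_bed <- function(x, prefix) {
  v <- x$variants
  bim <- data.frame(v$chrom, v$variant_id, 0, v$pos, v$allele1, v$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  s <- x$samples
  phen <- if ("phenotype" %in% names(s)) ifelse(is.na(s$phenotype), -9L, s$phenotype) else rep(-9L, nrow(s))
  fam <- data.frame(s$sample_id, s$sample_id, 0, 0, 0, phen)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  G <- x$dosages
  n <- nrow(G); m <- ncol(G)
  # 2-bit codes per sample: 00 hom a1 (dosage 0), 10 het (1), 11 hom a2 (2), 01 missing
  code <- matrix(1L, nrow = n, ncol = m)       # default: missing
  code[!is.na(G) & G == 0L] <- 0L
  code[!is.na(G) & G == 1L] <- 2L
  code[!is.na(G) & G == 2L] <- 3L
  bytes_per_variant <- ceiling(n / 4)
  pad <- bytes_per_variant * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, nrow = pad, ncol = m))
  # pack 4 samples per byte, first sample in the lowest-order bits
  dim(code) <- c(4, bytes_per_variant * m)
  packed <- as.raw(code[1, ] + code[2, ] * 4L + code[3, ] * 16L + code[4, ] * 64L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(plink_magic, con)
  writeBin(packed, con)
  invisible(c(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
              fam = paste0(prefix, ".fam")))
}

read_plink_bed <- function(prefix) {
  for (ext in c(".bed", ".bim", ".fam")) {
    if (!file.exists(paste0(prefix, ext))) {
      stop_invalid("format-error: file not found: %s", paste0(prefix, ext))
    }
  }
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  bed_path <- paste0(prefix, ".bed")
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || !identical(raw[1:3], plink_magic)) {
    stop_invalid("format-error: %s: bad magic bytes at offset 0 (expected 6c 1b 01, SNP-major)",
                 bed_path)
  }
  body <- raw[-(1:3)]
  bytes_per_variant <- ceiling(n / 4)
  if (length(body) != bytes_per_variant * m) {
    stop_invalid("format-error: %s: expected %d data bytes, found %d (byte offset 3)",
                 bed_path, bytes_per_variant * m, length(body))
  }
  vals <- as.integer(body)
  codes <- rbind(vals %% 4L, (vals %/% 4L) %% 4L,
                 (vals %/% 16L) %% 4L, (vals %/% 64L) %% 4L)
  dim(codes) <- c(4 * bytes_per_variant, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  decode <- c(0L, NA_integer_, 1L, 2L)
  G <- matrix(decode[codes + 1L], nrow = n, ncol = m)
  variants <- data.frame(variant_id = bim$V2, chrom = bim$V1, pos = bim$V4,
                         allele1 = bim$V5, allele2 = bim$V6,
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = as.character(fam$V2),
                        phenotype = as.integer(fam$V6),
                        stringsAsFactors = FALSE)
  genotype_data(G, variants, samples)
}

# ---- QC ---------------------------------------------------------------------

#' Per-variant call rate
#'
#' @param x Dosage matrix or `genotype_data`.
#' @return Named numeric vector: fraction of non-missing genotypes per variant.
#' @export
variant_call_rate <- function(x) {
  G <- dosage_matrix(x)
  if (nrow(G) < 1) stop_invalid("invalid input: need at least one sample")
  colMeans(!is.na(G))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed minor-allele count, the
#' probability of each possible heterozygote count is computed and the
#' p-value is the total probability of configurations no more probable than
#' the observed one. The deep tail behaves correctly where the chi-square
#' approximation does not, which matters at stringent thresholds.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major hom, het, minor hom); vectors
#'   are accepted and processed element-wise.
#' @param method `"exact"` (default) or `"chisq"` (1-df Pearson test with no
#'   continuity correction, provided for cross-checking).
#' @return Numeric vector of p-values in (0, 1]; monomorphic input gives 1.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa, method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop_invalid("invalid input: negative genotype counts")
  k <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(n_AA, k); n_Aa <- rep_len(n_Aa, k); n_aa <- rep_len(n_aa, k)
  if (any(n_AA + n_Aa + n_aa < 1)) stop_invalid("invalid input: empty genotype table")
  vapply(seq_len(k), function(i) {
    if (method == "exact") hwe_exact_one(n_AA[i], n_Aa[i], n_aa[i])
    else hwe_chisq_one(n_AA[i], n_Aa[i], n_aa[i])
  }, numeric(1))
}

hwe_exact_one <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  n_minor <- 2 * min(nAA, naa) + nAa
  # orient so 'a' is the minor allele
  if (naa > nAA) { tmp <- nAA; nAA <- naa; naa <- tmp }
  if (n_minor == 0 || n_minor == 2 * n) return(1)
  # possible heterozygote counts share the parity of the minor-allele count
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  # log P(het = h | n, n_minor) up to a constant
  lp <- vapply(hets, function(h) {
    a <- (n_minor - h) / 2          # minor homozygotes
    A <- n - h - a                  # major homozygotes
    h * log(2) - lfactorial(A) - lfactorial(h) - lfactorial(a)
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  p_obs <- p[match(nAa, hets)]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

hwe_chisq_one <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  p <- (2 * nAA + nAa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(nAA, nAa, naa) - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# genotype counts oriented by allele2 dosage: returns 3 x m matrix
genotype_counts <- function(G) {
  rbind(n0 = colSums(G == 0L, na.rm = TRUE),
        n1 = colSums(G == 1L, na.rm = TRUE),
        n2 = colSums(G == 2L, na.rm = TRUE))
}

#' Quality-control filter across cohorts sharing a variant space
#'
#' A variant survives iff it is present (typed) in every cohort, has call
#' rate at or above the threshold in every cohort, and the pooled control
#' genotypes are compatible with Hardy-Weinberg proportions at the stated
#' alpha. Filters are applied in that order and each removed variant is
#' counted once, at its first failing filter.
#'
#' @param cohorts List of `genotype_data` (or dosage matrices) sharing the
#'   same variant order.
#' @param call_rate_min Minimum per-cohort call rate (default 0.99).
#' @param hwe_alpha Hardy-Weinberg exact-test significance threshold
#'   (default 1e-8); a variant is removed when p < alpha.
#' @param control_idx Indices of the cohorts pooled for the HWE test
#'   (default: all of them).
#' @param controls Optional dosage matrix of control genotypes overriding
#'   `control_idx` (used when controls are a row subset of the cohorts).
#' @param hwe_method Passed to [hwe_exact_test()].
#' @return List with `cohorts` (filtered), `keep` (logical vector over input
#'   variants) and `report` (a `qc_report`).
#' @export
qc_filter <- function(cohorts, call_rate_min = 0.99, hwe_alpha = 1e-8,
                      control_idx = seq_along(cohorts), controls = NULL,
                      hwe_method = "exact") {
  if (!length(cohorts)) stop_invalid("invalid input: need at least one cohort")
  if (call_rate_min < 0 || call_rate_min > 1) stop_invalid("invalid configuration: call_rate_min outside [0,1]")
  if (hwe_alpha <= 0 || hwe_alpha > 1) stop_invalid("invalid configuration: hwe_alpha outside (0,1]")
  mats <- lapply(cohorts, dosage_matrix)
  m <- ncol(mats[[1]])
  if (!all(vapply(mats, ncol, 0L) == m)) {
    stop_invalid("invalid input: cohorts do not share a variant space")
  }
  # step 1: presence — typed (any non-missing genotype) in every cohort
  present <- Reduce(`&`, lapply(mats, function(G) colSums(!is.na(G)) > 0))
  removed_presence <- !present
  # step 2: call rate in every cohort
  cr_ok <- Reduce(`&`, lapply(mats, function(G) variant_call_rate(G) >= call_rate_min))
  removed_cr <- present & !cr_ok
  # step 3: HWE in pooled controls
  pooled <- if (!is.null(controls)) dosage_matrix(controls)
            else do.call(rbind, mats[control_idx])
  cnt <- genotype_counts(pooled)
  hwe_p <- rep(1, m)
  cand <- which(present & cr_ok)
  if (length(cand)) {
    hwe_p[cand] <- hwe_exact_test(cnt[1, cand], cnt[2, cand], cnt[3, cand],
                                  method = hwe_method)
  }
  removed_hwe <- present & cr_ok & (hwe_p < hwe_alpha)
  keep <- present & cr_ok & !removed_hwe
  if (!any(keep)) warning("QC removed every variant; returning empty matrices")
  out <- lapply(cohorts, function(x) {
    G <- dosage_matrix(x)[, keep, drop = FALSE]
    if (inherits(x, "genotype_data")) {
      genotype_data(G, x$variants[keep, , drop = FALSE], x$samples)
    } else G
  })
  report <- structure(list(n_input_variants = m,
                           n_removed_not_shared = sum(removed_presence),
                           n_removed_by_call_rate = sum(removed_cr),
                           n_removed_by_hwe = sum(removed_hwe),
                           n_retained = sum(keep)),
                      class = "qc_report")
  list(cohorts = out, keep = keep, hwe_p = hwe_p, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("QC report: %d variants in; removed %d not shared, ",
                     "%d by call rate, %d by HWE; %d retained\n"),
              x$n_input_variants, x$n_removed_not_shared,
              x$n_removed_by_call_rate, x$n_removed_by_hwe, x$n_retained))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report A `qc_report`.
#' @param path Output file.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(metric = names(unclass(report)),
                   value = unlist(unclass(report), use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-variant minor allele frequency
#'
#' Frequencies are computed over non-missing alleles only. A frequency of
#' exactly 0.5 is broken deterministically toward allele2 as the minor
#' allele, so repeated runs agree on orientation.
#'
#' @param x Dosage matrix or `genotype_data` (dosages count allele2 copies).
#' @return Data frame with columns `variant_id`, `maf`, `minor_copies`
#'   (copy count of the minor allele among non-missing genotypes),
#'   `minor_allele` (`"allele1"`/`"allele2"`) and `n_called`. Variants with
#'   no called genotypes get NA maf and are flagged in `defined`.
#' @export
compute_maf <- function(x) {
  G <- dosage_matrix(x)
  n_called <- colSums(!is.na(G))
  s <- colSums(G, na.rm = TRUE)               # allele2 copies
  p2 <- ifelse(n_called > 0, s / (2 * n_called), NA_real_)
  minor_is_2 <- !is.na(p2) & p2 <= 0.5        # tie (0.5) goes to allele2
  maf <- ifelse(minor_is_2, p2, 1 - p2)
  copies <- ifelse(minor_is_2, s, 2 * n_called - s)
  ids <- colnames(G)
  if (is.null(ids)) ids <- sprintf("var%06d", seq_len(ncol(G)))
  if (any(n_called == 0)) {
    warning(sum(n_called == 0), " variant(s) with no called genotypes: MAF undefined")
  }
  data.frame(variant_id = ids,
             maf = maf,
             minor_copies = as.integer(copies),
             minor_allele = ifelse(is.na(p2), NA_character_,
                                   ifelse(minor_is_2, "allele2", "allele1")),
             n_called = as.integer(n_called),
             defined = n_called > 0,
             stringsAsFactors = FALSE)
}

# samples x variants matrix of minor-allele dosages (NA preserved)
minor_dosages <- function(G, maf_table = compute_maf(G)) {
  G <- dosage_matrix(G)
  flip <- which(!is.na(maf_table$minor_allele) & maf_table$minor_allele == "allele1")
  if (length(flip)) G[, flip] <- 2L - G[, flip]
  G
}
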