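#' Armitage trend test
#'
#' One-degree-of-freedom chi-square for a dose-response relationship between
#' genotype dosage and a binary phenotype: N times the squared Pearson
#' correlation of dosage and phenotype over the N non-missing pairs.
#'
#' @param g Dosage vector.
#' @param y Binary 0/1 phenotype vector.
#' @return List with `statistic`, `p`, `n`. Constant dosage or phenotype
#'   gives statistic 0, p 1.
#' @export
armitage_trend <- function(g, y) {
  ok <- !is.na(g) & !is.na(y)
  g <- g[ok]; y <- y[ok]
  n <- length(g)
  if (n < 3) stop_invalid("invalid input: need at least 3 complete pairs")
  if (stats::sd(g) == 0 || stats::sd(y) == 0) {
    return(list(statistic = 0, p = 1, n = n))
  }
  stat <- n * stats::cor(g, y)^2
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE), n = n)
}

#' Vectorized Armitage trend scan
#'
#' @param x Dosage matrix or `genotype_data`.
#' @param y Binary 0/1 phenotype vector.
#' @return Data frame: `variant_id`, `statistic`, `p`, `n`.
#' @export
trend_scan <- function(x, y) {
  G <- dosage_matrix(x)
  if (length(y) != nrow(G)) stop_invalid("invalid input: phenotype length mismatch")
  ok_y <- !is.na(y)
  G <- G[ok_y, , drop = FALSE]; y <- y[ok_y]
  M <- !is.na(G)
  Gz <- G; Gz[!M] <- 0
  n <- colSums(M)
  Sx <- colSums(Gz); Sxx <- colSums(Gz^2)
  Sy <- crossprod(M, y)[, 1]; Syy <- crossprod(M, y^2)[, 1]
  Sxy <- colSums(Gz * y)
  vx <- n * Sxx - Sx^2
  vy <- n * Syy - Sy^2
  r2 <- ifelse(vx > 0 & vy > 0, (n * Sxy - Sx * Sy)^2 / (vx * vy), 0)
  stat <- n * r2
  data.frame(variant_id = colnames(G) %||% sprintf("var%06d", seq_len(ncol(G))),
             statistic = stat,
             p = stats::pchisq(stat, 1, lower.tail = FALSE),
             n = n, stringsAsFactors = FALSE)
}

# orthonormal basis of [1, covariates], dropping collinear columns
covariate_basis <- function(n, covariates = NULL) {
  X <- cbind(rep(1, n), covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("collinear covariates: ", ncol(X) - qrX$rank, " column(s) dropped")
  }
  qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
}

#' PC-adjusted association test (EIGENSTRAT-style)
#'
#' Dosage and phenotype are residualized on the top principal components
#' (with an intercept) by least squares; the statistic is
#' (N - k - 1) times the squared correlation of the residuals, referred to
#' a 1-df chi-square.
#'
#' @param g Dosage vector (missing values mean-imputed).
#' @param y Binary 0/1 phenotype.
#' @param pcs Matrix of k PC score vectors (k = 0 columns allowed, giving
#'   the trend test up to the N/(N-1) factor).
#' @return List with `statistic`, `p`, `k` (PCs actually used), `n`.
#' @export
eigenstrat_adjusted <- function(g, y, pcs = NULL) {
  res <- pcadj_scan(matrix(g, ncol = 1), y, pcs)
  list(statistic = res$statistic[1], p = res$p[1],
       k = attr(res, "k"), n = res$n[1])
}

#' Vectorized PC-adjusted scan
#'
#' @param x Dosage matrix or `genotype_data` (missing mean-imputed).
#' @param y Binary 0/1 phenotype.
#' @param pcs Matrix of PC score vectors (or `pc_result`).
#' @param k Use only the first `k` columns of `pcs` (default: all).
#' @return Data frame: `variant_id`, `statistic`, `p`, `n`; the number of
#'   PCs used is attached as attribute `k`.
#' @export
pcadj_scan <- function(x, y, pcs = NULL, k = NULL) {
  G <- impute_column_means(x)
  n <- nrow(G)
  if (length(y) != n) stop_invalid("invalid input: phenotype length mismatch")
  if (inherits(pcs, "pc_result")) pcs <- pcs$scores
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (!is.null(k)) pcs <- pcs[, seq_len(min(k, ncol(pcs))), drop = FALSE]
    if (ncol(pcs) >= n - 1) stop_invalid("invalid input: k must be < N - 1")
  }
  Q <- covariate_basis(n, pcs)
  k_used <- ncol(Q) - 1L
  ry <- y - Q %*% crossprod(Q, y)
  RG <- G - Q %*% crossprod(Q, G)
  sy <- sum(ry^2)
  sg <- colSums(RG^2)
  sxy <- crossprod(RG, ry)[, 1]
  # residuals that vanish to rounding noise are treated as exactly zero
  eps_g <- 1e-12 * colSums(G^2)
  eps_y <- 1e-12 * sum(y^2)
  r2 <- ifelse(sg > eps_g & sy > eps_y, sxy^2 / (sg * sy), 0)
  stat <- (n - k_used - 1) * r2
  out <- data.frame(variant_id = colnames(G) %||% sprintf("var%06d", seq_len(ncol(G))),
                    statistic = stat,
                    p = stats::pchisq(stat, 1, lower.tail = FALSE),
                    n = n, stringsAsFactors = FALSE)
  attr(out, "k") <- k_used
  out
}

#' Cochran-Mantel-Haenszel stratified allelic test
#'
#' 2 x 2 x K test of case/control allele counts stratified by region, no
#' continuity correction. With a single stratum it reduces to the
#' unstratified allelic chi-square. A permutation p-value can be obtained
#' by shuffling phenotypes within each stratum (add-one corrected).
#'
#' @param g Dosage vector.
#' @param y Binary 0/1 phenotype.
#' @param strata Per-sample stratum labels.
#' @param n_perm Number of within-stratum permutations (0 = asymptotic only).
#' @param seed Permutation seed.
#' @return List with `statistic`, `p` and optionally `p_permutation`. With
#'   no informative stratum, statistic NA and p 1 with a warning.
#' @export
cmh_test <- function(g, y, strata, n_perm = 0, seed = 1L) {
  G <- matrix(g, ncol = 1)
  stat <- cmh_allele_core(G, y == 1, strata)[1]
  if (is.na(stat)) {
    warning("no informative stratum: p = 1")
    return(list(statistic = NA_real_, p = 1))
  }
  out <- list(statistic = stat,
              p = stats::pchisq(stat, 1, lower.tail = FALSE))
  if (n_perm > 0) {
    strata <- factor(strata)
    idx_by_stratum <- split(seq_along(y), strata)
    b <- with_seed(derive_seed(seed, "cmh_perm"), {
      hits <- 0L
      for (i in seq_len(n_perm)) {
        yp <- y
        for (idx in idx_by_stratum) yp[idx] <- y[sample(idx)]
        s <- cmh_allele_core(G, yp == 1, strata)[1]
        if (!is.na(s) && s >= stat - 1e-12) hits <- hits + 1L
      }
      hits
    })
    out$p_permutation <- (b + 1) / (n_perm + 1)
  }
  out
}

#' Vectorized CMH scan
#'
#' @param x Dosage matrix or `genotype_data`.
#' @param y Binary 0/1 phenotype.
#' @param strata Per-sample stratum labels.
#' @return Data frame: `variant_id`, `statistic`, `p`.
#' @export
cmh_scan <- function(x, y, strata) {
  G <- dosage_matrix(x)
  stat <- cmh_allele_core(G, y == 1, strata)
  data.frame(variant_id = colnames(G) %||% sprintf("var%06d", seq_len(ncol(G))),
             statistic = stat,
             p = stats::pchisq(stat, 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Genetic relatedness matrix from standardized dosages
#'
#' K = Z Z' / m where Z is the mean-centered, standard-deviation-scaled
#' dosage matrix over the m variants of the chosen set (missing values
#' mean-imputed; monomorphic variants dropped).
#'
#' @param x Dosage matrix or `genotype_data`.
#' @return Symmetric samples x samples matrix.
#' @export
grm <- function(x) {
  X <- impute_column_means(x)
  if (ncol(X) < 2) stop_invalid("invalid input: need at least 2 variants")
  sds <- apply(X, 2, stats::sd)
  mono <- sds == 0
  if (any(mono)) {
    warning(sum(mono), " monomorphic variant(s) dropped from the GRM")
    X <- X[, !mono, drop = FALSE]; sds <- sds[!mono]
  }
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, sds, `/`)
  K <- tcrossprod(Z) / ncol(Z)
  (K + t(K)) / 2
}

#' Mixed-model association scan with a fixed kinship (EMMAX-style)
#'
#' Variance components of y = mu + u + e with u ~ N(0, sg2 K) and
#' e ~ N(0, se2 I) are fitted once under the null by REML (1-D search over
#' the log variance ratio after eigendecomposition of K). Each variant is
#' then tested by generalized least squares with those components held
#' fixed: the data are rotated and whitened, and the variant's F statistic
#' (equivalently squared t) with 1 and N - 2 degrees of freedom gives the
#' p-value, so an identity kinship recovers ordinary regression exactly.
#' The binary phenotype is treated as quantitative 0/1.
#'
#' @param y Numeric phenotype vector (0/1 for case-control).
#' @param kinship Samples x samples relatedness matrix, e.g. from [grm()].
#' @param x Dosage matrix or `genotype_data` (missing mean-imputed).
#' @param ratio_interval Search interval for delta = se2/sg2
#'   (default `c(1e-5, 1e5)`, searched on the log scale).
#' @param tol Optimizer tolerance on log delta.
#' @return List with `scan` (variant_id, statistic, p), `delta`,
#'   `sigma_g2`, `sigma_e2`, `reml_loglik` (at the optimum),
#'   `reml_loglik_bounds` (at the interval endpoints) and `boundary_ols`
#'   (TRUE when the genetic variance hit the zero boundary, where the model
#'   reduces to ordinary regression).
#' @export
emmax_scan <- function(y, kinship, x, ratio_interval = c(1e-5, 1e5),
                       tol = 1e-6) {
  G <- impute_column_means(x)
  n <- length(y)
  if (!is.matrix(kinship) || nrow(kinship) != n || ncol(kinship) != n) {
    stop_invalid("invalid input: kinship must be an %d x %d matrix", n, n)
  }
  eig <- eigen(kinship, symmetric = TRUE)
  D <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- crossprod(U, y)[, 1]
  xt0 <- crossprod(U, rep(1, n))[, 1]
  reml_ll <- function(log_delta) {
    v <- D + exp(log_delta)
    w <- 1 / v
    sw0 <- sum(w * xt0^2)
    b <- sum(w * xt0 * yt) / sw0
    r <- yt - xt0 * b
    s2 <- sum(w * r^2) / (n - 1)
    -0.5 * ((n - 1) * log(s2) + sum(log(v)) + log(sw0))
  }
  opt <- stats::optimize(reml_ll, interval = log(ratio_interval),
                         maximum = TRUE, tol = tol)
  ll_bounds <- c(reml_ll(log(ratio_interval[1])), reml_ll(log(ratio_interval[2])))
  if (!is.finite(opt$objective)) {
    stop_invalid("REML bracketing failed over delta in [%g, %g]",
                 ratio_interval[1], ratio_interval[2])
  }
  delta <- exp(opt$maximum)
  boundary_ols <- opt$maximum > log(ratio_interval[2]) - 1e-3
  if (boundary_ols) {
    warning("genetic variance at the zero boundary: scan reduces to ordinary regression")
  }
  v <- D + delta
  w <- 1 / v
  sw0 <- sum(w * xt0^2)
  b <- sum(w * xt0 * yt) / sw0
  r <- yt - xt0 * b
  sigma_g2 <- sum(w * r^2) / (n - 1)
  sigma_e2 <- sigma_g2 * delta
  # whiten and test each variant by OLS on the rotated data
  sw <- sqrt(w)
  ys <- yt * sw
  a <- xt0 * sw
  Gs <- crossprod(U, G) * sw
  aa <- sum(a^2)
  ya <- ys - a * (sum(a * ys) / aa)
  Ga <- Gs - a %*% t(colSums(Gs * a) / aa)
  sg <- colSums(Ga^2)
  sxy <- colSums(Ga * ya)
  syy <- sum(ya^2)
  beta2s <- ifelse(sg > 0, sxy^2 / sg, 0)
  rss <- pmax(syy - beta2s, 0)
  stat <- ifelse(sg > 0 & rss > 0, beta2s * (n - 2) / rss, 0)
  scan <- data.frame(variant_id = colnames(G) %||% sprintf("var%06d", seq_len(ncol(G))),
                     statistic = stat,
                     p = stats::pf(stat, 1, n - 2, lower.tail = FALSE),
                     stringsAsFactors = FALSE)
  list(scan = scan, delta = delta, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
       reml_loglik = opt$objective, reml_loglik_bounds = ll_bounds,
       boundary_ols = boundary_ols)
}

#' Genomic-control inflation factor
#'
#' Ratio of the median observed chi-square statistic to the median of the
#' theoretical chi-square with `df` degrees of freedom (0.4549 for 1 df).
#' P-value input is first converted to chi-square quantiles via the
#' upper-tail inverse.
#'
#' @param values Chi-square statistics or p-values.
#' @param df Reference degrees of freedom (default 1).
#' @param input `"chisq"` (default) or `"p"`.
#' @return Scalar lambda.
#' @export
lambda_gc <- function(values, df = 1, input = c("chisq", "p")) {
  input <- match.arg(input)
  values <- values[!is.na(values)]
  if (!length(values)) stop_invalid("invalid input: no statistics supplied")
  if (input == "p") values <- stats::qchisq(values, df = df, lower.tail = FALSE)
  stats::median(values) / stats::qchisq(0.5, df = df)
}

#' Association scans under every correction strategy, summarized by lambda
#'
#' Runs the uncorrected trend test, the region-stratified CMH test,
#' PC-adjusted tests for each supplied PC source set and each k, and the
#' mixed-model scan for each supplied kinship, then tabulates the
#' genomic-control lambda per MAF category (with the rare category further
#' subdivided at MAF 0.005). Lambdas of the chi-square-based tests are
#' computed from the statistics; mixed-model lambdas are computed after
#' transforming the p-values back into 1-df chi-square quantiles.
#'
#' @param x Dosage matrix or `genotype_data` over all tested variants.
#' @param y Binary 0/1 phenotype.
#' @param strata Stratum labels for the CMH test (the true regions).
#' @param variant_table Data frame from [build_variant_table()] aligned
#'   with the variants of `x` (columns `category`, `rare_subcategory`).
#' @param pc_sets Named list of PC score matrices (or `pc_result`s), e.g.
#'   one per source MAF category.
#' @param pc_counts PC adjustment depths (default `c(2, 3, 4, 10)`).
#' @param kinships Named list of kinship matrices for the mixed model.
#' @return An object of class `association_summary`: `lambda` (long data
#'   frame method x category), `grid` (methods x categories matrix) and
#'   `scans` (per-method per-variant results).
#' @export
scan_and_summarize <- function(x, y, strata, variant_table,
                               pc_sets = list(), pc_counts = c(2, 3, 4, 10),
                               kinships = list()) {
  G <- dosage_matrix(x)
  if (nrow(variant_table) != ncol(G)) {
    stop_invalid("invalid input: variant table does not match the variant space")
  }
  # variants monomorphic in the analyzed sample are untestable (their
  # statistics are identically 0) and are excluded from the lambda medians,
  # as association software reports them as NA
  rng <- apply(G, 2, function(g) { g <- g[!is.na(g)]
    if (!length(g)) 0 else max(g) - min(g) })
  poly <- rng > 0
  cat_masks <- list(
    common  = variant_table$category == "common",
    lowfreq = variant_table$category == "lowfreq",
    rare    = variant_table$category == "rare",
    rare_maf_le_0.005 = variant_table$category == "rare" &
      variant_table$rare_subcategory == "very_rare",
    rare_maf_gt_0.005 = variant_table$category == "rare" &
      variant_table$rare_subcategory == "less_rare")
  cat_masks <- lapply(cat_masks, function(mk) which(!is.na(mk) & mk & poly))

  scans <- list()
  scans[["CMH"]] <- list(values = cmh_scan(G, y, strata)$statistic, input = "chisq")
  scans[["Raw"]] <- list(values = trend_scan(G, y)$statistic, input = "chisq")
  for (set_name in names(pc_sets)) {
    pcs <- pc_sets[[set_name]]
    if (inherits(pcs, "pc_result")) pcs <- pcs$scores
    for (k in pc_counts) {
      kk <- min(k, ncol(pcs))
      scans[[paste0(set_name, ".", k)]] <-
        list(values = pcadj_scan(G, y, pcs, k = kk)$statistic, input = "chisq")
    }
  }
  for (set_name in names(kinships)) {
    em <- emmax_scan(y, kinships[[set_name]], G)
    scans[[paste0("EMMAX.", set_name)]] <- list(values = em$scan$p, input = "p")
  }

  rows <- list()
  grid <- matrix(NA_real_, nrow = length(scans), ncol = length(cat_masks),
                 dimnames = list(names(scans), names(cat_masks)))
  for (meth in names(scans)) {
    for (cat in names(cat_masks)) {
      idx <- cat_masks[[cat]]
      lam <- if (length(idx)) {
        lambda_gc(scans[[meth]]$values[idx], df = 1, input = scans[[meth]]$input)
      } else NA_real_
      grid[meth, cat] <- lam
      rows[[length(rows) + 1L]] <- data.frame(method = meth, category = cat,
                                              n_variants = length(idx),
                                              lambda_gc = lam,
                                              stringsAsFactors = FALSE)
    }
  }
  structure(list(lambda = do.call(rbind, rows), grid = grid, scans = scans),
            class = "association_summary")
}

#' @export
print.association_summary <- function(x, ...) {
  cat("genomic-control lambda by method and MAF category:\n")
  print(round(x$grid, 3))
  invisible(x)
}
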