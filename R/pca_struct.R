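#' Greedy LD pruning by pairwise r-squared in sliding windows
#'
#' Within each window of `window` consecutive variants, pairs of retained
#' variants with squared dosage correlation above `r2_max` are resolved by
#' removing the lower-MAF member (ties: the later position); the window then
#' slides by `step` variants. Variants must be ordered by chromosome and
#' position. Missing dosages are mean-imputed for the correlation only.
#'
#' @param x Dosage matrix or `genotype_data`.
#' @param window Window size in variants (default 50).
#' @param step Window slide in variants (default 5).
#' @param r2_max Maximum tolerated squared correlation (default 0.2).
#' @return Integer indices of the retained variants, in input order.
#' @export
ld_prune <- function(x, window = 50, step = 5, r2_max = 0.2) {
  G <- dosage_matrix(x)
  m <- ncol(G)
  if (m == 0) return(integer(0))
  mafs <- compute_maf(G)$maf
  X <- impute_column_means(G)
  keep <- rep(TRUE, m)
  starts <- seq(1, max(1, m - 1), by = step)
  for (s in starts) {
    idx <- s:min(s + window - 1, m)
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(stats::cor(X[, idx, drop = FALSE]))^2
    r2[!is.finite(r2)] <- 0
    active <- rep(TRUE, length(idx))
    for (i in seq_len(length(idx) - 1)) {
      if (!active[i]) next
      for (j in (i + 1):length(idx)) {
        if (!active[j] || r2[i, j] <= r2_max) next
        vi <- idx[i]; vj <- idx[j]
        drop_j <- mafs[vj] < mafs[vi] || (mafs[vj] == mafs[vi])  # tie: later
        if (drop_j) active[j] <- FALSE else { active[i] <- FALSE; break }
      }
    }
    keep[idx[!active]] <- FALSE
  }
  which(keep)
}

impute_column_means <- function(G) {
  G <- dosage_matrix(G)
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- mu[na_idx[, 2]]
  }
  G
}

#' Principal component analysis of genotype dosages
#'
#' Columns are mean-centered and, under allele-frequency weighting, divided
#' by sqrt(p(1-p)) with the posterior-mean frequency estimate
#' p = (1 + sum g) / (2 + 2 n), which up-weights rare variants and never
#' assigns a zero weight. Missing dosages are imputed to the column mean
#' before weighting. Scores and eigenvalues come from the spectral
#' decomposition of the sample-by-sample covariance of the normalized
#' matrix (divisor m, the variant count). The sign of each component is
#' fixed by making its largest-magnitude score positive.
#'
#' @param x Dosage matrix or `genotype_data`.
#' @param k Number of components to return (`k < min(samples, variants)`).
#' @param weighting `"af"` (allele-frequency weighting, the default) or
#'   `"none"`.
#' @return An object of class `pc_result` with `scores` (samples x k,
#'   eigenvector scaled by the square root of its eigenvalue),
#'   `eigenvalues` (non-increasing), `pve` (proportion of variance
#'   explained, over all computed eigenvalues), `variant_ids`, `weighting`.
#' @export
eigen_pca <- function(x, k = 10, weighting = c("af", "none")) {
  weighting <- match.arg(weighting)
  G <- dosage_matrix(x)
  n <- nrow(G); m0 <- ncol(G)
  if (n < 2) stop_invalid("invalid input: need at least two samples")
  if (k >= min(n, m0) && min(n, m0) > 1) k <- min(n, m0) - 1
  k <- max(1L, as.integer(k))
  n_called <- colSums(!is.na(G))
  X <- impute_column_means(G)
  mono <- apply(X, 2, function(col) max(col) == min(col))
  if (any(mono)) {
    warning(sum(mono), " monomorphic variant(s) dropped before PCA")
    X <- X[, !mono, drop = FALSE]
    n_called <- n_called[!mono]
    if (ncol(X) == 0) stop_invalid("invalid input: no polymorphic variants left")
  }
  mu <- colMeans(X)
  X <- sweep(X, 2, mu)
  if (weighting == "af") {
    phat <- (1 + mu * n_called) / (2 + 2 * n_called)   # mu is mean dosage
    X <- sweep(X, 2, sqrt(phat * (1 - phat)), `/`)
  }
  C <- tcrossprod(X) / ncol(X)
  eig <- eigen(C, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(values[seq_len(k)]), nrow = k)
  # deterministic sign: largest-magnitude score entry positive
  for (i in seq_len(k)) {
    peak <- which.max(abs(scores[, i]))
    if (length(peak) && scores[peak, i] < 0) scores[, i] <- -scores[, i]
  }
  dimnames(scores) <- list(rownames(G), paste0("PC", seq_len(k)))
  structure(list(scores = scores,
                 eigenvalues = values[seq_len(k)],
                 pve = values[seq_len(k)] / sum(values),
                 all_eigenvalues = values,
                 variant_ids = colnames(X) %||% which(!mono),
                 weighting = weighting),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("pc_result: %d samples, %d components (%s weighting); PVE: %s\n",
              nrow(x$scores), ncol(x$scores), x$weighting,
              paste(sprintf("%.1f%%", 100 * x$pve), collapse = " ")))
  invisible(x)
}

#' One-way ANOVA of a principal component across regions
#'
#' @param score Numeric vector of one PC's scores.
#' @param regions Per-sample region labels; regions with fewer than two
#'   samples are excluded with a warning.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
pc_region_anova <- function(score, regions) {
  regions <- factor(regions)
  sizes <- table(regions)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("regions with <2 samples excluded from ANOVA: ",
            paste(small, collapse = ", "))
    keep <- !(regions %in% small)
    score <- score[keep]; regions <- droplevels(regions[keep])
  }
  if (nlevels(regions) < 2) stop_invalid("invalid input: need >=2 regions")
  fit <- stats::anova(stats::lm(score ~ regions))
  list(F = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
       p = fit$`Pr(>F)`[1])
}

#' Cross-correlation of principal components from two analyses
#'
#' Single R-squared values are squared Pearson correlations between score
#' vectors; the cumulative R-squared of a component against the other
#' analysis is the coefficient of determination of its least-squares
#' projection (with intercept) onto the other analysis' top `top_k`
#' components.
#'
#' @param pcs_a,pcs_b `pc_result` objects over the same samples, same order.
#' @param n_pcs How many leading components of each side to tabulate.
#' @param top_k How many components of `pcs_b` enter the cumulative fit.
#' @return List with `single` (n_pcs x n_pcs matrix of R-squared) and
#'   `cumulative` (length-n_pcs vector, one per component of `pcs_a`).
#' @export
pc_cross_correlation <- function(pcs_a, pcs_b, n_pcs = 2, top_k = 10) {
  A <- if (inherits(pcs_a, "pc_result")) pcs_a$scores else as.matrix(pcs_a)
  B <- if (inherits(pcs_b, "pc_result")) pcs_b$scores else as.matrix(pcs_b)
  if (nrow(A) != nrow(B)) stop_invalid("invalid input: sample sets differ")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B))) {
    stop_invalid("invalid input: sample order differs between analyses")
  }
  ka <- min(n_pcs, ncol(A)); kb <- min(n_pcs, ncol(B))
  single <- matrix(NA_real_, ka, kb,
                   dimnames = list(colnames(A)[seq_len(ka)],
                                   colnames(B)[seq_len(kb)]))
  for (i in seq_len(ka)) for (j in seq_len(kb)) {
    single[i, j] <- suppressWarnings(stats::cor(A[, i], B[, j]))^2
  }
  kk <- min(top_k, ncol(B))
  # coefficient of determination of the least-squares projection onto
  # [1, B_1..B_kk], computed directly (degenerate perfect fits are fine)
  Qb <- qr.Q(qr(cbind(1, B[, seq_len(kk), drop = FALSE])))
  cumulative <- vapply(seq_len(ka), function(i) {
    a <- A[, i]
    tss <- sum((a - mean(a))^2)
    if (tss == 0) return(NA_real_)
    rss <- sum((a - Qb %*% crossprod(Qb, a))^2)
    max(0, min(1, 1 - rss / tss))
  }, numeric(1))
  names(cumulative) <- colnames(A)[seq_len(ka)]
  list(single = single, cumulative = cumulative, top_k = kk)
}

#' Cross-subset stability of principal components
#'
#' Draws disjoint random variant subsets, runs a PCA on each and tabulates
#' the R-squared between like-numbered components of every subset pair, plus
#' the cumulative R-squared against the other subset's top components. Used
#' to gauge how much of a structure signal survives a change of markers.
#'
#' @param x Dosage matrix or `genotype_data`.
#' @param n_subsets Number of disjoint subsets.
#' @param subset_size Variants per subset (`n_subsets * subset_size` must
#'   not exceed the variant count).
#' @param seed Seed controlling the partition.
#' @param n_pcs,top_k,weighting,k Passed through to the PCA / correlation.
#' @return List with `partition` (list of variant index vectors), `pcs`
#'   (list of `pc_result`) and `r2` (data frame: subset_a, subset_b, pc,
#'   r2_single, r2_cumulative).
#' @export
disjoint_subset_stability <- function(x, n_subsets, subset_size, seed = 1L,
                                      n_pcs = 2, top_k = 10, k = 10,
                                      weighting = "af") {
  G <- dosage_matrix(x)
  m <- ncol(G)
  if (n_subsets * subset_size > m) {
    stop_invalid("invalid input: %d subsets of %d variants exceed the %d available",
                 n_subsets, subset_size, m)
  }
  partition <- with_seed(derive_seed(seed, "subset_partition"), {
    perm <- sample.int(m, n_subsets * subset_size)
    split(perm, rep(seq_len(n_subsets), each = subset_size))
  })
  pcs <- lapply(partition, function(idx) {
    eigen_pca(G[, sort(idx), drop = FALSE], k = k, weighting = weighting)
  })
  rows <- list()
  for (a in seq_len(n_subsets - 1)) for (b in (a + 1):n_subsets) {
    cc <- pc_cross_correlation(pcs[[a]], pcs[[b]], n_pcs = n_pcs, top_k = top_k)
    for (p in seq_len(nrow(cc$single))) {
      rows[[length(rows) + 1L]] <- data.frame(
        subset_a = a, subset_b = b, pc = p,
        r2_single = cc$single[p, min(p, ncol(cc$single))],
        r2_cumulative = cc$cumulative[p])
    }
  }
  list(partition = partition, pcs = pcs, r2 = do.call(rbind, rows))
}

#' Supervised ancestry assignment by EM
#'
#' Per-region allele frequencies are fixed from labelled reference samples
#' (with a pseudocount of 0.5 per allele, so no frequency is ever 0 or 1).
#' For each target individual the admixture proportions q over the K
#' regions maximize the binomial log-likelihood
#' sum_j [ g_j log(sum_r q_r p_rj) + (2 - g_j) log(1 - sum_r q_r p_rj) ]
#' on the simplex, via EM. The log-likelihood is checked to be
#' non-decreasing at every iteration.
#'
#' @param ref Dosage matrix or `genotype_data` of the labelled reference.
#' @param ref_regions Region labels of the reference samples (must cover
#'   every region of interest).
#' @param target Dosage matrix or `genotype_data` over the same variants.
#' @param tol Convergence threshold on the total log-likelihood gain per
#'   iteration (default 1e-4, the termination criterion of the reference
#'   admixture software).
#' @param max_iter Iteration cap; non-convergence returns with a warning.
#' @return An object of class `ancestry_result`: `Q` (targets x regions,
#'   rows on the simplex), `loglik` per target, `assignment` (argmax
#'   region), `confident` (max posterior above 0.5), `converged`,
#'   `n_iter`, `ref_freq`.
#' @export
supervised_ancestry <- function(ref, ref_regions, target,
                                tol = 1e-4, max_iter = 1000) {
  Gr <- dosage_matrix(ref)
  Gt <- dosage_matrix(target)
  if (ncol(Gr) != ncol(Gt)) stop_invalid("invalid input: variant spaces differ")
  ref_regions <- factor(ref_regions)
  K <- nlevels(ref_regions)
  called_r <- !is.na(Gr)
  Gr0 <- Gr; Gr0[!called_r] <- 0L
  a2 <- rowsum_full(Gr0, ref_regions)                 # K x m allele2 copies
  tot <- 2 * rowsum_full(called_r + 0L, ref_regions)  # K x m total alleles
  P <- t((a2 + 0.5) / (tot + 1))                      # m x K frequencies
  t_n <- nrow(Gt); m <- ncol(Gt)
  W <- !is.na(Gt)
  G1 <- ifelse(W, Gt, 0)          # allele2 copies
  G0 <- ifelse(W, 2 - Gt, 0)      # allele1 copies
  m_i <- rowSums(W)
  if (any(m_i == 0)) stop_invalid("invalid input: target individual with no called genotypes")
  Q <- matrix(1 / K, nrow = t_n, ncol = K,
              dimnames = list(rownames(Gt), levels(ref_regions)))
  loglik_of <- function(Q) {
    MU <- pmin(pmax(Q %*% t(P), 1e-12), 1 - 1e-12)
    rowSums(G1 * log(MU) + G0 * log1p(-MU))
  }
  ll <- loglik_of(Q)
  converged <- FALSE; iter <- 0L
  if (K == 1) { converged <- TRUE }
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    MU <- pmin(pmax(Q %*% t(P), 1e-12), 1 - 1e-12)
    A <- (G1 / MU) %*% P            # targets x K: allele2-responsibility mass
    B <- (G0 / (1 - MU)) %*% (1 - P)
    Q_new <- Q * (A + B) / (2 * m_i)
    Q_new <- Q_new / rowSums(Q_new)
    ll_new <- loglik_of(Q_new)
    if (any(ll_new < ll - 1e-6)) {
      stop("internal error: EM log-likelihood decreased")
    }
    gain <- sum(ll_new) - sum(ll)
    Q <- Q_new; ll <- ll_new
    if (gain < tol) converged <- TRUE
  }
  if (!converged) warning("supervised ancestry EM did not converge in ",
                          max_iter, " iterations")
  best <- max.col(Q, ties.method = "first")
  structure(list(Q = Q,
                 loglik = ll,
                 assignment = colnames(Q)[best],
                 confident = Q[cbind(seq_len(t_n), best)] > 0.5,
                 converged = converged,
                 n_iter = iter,
                 ref_freq = P),
            class = "ancestry_result")
}

#' Summarize supervised ancestry assignments against true labels
#'
#' @param ancestry An `ancestry_result` (or a Q matrix with region-named
#'   columns).
#' @param true_regions Character vector of true region labels per target.
#' @param threshold Posterior-probability threshold (default 0.5).
#' @return List: `n_correct_confident` (individuals whose posterior at the
#'   true region exceeds the threshold), `fraction_correct_confident`,
#'   `n_correct_argmax`, `fraction_correct_argmax`.
#' @export
summarize_assignment <- function(ancestry, true_regions, threshold = 0.5) {
  Q <- if (inherits(ancestry, "ancestry_result")) ancestry$Q else as.matrix(ancestry)
  if (nrow(Q) != length(true_regions)) stop_invalid("invalid input: label length mismatch")
  col_idx <- match(as.character(true_regions), colnames(Q))
  if (anyNA(col_idx)) stop_invalid("invalid input: true region absent from Q columns")
  p_true <- Q[cbind(seq_len(nrow(Q)), col_idx)]
  argmax <- max.col(Q, ties.method = "first")
  list(n_correct_confident = sum(p_true > threshold),
       fraction_correct_confident = mean(p_true > threshold),
       n_correct_argmax = sum(argmax == col_idx),
       fraction_correct_argmax = mean(argmax == col_idx))
}
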