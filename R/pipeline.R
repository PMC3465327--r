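pipeline_defaults <- function() {
  list(
    simulation = list(n_regions = 2, samples_per_region = c(100, 100),
                      n_variants = c(common = 4000, lowfreq = 1000, rare = 1000),
                      maf_spectrum = NULL, fst = 0.01,
                      private_rare_fraction = 0.2,
                      missing_rate = 0.002, genotype_error_rate = 0),
    scenario = list(case_fraction_by_region = NULL,
                    assignment_mode = "deterministic"),
    qc = list(call_rate_min = 0.99, hwe_alpha = 1e-8),
    categories = list(copy_threshold = 2),
    pruning = list(window = 50, step = 5, r2_max = 0.2),
    pca = list(k = 10, weighting = "af", n_pcs = 2, top_k = 10),
    ancestry = list(run = FALSE, tol = 1e-6, max_iter = 500),
    association = list(pc_counts = c(2, 3, 4, 10),
                       pc_sources = c("common", "lowfreq", "rare"),
                       kinship_sources = c("common", "lowfreq", "rare")),
    seed = 1L,
    out_dir = "stratspectrum_out"
  )
}

#' Build and validate a pipeline configuration
#'
#' @param config Named list (or path to a YAML/JSON file) overriding the
#'   defaults section by section. Unknown keys are rejected.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop_invalid("invalid configuration: unknown key(s): %s",
                 paste(unknown, collapse = ", "))
  }
  out <- defaults
  for (sect in names(config)) {
    if (is.list(defaults[[sect]]) && !is.null(names(defaults[[sect]]))) {
      bad <- setdiff(names(config[[sect]]), names(defaults[[sect]]))
      if (length(bad)) {
        stop_invalid("invalid configuration: unknown key(s) in %s: %s",
                     sect, paste(bad, collapse = ", "))
      }
      out[[sect]][names(config[[sect]])] <- config[[sect]]
    } else {
      out[[sect]] <- config[[sect]]
    }
  }
  if (is.list(out$simulation$n_variants)) {
    out$simulation$n_variants <- unlist(out$simulation$n_variants)
  }
  if (is.list(out$scenario$case_fraction_by_region)) {
    out$scenario$case_fraction_by_region <- unlist(out$scenario$case_fraction_by_region)
  }
  if (out$qc$hwe_alpha <= 0 || out$qc$hwe_alpha > 1) {
    stop_invalid("invalid configuration: qc$hwe_alpha outside (0, 1]")
  }
  if (out$qc$call_rate_min < 0 || out$qc$call_rate_min > 1) {
    stop_invalid("invalid configuration: qc$call_rate_min outside [0, 1]")
  }
  if (out$pruning$r2_max <= 0 || out$pruning$r2_max > 1) {
    stop_invalid("invalid configuration: pruning$r2_max outside (0, 1]")
  }
  # constructing the stage configs validates their own invariants eagerly
  do.call(sim_config, c(out$simulation, list(seed = out$seed)))
  if (!is.null(out$scenario$case_fraction_by_region)) {
    scenario_config(out$scenario$case_fraction_by_region,
                    out$scenario$assignment_mode, seed = out$seed)
  }
  structure(out, class = "pipeline_config")
}

#' Serialize a pipeline configuration to YAML
#'
#' Named vectors (variant counts, case fractions) are written as YAML maps
#' so that every field stays addressable by key on re-read.
#'
#' @param config A `pipeline_config` (or coercible list).
#' @param path Output file.
#' @export
write_pipeline_config <- function(config, path) {
  config <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  out <- unclass(config)
  out$simulation$n_variants <- as.list(out$simulation$n_variants)
  if (!is.null(out$scenario$case_fraction_by_region)) {
    out$scenario$case_fraction_by_region <- as.list(out$scenario$case_fraction_by_region)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  path
}

#' Run the full stratification analysis pipeline
#'
#' Stage order: simulate a structured cohort (and assign case status when a
#' scenario is configured), quality control, MAF stratification statistics,
#' pruning + PCA + cross-category PC correlations, optional supervised
#' ancestry, association scans with the lambda grid, and report tables.
#' Every intermediate artifact is written as PLINK or TSV under `out_dir`,
#' and a manifest records the seed and per-file checksums; identical
#' configurations reproduce identical outputs.
#'
#' @param config A [pipeline_config()] (or list / path coercible to one).
#' @param out_dir Output directory (overrides the config entry).
#' @param stages Character vector of stages to run (default all, in order).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL,
                         stages = c("simulate", "qc", "stratify", "pca",
                                    "ancestry", "assoc", "report")) {
  config <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  all_stages <- c("simulate", "qc", "stratify", "pca", "ancestry", "assoc", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  for (stage in all_stages[all_stages %in% stages]) {
    fn <- get(paste0("stage_", stage), mode = "function")
    t0 <- Sys.time()
    ok <- try(fn(state, config, out_dir), silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop_invalid("stage '%s' failed [E_%s]: %s", stage, toupper(stage),
                   conditionMessage(attr(ok, "condition")))
    }
    message(sprintf("[%s] done in %.1fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  invisible(as.list(state))
}

load_cohort_state <- function(state, out_dir) {
  if (!is.null(state$genotypes)) return(invisible(state))
  prefix <- file.path(out_dir, "cohort")
  state$genotypes <- read_plink(prefix)
  meta <- utils::read.table(paste0(prefix, ".samples.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  meta$phenotype[meta$phenotype %in% c(0L, -9L)] <- NA_integer_
  state$metadata <- meta
  invisible(state)
}

stage_simulate <- function(state, config, out_dir) {
  sc <- do.call(sim_config, c(config$simulation, list(seed = config$seed)))
  cohort <- simulate_cohort(sc)
  if (!is.null(config$scenario$case_fraction_by_region)) {
    scen <- scenario_config(config$scenario$case_fraction_by_region,
                            config$scenario$assignment_mode,
                            seed = config$seed)
    cohort$sample_metadata$phenotype <- assign_case_control(cohort, scen)
    cohort$genotypes$samples$phenotype <- cohort$sample_metadata$phenotype
  }
  write_cohort(cohort, file.path(out_dir, "cohort"))
  state$cohort <- cohort
  state$genotypes <- cohort$genotypes
  state$metadata <- cohort$sample_metadata
  invisible(state)
}

stage_qc <- function(state, config, out_dir) {
  load_cohort_state(state, out_dir)
  meta <- state$metadata
  G <- state$genotypes
  by_cohort <- split(seq_len(nrow(meta)), meta$cohort)
  cohorts <- lapply(by_cohort, function(idx) {
    genotype_data(G$dosages[idx, , drop = FALSE], G$variants,
                  G$samples[idx, , drop = FALSE])
  })
  is_control <- is.na(meta$phenotype) | meta$phenotype == 1L
  # HWE is evaluated on control genotypes only, pooled across cohorts
  qc <- qc_filter(cohorts, call_rate_min = config$qc$call_rate_min,
                  hwe_alpha = config$qc$hwe_alpha,
                  controls = G$dosages[is_control, , drop = FALSE])
  state$keep <- qc$keep
  state$qc_report <- qc$report
  state$genotypes_qc <- genotype_data(G$dosages[, qc$keep, drop = FALSE],
                                      G$variants[qc$keep, , drop = FALSE],
                                      G$samples)
  write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"))
  write_tsv(data.frame(variant_id = G$variants$variant_id, kept = qc$keep),
            file.path(out_dir, "qc_keep.tsv"))
  invisible(state)
}

load_qc_state <- function(state, config, out_dir) {
  if (!is.null(state$genotypes_qc)) return(invisible(state))
  load_cohort_state(state, out_dir)
  keep_path <- file.path(out_dir, "qc_keep.tsv")
  if (!file.exists(keep_path)) stop("qc outputs not found; run the qc stage first")
  keep <- utils::read.table(keep_path, header = TRUE, sep = "\t")$kept
  G <- state$genotypes
  state$keep <- keep
  state$genotypes_qc <- genotype_data(G$dosages[, keep, drop = FALSE],
                                      G$variants[keep, , drop = FALSE],
                                      G$samples)
  invisible(state)
}

stage_stratify <- function(state, config, out_dir) {
  load_qc_state(state, config, out_dir)
  meta <- state$metadata
  Gq <- state$genotypes_qc
  is_control <- is.na(meta$phenotype) | meta$phenotype == 1L
  Gc <- Gq$dosages[is_control, , drop = FALSE]
  regions_c <- meta$region[is_control]
  vt <- build_variant_table(Gc, regions = regions_c,
                            copy_threshold = config$categories$copy_threshold)
  state$variant_table <- vt
  write_tsv(vt, file.path(out_dir, "variant_table.tsv"))

  lam_rows <- list(); share_rows <- list()
  het <- heterogeneity_scan(Gc, regions_c)
  for (cat in c("common", "lowfreq", "rare")) {
    idx <- which(!is.na(vt$category) & vt$category == cat)
    if (!length(idx)) next
    p <- het$p[idx]; p <- p[!is.na(p)]
    lam_rows[[cat]] <- data.frame(category = cat, n_variants = length(idx),
                                  lambda_r = if (length(p)) lambda_r(p) else NA_real_)
    if (cat %in% c("rare", "lowfreq")) {
      sh <- region_sharing(Gc, regions_c, variant_subset = idx,
                           expected = (cat == "rare"), method = "exact")
      share_rows[[cat]] <- data.frame(
        category = cat,
        n_regions = as.integer(names(sh$histogram)),
        n_variants = as.integer(sh$histogram),
        proportion_all_regions = sh$proportion_all_regions,
        expected_all_regions = sh$expected_all_regions %||% NA_real_)
    }
  }
  state$lambda_r_table <- do.call(rbind, lam_rows)
  write_tsv(state$lambda_r_table, file.path(out_dir, "lambda_r.tsv"))
  if (length(share_rows)) {
    state$sharing_table <- do.call(rbind, share_rows)
    write_tsv(state$sharing_table, file.path(out_dir, "sharing.tsv"))
  }
  rare_idx <- which(!is.na(vt$category) & vt$category == "rare")
  if (length(rare_idx)) {
    bt <- rare_allele_burden(Gc, rare_idx, regions_c)
    burden_df <- data.frame(sample_id = rownames(Gc) %||% seq_len(nrow(Gc)),
                            region = regions_c, rare_burden = bt$burden)
    write_tsv(burden_df, file.path(out_dir, "burden.tsv"))
    state$burden <- bt
  }
  invisible(state)
}

load_variant_table <- function(state, config, out_dir) {
  if (!is.null(state$variant_table)) return(invisible(state))
  path <- file.path(out_dir, "variant_table.tsv")
  if (!file.exists(path)) stop("variant table not found; run the stratify stage first")
  state$variant_table <- utils::read.table(path, header = TRUE, sep = "\t",
                                           stringsAsFactors = FALSE)
  invisible(state)
}

stage_pca <- function(state, config, out_dir) {
  load_qc_state(state, config, out_dir)
  load_variant_table(state, config, out_dir)
  Gq <- state$genotypes_qc$dosages
  vt <- state$variant_table
  meta <- state$metadata
  pcs <- list(); anova_rows <- list()
  for (cat in c("common", "lowfreq", "rare")) {
    idx <- which(!is.na(vt$category) & vt$category == cat)
    if (length(idx) < 3) next
    sub <- Gq[, idx, drop = FALSE]
    kept <- ld_prune(sub, window = config$pruning$window,
                     step = config$pruning$step, r2_max = config$pruning$r2_max)
    pr <- eigen_pca(sub[, kept, drop = FALSE], k = config$pca$k,
                    weighting = config$pca$weighting)
    pcs[[cat]] <- pr
    write_tsv(data.frame(sample_id = rownames(pr$scores), pr$scores),
              file.path(out_dir, sprintf("pca_%s_scores.tsv", cat)))
    write_tsv(data.frame(component = seq_along(pr$eigenvalues),
                         eigenvalue = pr$eigenvalues, pve = pr$pve),
              file.path(out_dir, sprintf("pca_%s_scree.tsv", cat)))
    for (pc in seq_len(min(3, ncol(pr$scores)))) {
      an <- tryCatch(pc_region_anova(pr$scores[, pc], meta$region),
                     error = function(e) NULL)
      if (!is.null(an)) {
        anova_rows[[paste(cat, pc)]] <- data.frame(category = cat, pc = pc,
                                                   F = an$F, p = an$p)
      }
    }
  }
  state$pcs <- pcs
  if (length(anova_rows)) {
    write_tsv(do.call(rbind, anova_rows), file.path(out_dir, "pc_region_anova.tsv"))
  }
  if (length(pcs) >= 2) {
    state$pc_correlations <- pc_correlation_table(pcs, n_pcs = config$pca$n_pcs,
                                                  top_k = config$pca$top_k)
    write_tsv(as.data.frame(state$pc_correlations),
              file.path(out_dir, "pc_correlations.tsv"), row_names = TRUE)
  }
  invisible(state)
}

stage_ancestry <- function(state, config, out_dir) {
  if (!isTRUE(config$ancestry$run)) return(invisible(state))
  load_qc_state(state, config, out_dir)
  load_variant_table(state, config, out_dir)
  meta <- state$metadata
  Gq <- state$genotypes_qc$dosages
  vt <- state$variant_table
  is_ref <- meta$cohort == sort(unique(meta$cohort))[1]
  rows <- list()
  for (cat in c("common", "lowfreq", "rare")) {
    idx <- which(!is.na(vt$category) & vt$category == cat)
    if (length(idx) < 10) next
    anc <- supervised_ancestry(Gq[is_ref, idx, drop = FALSE],
                               meta$region[is_ref],
                               Gq[!is_ref, idx, drop = FALSE],
                               tol = config$ancestry$tol,
                               max_iter = config$ancestry$max_iter)
    sm <- summarize_assignment(anc, meta$region[!is_ref])
    rows[[cat]] <- data.frame(category = cat,
                              n_targets = nrow(anc$Q),
                              n_correct_confident = sm$n_correct_confident,
                              fraction_correct_confident = sm$fraction_correct_confident,
                              fraction_correct_argmax = sm$fraction_correct_argmax)
    write_tsv(data.frame(sample_id = rownames(anc$Q) %||% seq_len(nrow(anc$Q)),
                         anc$Q),
              file.path(out_dir, sprintf("ancestry_%s_Q.tsv", cat)))
  }
  if (length(rows)) {
    state$ancestry_summary <- do.call(rbind, rows)
    write_tsv(state$ancestry_summary, file.path(out_dir, "ancestry_summary.tsv"))
  }
  invisible(state)
}

stage_assoc <- function(state, config, out_dir) {
  load_qc_state(state, config, out_dir)
  load_variant_table(state, config, out_dir)
  meta <- state$metadata
  if (all(is.na(meta$phenotype))) {
    message("no phenotype configured: association stage skipped")
    return(invisible(state))
  }
  y <- phenotype01(meta$phenotype)
  Gq <- state$genotypes_qc$dosages
  vt <- state$variant_table
  pc_sets <- list()
  for (src in config$association$pc_sources) {
    if (!is.null(state$pcs[[src]])) pc_sets[[src]] <- state$pcs[[src]]$scores
  }
  kinships <- list()
  for (src in config$association$kinship_sources) {
    idx <- which(!is.na(vt$category) & vt$category == src)
    if (length(idx) >= 2) kinships[[src]] <- grm(Gq[, idx, drop = FALSE])
  }
  summ <- scan_and_summarize(Gq, y, meta$region, vt,
                             pc_sets = pc_sets,
                             pc_counts = config$association$pc_counts,
                             kinships = kinships)
  state$association <- summ
  write_tsv(summ$lambda, file.path(out_dir, "lambda_gc_grid.tsv"))
  long <- do.call(rbind, lapply(names(summ$scans), function(m) {
    data.frame(variant_id = vt$variant_id, method = m,
               value = summ$scans[[m]]$values,
               value_type = summ$scans[[m]]$input, stringsAsFactors = FALSE)
  }))
  write_tsv(long, file.path(out_dir, "assoc_scans.tsv"))
  invisible(state)
}

stage_report <- function(state, config, out_dir) {
  tables <- make_report_tables(state)
  if (!is.null(tables$table1)) {
    write_tsv(as.data.frame(tables$table1), file.path(out_dir, "table1_pc_r2.tsv"),
              row_names = TRUE)
  }
  if (!is.null(tables$table2)) {
    write_tsv(as.data.frame(tables$table2), file.path(out_dir, "table2_lambda_gc.tsv"),
              row_names = TRUE)
  }
  files <- setdiff(list.files(out_dir), "manifest.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))))
  manifest <- manifest[order(manifest$file), ]
  cfg_string <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "\n")
  cfg_file <- tempfile(); writeLines(cfg_string, cfg_file)
  header <- data.frame(file = c("#seed", "#config_hash"),
                       md5 = c(as.character(config$seed),
                               unname(tools::md5sum(cfg_file))))
  unlink(cfg_file)
  write_tsv(rbind(header, manifest), file.path(out_dir, "manifest.tsv"))
  state$manifest <- manifest
  invisible(state)
}

# Table-1-shaped matrix of pairwise PC R^2 values across MAF categories
pc_correlation_table <- function(pcs, n_pcs = 2, top_k = 10) {
  cats <- names(pcs)
  pc_labels <- unlist(lapply(cats, function(cat) paste0("PC", seq_len(n_pcs), ".", cat)))
  top_labels <- paste0("Top", top_k, ".", cats)
  out <- matrix(NA_real_, nrow = length(pc_labels),
                ncol = length(pc_labels) + length(cats),
                dimnames = list(pc_labels, c(pc_labels, top_labels)))
  for (a in cats) for (b in cats) {
    cc <- pc_cross_correlation(pcs[[a]], pcs[[b]], n_pcs = n_pcs, top_k = top_k)
    for (i in seq_len(nrow(cc$single))) {
      row <- paste0("PC", i, ".", a)
      for (j in seq_len(ncol(cc$single))) {
        out[row, paste0("PC", j, ".", b)] <- cc$single[i, j]
      }
      out[row, paste0("Top", top_k, ".", b)] <- cc$cumulative[i]
    }
  }
  out
}

#' Assemble report tables mirroring the headline table layouts
#'
#' @param state Pipeline state (list or environment) holding `pcs` and/or
#'   `association` results; missing stages yield NULL entries.
#' @return List with `table1` (PC R-squared matrix, PC1.common ...
#'   Top10.rare) and `table2` (lambda grid, methods x MAF categories).
#' @export
make_report_tables <- function(state) {
  if (is.environment(state)) state <- as.list(state)
  table1 <- NULL; table2 <- NULL
  if (!is.null(state$pc_correlations)) {
    table1 <- state$pc_correlations
  } else if (!is.null(state$pcs) && length(state$pcs) >= 2) {
    table1 <- pc_correlation_table(state$pcs)
  }
  if (!is.null(state$association)) {
    table2 <- state$association$grid
    colnames(table2) <- c("Common", "LowFreq", "Rare",
                          "MAF<=0.005", "MAF>0.005")[seq_len(ncol(table2))]
  }
  list(table1 = table1, table2 = table2)
}
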