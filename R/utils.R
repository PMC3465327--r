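#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a global seed and a stage label.
# Stages of a pipeline draw from independent substreams so that each stage
# can be re-run in isolation with the same stream it saw in the full run.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(label) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

# Run an expression with a locally seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Accept either a plain dosage matrix or a genotype_data object.
dosage_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "genotype_data")) return(x$dosages)
  if (inherits(x, "synthetic_cohort")) return(x$genotypes$dosages)
  stop_invalid("expected a dosage matrix, genotype_data or synthetic_cohort")
}

check_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1) ||
      (!allow_zero && any(x == 0)) || (!allow_one && any(x == 1))) {
    stop_invalid("invalid configuration: %s must lie in %s", name,
                 if (allow_zero && allow_one) "[0, 1]" else "(0, 1)")
  }
  invisible(x)
}
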