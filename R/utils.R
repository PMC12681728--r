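# Internal condition helpers and shared input validation.
#
# All user-facing errors carry a package-specific condition class so callers
# (and the test suite) can distinguish bad inputs from genuine bugs:
#   g6pd_invalid_input    - malformed numeric/vector arguments
#   g6pd_invalid_genotype - X-linkage violations in genotype data
#   g6pd_lookup_error     - requested variant absent from a VCF
#   g6pd_degenerate_labels- single-class labels where two classes are required
#   g6pd_data_integrity   - inconsistent keyed tables (duplicates, misjoins)
#   g6pd_config_error     - bad configuration values or missing columns

abort_invalid <- function(message) {
  rlang::abort(message, class = "g6pd_invalid_input")
}

abort_genotype <- function(message) {
  rlang::abort(message, class = "g6pd_invalid_genotype")
}

abort_lookup <- function(message) {
  rlang::abort(message, class = "g6pd_lookup_error")
}

abort_degenerate <- function(message) {
  rlang::abort(message, class = "g6pd_degenerate_labels")
}

abort_integrity <- function(message) {
  rlang::abort(message, class = "g6pd_data_integrity")
}

abort_config <- function(message) {
  rlang::abort(message, class = "g6pd_config_error")
}

# Require a numeric vector with all entries finite.
check_numeric_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x))) {
    abort_invalid(sprintf("`%s` must be numeric, non-empty, and finite.", name))
  }
  invisible(x)
}

# Require columns to be present, naming the first offender.
validate_columns <- function(df, required, where) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort_config(sprintf(
      "%s is missing required column(s): %s.",
      where, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb user-level randomness.
with_local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a RNG state to save
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}
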