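# internal helpers shared across modules

# stop unless x is a numeric matrix with unique, non-empty dimnames
check_named_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", what))
  }
  rn <- rownames(x)
  cn <- colnames(x)
  if (is.null(rn) || is.null(cn)) {
    abort(sprintf("`%s` must have row and column names.", what))
  }
  if (anyDuplicated(rn)) abort(sprintf("duplicate row names in `%s`.", what))
  if (anyDuplicated(cn)) abort(sprintf("duplicate column names in `%s`.", what))
  invisible(x)
}

check_scalar_number <- function(x, what, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].", what, lower, upper))
  }
  invisible(x)
}

# run expr with a private RNG state seeded from `seed` (global state untouched)
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# deterministic derived seeds for sub-stages, kept under 2^31
# (double arithmetic stays exact: products are far below 2^53)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483647)
}
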