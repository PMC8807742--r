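# Internal helpers shared across modules.

# Validate a beta matrix: numeric matrix, CpG rows, sample columns,
# unique dimnames, unmasked values in [0,1].
check_beta_matrix <- function(beta, allow_na = FALSE, arg = "beta") {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    abort(sprintf("`%s` must be a numeric matrix (CpGs x samples).", arg))
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    abort(sprintf("`%s` must have CpG rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(beta)) || anyDuplicated(colnames(beta))) {
    abort(sprintf("`%s` has duplicated CpG or sample ids.", arg))
  }
  vals <- beta[!is.na(beta)]
  if (!allow_na && anyNA(beta)) {
    abort(sprintf("`%s` contains masked (NA) entries where none are allowed.", arg))
  }
  if (length(vals) && (min(vals) < 0 || max(vals) > 1)) {
    abort(sprintf("`%s` has values outside [0, 1].", arg))
  }
  invisible(beta)
}

check_scalar_number <- function(x, arg, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", arg, lower, upper))
  }
  invisible(x)
}

# Derive a per-stage seed from a global seed; keeps within 32-bit range.
derive_seed <- function(seed, stage) {
  (as.integer(seed) + as.integer(stage)) %% .Machine$integer.max
}

# Dirichlet draws via normalized gammas; rows sum to 1.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# pmin/pmax keep the first argument's attributes, so x must come first
# or matrix inputs lose their dims.
clip01 <- function(x, eps = 0) pmin(pmax(x, eps), 1 - eps)

# Beta-distribution mean/variance from shapes.
beta_mean <- function(a, b) a / (a + b)
beta_var <- function(a, b) a * b / ((a + b)^2 * (a + b + 1))

# Shapes from mean m and precision s = a + b.
beta_shapes <- function(m, s) list(a = m * s, b = (1 - m) * s)

cell_types <- function() c("epithelial", "fibroblast", "immune", "tumour")
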