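# Internal helpers shared across modules.

# Deterministically derive `n` child seeds from a master seed, so that every
# source of randomness (feature draws, docking draws, per-k k-means runs, gap
# reference datasets) consumes an independent, reproducible stream. Seeds stay
# below 2^31 - 1.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# Squared Euclidean cross-distances between the rows of A and the rows of B.
# Clamped at zero: the expansion |a|^2 + |b|^2 - 2ab can go slightly negative
# in floating point for near-duplicate rows.
cross_sqdist <- function(A, B) {
  d <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

stop_rffr <- function(message, class, ...) {
  abort(message, class = c(class, "rffr_error"), ...)
}

# Coerce the feature argument of the clustering/validity functions: accepts an
# `rffr_features` object (preferred) or a bare numeric matrix.
feature_values <- function(x, arg = "x") {
  if (inherits(x, "rffr_features")) {
    return(x$values)
  }
  if (is.matrix(x) && is.numeric(x)) {
    return(x)
  }
  stop_rffr(
    sprintf("`%s` must be an `rffr_features` object or a numeric matrix.", arg),
    "rffr_type_error"
  )
}

feature_row_ids <- function(x) {
  if (inherits(x, "rffr_features")) x$row_ids else rownames(x) %||% as.character(seq_len(nrow(x)))
}
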