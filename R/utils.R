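# Internal helpers shared across modules.

# Numerically stable row-wise softmax for a matrix of logits.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Probability-vector validation used by the policy core.  Tolerance on the
# sum is looser than the 1e-9 construction invariant so that float output of
# a softmax never trips it.
check_prob_vector <- function(p, arg = "p", tol = 1e-6) {
  if (!is.numeric(p) || length(p) < 2L) {
    abort(sprintf("`%s` must be a numeric probability vector over K >= 2 classes.", arg),
          class = "epee_error_class_space")
  }
  if (anyNA(p) || any(p < -tol) || any(p > 1 + tol)) {
    abort(sprintf("`%s` must have entries in [0, 1].", arg),
          class = "epee_error_distribution")
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (off by %.3g).", arg, abs(sum(p) - 1)),
          class = "epee_error_distribution")
  }
  invisible(p)
}

check_prob_matrix <- function(probs, arg = "probs") {
  if (!is.matrix(probs) || nrow(probs) < 1L) {
    abort(sprintf("`%s` must be a layers-by-classes probability matrix.", arg),
          class = "epee_error_trajectory")
  }
  for (m in seq_len(nrow(probs))) check_prob_vector(probs[m, ], arg)
  invisible(probs)
}

check_count <- function(x, arg, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", arg, min),
          class = "epee_error_config")
  }
  as.integer(x)
}

check_fraction <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", arg),
          class = "epee_error_config")
  }
  as.numeric(x)
}

first_true <- function(x) {
  # Index of the first TRUE, or NA_integer_ if none.
  w <- which(x)
  if (length(w)) w[[1L]] else NA_integer_
}
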