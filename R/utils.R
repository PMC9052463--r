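#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform `%||%`
#' @importFrom stats rnorm runif sd median var optim coef lm setNames
#' @importFrom utils head tail
NULL

# Row-wise log-sum-exp of a matrix of log terms.
logsumexp_rows <- function(logx) {
  m <- logx[, 1L]
  for (k in seq_len(ncol(logx))[-1L]) m <- pmax(m, logx[, k])
  m + log(rowSums(exp(logx - m)))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

# Draw one sub-seed per consumer from a parent seed without touching the
# caller's RNG state.  Sub-seeds stay below 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_psd <- function(mat, name = "growth_cov", tol = 1e-8) {
  if (!is.matrix(mat) || !all(dim(mat) == c(2L, 2L))) {
    abort(sprintf("`%s` must be a 2x2 matrix.", name))
  }
  if (max(abs(mat - t(mat))) > tol * max(1, max(abs(mat)))) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  ev <- eigen((mat + t(mat)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev)))) {
    abort(sprintf("`%s` must be positive semi-definite.", name))
  }
  invisible(TRUE)
}
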