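#' Implied mean and covariance of one latent class
#'
#' Marginalizing the random growth factors out of the linear growth model
#' gives, for a class with mean intercept `a0` and mean slope `a1`, the
#' occasion mean `mu_t = a0 + a1 * lambda_t` and covariance
#' `Sigma = L Psi L' + theta I`, where `L` has rows `(1, lambda_t)`, `Psi`
#' is the growth-factor covariance and `theta` the occasion residual
#' variance.
#'
#' @param intercept,slope Class growth-factor means.
#' @param growth_cov 2x2 positive semi-definite growth-factor covariance.
#' @param residual_var Occasion residual variance, `>= 0`.
#' @param time_scores Numeric vector of time scores.
#' @return A list with `mean` (length T) and `cov` (T x T).
#' @examples
#' implied_moments(10, 0, diag(2) * 0, 1, time_scores = 0:2)
#' @export
implied_moments <- function(intercept, slope, growth_cov, residual_var,
                            time_scores) {
  check_psd(growth_cov)
  if (residual_var < 0) abort("`residual_var` must be nonnegative.")
  if (!all(is.finite(time_scores))) abort("`time_scores` must be finite.")
  L <- cbind(1, time_scores)
  covm <- L %*% growth_cov %*% t(L) + diag(residual_var, length(time_scores))
  list(mean = as.numeric(intercept + slope * time_scores),
       cov = (covm + t(covm)) / 2)
}

# Unvalidated implied covariance for hot paths (exported implied_moments
# performs the PSD validation).
implied_cov_fast <- function(growth_cov, residual_var, lambda) {
  L <- cbind(1, lambda)
  covm <- L %*% growth_cov %*% t(L)
  diag(covm) <- diag(covm) + residual_var
  covm
}

# Cholesky-based log-density of MVN observations. `chol_cov` is the upper
# Cholesky factor of the covariance; `resid` a T x n matrix of centred
# observations (one column per unit).
mvn_loglik_chol <- function(resid, chol_cov) {
  z <- backsolve(chol_cov, resid, transpose = TRUE)
  logdet <- 2 * sum(log(diag(chol_cov)))
  -0.5 * (nrow(chol_cov) * log(2 * pi) + logdet + colSums(z^2))
}

safe_chol <- function(covm, context = "implied covariance") {
  ch <- tryCatch(chol(covm), error = function(e) NULL)
  if (is.null(ch)) {
    abort(sprintf(
      "%s is singular; consider flooring the residual variance above 0.",
      context
    ))
  }
  ch
}

#' Log-likelihood of one trajectory under one class
#'
#' Evaluates the log multivariate-normal density of a single unit's
#' observed values under a class's implied moments, restricted to the
#' non-missing occasions (the marginal of an MVN over a subset of
#' coordinates is the MVN of that subset).
#'
#' @param values Numeric vector of length T; `NA` marks missing occasions.
#' @param time_scores Time scores, length T.
#' @inheritParams implied_moments
#' @return The log-density (a scalar).
#' @export
class_loglik <- function(values, time_scores, intercept, slope, growth_cov,
                         residual_var) {
  obs <- !is.na(values)
  if (!any(obs)) abort("Need at least one non-missing observation.")
  mom <- implied_moments(intercept, slope, growth_cov, residual_var,
                         time_scores[obs])
  ch <- safe_chol(mom$cov, "restricted implied covariance")
  as.numeric(mvn_loglik_chol(cbind(values[obs] - mom$mean), ch))
}

# Per-unit, per-class log-density matrix for a whole panel. Units sharing a
# missingness pattern share Cholesky factors (and, with a shared
# growth-factor covariance, all classes share the same factor).
panel_class_logliks <- function(panel, model) {
  n <- nrow(panel$values)
  K <- model$K
  lambda <- panel$time_scores
  out <- matrix(NA_real_, n, K)
  for (grp in panel$pattern_groups) {
    lam <- lambda[grp$obs]
    ch <- NULL  # shared across classes when the growth covariance is shared
    for (k in seq_len(K)) {
      if (is.null(ch) || model$classwise_psi) {
        covk <- implied_cov_fast(psi_k(model, k), model$residual_var, lam)
        ch <- safe_chol(covk, "restricted implied covariance")
      }
      mu <- model$intercepts[k] + model$slopes[k] * lam
      out[grp$rows, k] <- mvn_loglik_chol(grp$Yt - mu, ch)
    }
  }
  out
}
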