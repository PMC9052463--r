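# Independent brute-force oracles used to validate the likelihood code.
# Deliberately naive: explicit determinant and matrix inverse, no Cholesky,
# no log-space tricks, so they share no code path with the package.

bf_mvn_loglik <- function(y, mu, Sigma) {
  d <- length(y)
  dev <- as.numeric(y - mu)
  quad <- as.numeric(t(dev) %*% solve(Sigma) %*% dev)
  -0.5 * (d * log(2 * pi) + log(det(Sigma)) + quad)
}

bf_implied_moments <- function(intercept, slope, psi, theta, lambda) {
  Tn <- length(lambda)
  L <- cbind(rep(1, Tn), lambda)
  list(mean = intercept + slope * lambda,
       cov = L %*% psi %*% t(L) + theta * diag(Tn))
}

# Mixture loglik and posteriors for one unit, summing densities naively.
bf_unit_mixture <- function(y, lambda, weights, intercepts, slopes, psi,
                            theta) {
  obs <- !is.na(y)
  dens <- sapply(seq_along(weights), function(k) {
    mom <- bf_implied_moments(intercepts[k], slopes[k], psi, theta,
                              lambda[obs])
    exp(bf_mvn_loglik(y[obs], mom$mean, mom$cov))
  })
  list(loglik = log(sum(weights * dens)),
       post = weights * dens / sum(weights * dens))
}

bf_panel_mixture <- function(panel, model) {
  n <- nrow(panel$values)
  out <- lapply(seq_len(n), function(i) {
    bf_unit_mixture(panel$values[i, ], panel$time_scores, model$weights,
                    model$intercepts, model$slopes, model$growth_cov,
                    model$residual_var)
  })
  list(loglik = sum(vapply(out, `[[`, numeric(1), "loglik")),
       post = matrix(unlist(lapply(out, `[[`, "post")), nrow = n,
                     byrow = TRUE))
}

# Per-class ordinary least squares on pooled observations, for hard labels.
bf_class_ols <- function(panel, labels, k) {
  rows <- which(labels == k)
  idx <- which(!panel$missing_mask[rows, , drop = FALSE], arr.ind = TRUE)
  X <- cbind(1, panel$time_scores[idx[, 2]])
  y <- panel$values[rows, , drop = FALSE][idx]
  as.numeric(solve(t(X) %*% X) %*% t(X) %*% y)
}

# Small random panel with values safely inside the percent scale.
random_panel <- function(n, Tn, seed, missing_rate = 0) {
  withr::with_seed(seed, {
    lambda <- 0:(Tn - 1)
    vals <- matrix(50 + rnorm(n * Tn, sd = 8), n, Tn)
    vals <- vals + outer(runif(n, -1, 1), lambda)
    vals <- pmin(pmax(vals, 0), 100)
    if (missing_rate > 0) {
      drop <- matrix(runif(n * Tn) < missing_rate, n, Tn)
      drop[rowSums(!drop) < 2, ] <- FALSE
      vals[drop] <- NA_real_
    }
    trajmix:::new_panel(sprintf("u%02d", 1:n), 2000L + lambda, vals)
  })
}

random_small_model <- function(K, seed) {
  withr::with_seed(seed, {
    w <- runif(K, 0.5, 1.5)
    a <- matrix(rnorm(2), 2, 2)
    psi <- a %*% t(a) / 2 + diag(c(0.5, 0.05))
    psi[1, 2] <- psi[2, 1] <- psi[1, 2] / 2
    gmm_model(
      weights = w / sum(w),
      intercepts = runif(K, 42, 58),
      slopes = runif(K, -1, 1),
      growth_cov = psi,
      residual_var = runif(1, 0.5, 3)
    )
  })
}
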