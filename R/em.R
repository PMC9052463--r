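#' E-step: posterior class memberships and total log-likelihood
#'
#' Computes, for every unit, the posterior probability of each latent class
#' (Bayes' rule over the class-marginal multivariate-normal densities,
#' evaluated stably in log space) and the observed-data log-likelihood
#' `sum_i log sum_k pi_k f_k(y_i)`.
#'
#' @param panel A `trajmix_panel`.
#' @param model A `trajmix_model`.
#' @return A list with `posteriors` (n x K matrix, rows summing to 1) and
#'   `loglik` (scalar).
#' @export
e_step <- function(panel, model) {
  ll <- panel_class_logliks(panel, model)
  logw <- sweep(ll, 2L, log(model$weights), `+`)
  lse <- logsumexp_rows(logw)
  if (any(!is.finite(lse))) {
    bad <- which(!is.finite(lse))[1]
    abort(sprintf(
      "All class densities underflow for unit '%s'.", panel$unit_ids[bad]
    ))
  }
  post <- exp(logw - lse)
  list(posteriors = post, loglik = sum(lse))
}

#' M-step: update model parameters given posterior memberships
#'
#' Class weights are the mean posterior memberships. Class means are the
#' posterior-weighted generalized-least-squares regressions of each
#' trajectory on `(1, lambda)` under the current implied covariance.
#' The growth-factor covariance and the residual variance are then updated
#' by posterior-weighted expected-moment formulas, using the conditional
#' moments of the latent growth factors evaluated at the refreshed class
#' means (so a full `e_step`/`m_step` sweep never decreases the observed
#' log-likelihood).
#'
#' @param panel A `trajmix_panel`.
#' @param posteriors n x K posterior matrix from [e_step()].
#' @param model Current `trajmix_model`.
#' @param control A [gmm_control()] list.
#' @return The updated `trajmix_model`.
#' @export
m_step <- function(panel, posteriors, model, control = gmm_control()) {
  n <- nrow(panel$values)
  K <- model$K
  stopifnot(nrow(posteriors) == n, ncol(posteriors) == K)
  mass <- colSums(posteriors)
  if (any(mass < control$min_class_mass)) {
    abort(sprintf("Class %d has posterior mass %.3f (< %g unit-equivalents).",
                  which.min(mass), min(mass), control$min_class_mass),
          class = "trajmix_degenerate")
  }
  weights_new <- mass / n

  lambda <- panel$time_scores
  groups <- panel$pattern_groups

  # --- class means by posterior-weighted GLS under the current covariance
  mu_new <- matrix(0, K, 2)
  A_acc <- replicate(K, matrix(0, 2, 2), simplify = FALSE)
  b_acc <- replicate(K, numeric(2), simplify = FALSE)
  for (grp in groups) {
    X <- grp$X
    Y <- grp$Yt
    SiX <- NULL
    for (k in seq_len(K)) {
      if (is.null(SiX) || model$classwise_psi) {
        covk <- implied_cov_fast(psi_k(model, k), model$residual_var,
                                 lambda[grp$obs])
        ch <- safe_chol(covk)
        SiX <- backsolve(ch, backsolve(ch, X, transpose = TRUE))
      }
      pk <- posteriors[grp$rows, k]
      A_acc[[k]] <- A_acc[[k]] + sum(pk) * crossprod(X, SiX)
      b_acc[[k]] <- b_acc[[k]] + drop(crossprod(SiX, Y %*% pk))
    }
  }
  for (k in seq_len(K)) mu_new[k, ] <- solve(A_acc[[k]], b_acc[[k]])

  mid <- new_gmm_model(weights_new, mu_new[, 1], mu_new[, 2],
                       model$growth_cov, model$residual_var,
                       model$classwise_psi)

  # --- fresh E-pass at the refreshed means, then expected-moment updates
  post2 <- e_step(panel, mid)$posteriors
  psi_num <- if (model$classwise_psi) {
    replicate(K, matrix(0, 2, 2), simplify = FALSE)
  } else {
    matrix(0, 2, 2)
  }
  psi_den <- numeric(K)
  theta_num <- 0
  theta_den <- 0
  for (grp in groups) {
    rows <- grp$rows
    Tj <- sum(grp$obs)
    X <- grp$X
    Y <- grp$Yt
    G <- NULL
    for (k in seq_len(K)) {
      if (is.null(G) || model$classwise_psi) {
        psi <- psi_k(mid, k)
        covk <- implied_cov_fast(psi, mid$residual_var, lambda[grp$obs])
        ch <- safe_chol(covk)
        G <- t(backsolve(ch, backsolve(ch, X %*% psi, transpose = TRUE))) # 2 x T
        V <- psi - G %*% X %*% psi                                       # 2 x 2
        trXVX <- sum(diag(X %*% V %*% t(X)))
      }
      D <- G %*% (Y - as.numeric(X %*% mu_new[k, ]))                    # 2 x n
      pk <- post2[rows, k]
      contrib <- V * sum(pk) + D %*% (t(D) * pk)
      if (model$classwise_psi) {
        psi_num[[k]] <- psi_num[[k]] + contrib
      } else {
        psi_num <- psi_num + contrib
      }
      psi_den[k] <- psi_den[k] + sum(pk)
      R <- Y - X %*% (D + mu_new[k, ])                                  # resid
      theta_num <- theta_num + sum(pk * colSums(R^2)) + sum(pk) * trXVX
      theta_den <- theta_den + sum(pk) * Tj
    }
  }
  sym <- function(m) (m + t(m)) / 2
  psi_new <- if (model$classwise_psi) {
    purrr::imap(psi_num, function(m, k) sym(m / psi_den[k]))
  } else {
    sym(psi_num / n)
  }
  theta_new <- max(theta_num / theta_den, control$theta_floor)

  new_gmm_model(weights_new, mu_new[, 1], mu_new[, 2], psi_new, theta_new,
                model$classwise_psi)
}

#' EM control parameters
#'
#' @param n_starts Number of random initializations in the multi-start
#'   search.
#' @param n_final Number of best short-run starts continued to full
#'   convergence.
#' @param short_iter EM sweeps allotted to each short run.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM sweeps for a full run.
#' @param min_class_mass Minimum posterior mass (in unit-equivalents) a
#'   class may shrink to before the start is declared degenerate.
#' @param theta_floor Lower bound for the residual variance, keeping
#'   implied covariances positive definite.
#' @param classwise_psi Free the growth-factor covariance per class?
#' @param boot_n_starts,boot_n_final,boot_max_iter Reduced multi-start and
#'   iteration settings used for the many refits inside bootstrap
#'   procedures (each bootstrap refit is additionally warm-started from
#'   the generating estimates).
#' @return A named list of class `trajmix_control`.
#' @export
gmm_control <- function(n_starts = 50L, n_final = 10L, short_iter = 30L,
                        tol = 1e-8, max_iter = 500L, min_class_mass = 1,
                        theta_floor = 1e-6, classwise_psi = FALSE,
                        boot_n_starts = 2L, boot_n_final = 1L,
                        boot_max_iter = 50L) {
  stopifnot(n_starts >= 1L, n_final >= 1L, tol > 0, max_iter >= 1L)
  structure(
    list(
      n_starts = as.integer(n_starts), n_final = as.integer(n_final),
      short_iter = as.integer(short_iter), tol = tol,
      max_iter = as.integer(max_iter), min_class_mass = min_class_mass,
      theta_floor = theta_floor, classwise_psi = isTRUE(classwise_psi),
      boot_n_starts = as.integer(boot_n_starts),
      boot_n_final = as.integer(boot_n_final),
      boot_max_iter = as.integer(boot_max_iter)
    ),
    class = "trajmix_control"
  )
}

# One EM run from a given model; returns model, trace, convergence flag.
run_em <- function(panel, model, control, max_iter) {
  trace <- numeric(0)
  est <- e_step(panel, model)
  trace <- est$loglik
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    model <- m_step(panel, est$posteriors, model, control)
    est <- e_step(panel, model)
    trace <- c(trace, est$loglik)
    delta <- trace[it + 1L] - trace[it]
    if (abs(delta) < control$tol * (abs(trace[it + 1L]) + 1e-3)) {
      converged <- TRUE
      break
    }
  }
  list(model = model, posteriors = est$posteriors, loglik = est$loglik,
       trace = trace, converged = converged)
}

# Per-unit OLS lines, used for initialization.
unit_ols <- function(panel) {
  n <- nrow(panel$values)
  coefs <- matrix(NA_real_, n, 2)
  rss <- numeric(n)
  dfs <- numeric(n)
  for (i in seq_len(n)) {
    obs <- !panel$missing_mask[i, ]
    X <- cbind(1, panel$time_scores[obs])
    y <- panel$values[i, obs]
    beta <- solve(crossprod(X), crossprod(X, y))
    coefs[i, ] <- beta
    rss[i] <- sum((y - X %*% beta)^2)
    dfs[i] <- max(sum(obs) - 2, 0)
  }
  list(coefs = coefs, rss = rss, dfs = dfs)
}

# Random-partition initialization: units split into K groups, class lines
# from pooled per-group OLS, variance components from per-unit OLS moments.
init_model <- function(panel, K, control, partition = NULL) {
  ols <- unit_ols(panel)
  n <- nrow(panel$values)
  partition <- partition %||% sample(rep_len(seq_len(K), n))
  mu <- matrix(0, K, 2)
  for (k in seq_len(K)) {
    rows <- which(partition == k)
    if (!length(rows)) rows <- sample.int(n, 1L)
    obs <- which(!panel$missing_mask[rows, , drop = FALSE], arr.ind = TRUE)
    X <- cbind(1, panel$time_scores[obs[, 2]])
    y <- panel$values[rows, , drop = FALSE][obs]
    mu[k, ] <- solve(crossprod(X), crossprod(X, y))
  }
  psi0 <- diag(c(max(var(ols$coefs[, 1]), 1e-2),
                 max(var(ols$coefs[, 2]), 1e-4)))
  theta0 <- max(sum(ols$rss) / max(sum(ols$dfs), 1), control$theta_floor, 0.1)
  w <- tabulate(partition, K)
  w <- pmax(w, 0.5)
  gmm_model(w / sum(w), mu[, 1], mu[, 2],
            if (control$classwise_psi) replicate(K, psi0, simplify = FALSE)
            else psi0,
            theta0, control$classwise_psi)
}
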