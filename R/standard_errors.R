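#' Standard errors for class intercepts and slopes
#'
#' Two methods are offered. `"bootstrap"` (parametric) simulates `B`
#' panels from the fitted model, refits each one (warm-started at the
#' fitted estimates plus reduced random starts), matches the replicate
#' classes back to the original labels, and reports the standard deviation
#' of the estimates over replicates. `"hessian"` computes the numeric
#' observed information of the mixture log-likelihood at the estimates (on
#' an unconstrained parameterization) and reports the square roots of the
#' corresponding diagonal entries of its inverse.
#'
#' @param fit A converged `trajmix_fit` (the panel travels inside it).
#' @param method `"bootstrap"` or `"hessian"`.
#' @param B Bootstrap replicates (`>= 20`); ignored for `"hessian"`.
#' @param seed Integer seed (bootstrap only).
#' @return A tibble with columns `class`, `intercept_se`, `slope_se`, plus
#'   (bootstrap) `n_replicates`. Also available via `tidy()` after
#'   assigning the result to `fit$se`.
#' @examples
#' \donttest{
#' sim <- simulate_panel(asia_underweight_spec(), seed = 1)
#' fit <- fit_growth_mixture(sim$panel, K = 3, seed = 1)
#' standard_errors(fit, method = "hessian")
#' }
#' @export
standard_errors <- function(fit, method = c("bootstrap", "hessian"), B = 200L,
                            seed = NULL) {
  stopifnot(inherits(fit, "trajmix_fit"))
  method <- match.arg(method)
  if (!fit$converged) abort("Standard errors need a converged fit.")
  if (method == "bootstrap") {
    if (!is_count(B) || B < 20L) abort("Bootstrap needs `B >= 20`.")
    if (is.null(seed) || !is_count(seed)) abort("`seed` (integer) is required.")
    se_bootstrap(fit, B, seed)
  } else {
    se_hessian(fit)
  }
}

se_bootstrap <- function(fit, B, seed) {
  ctrl <- fit$control
  ctrl$n_starts <- fit$control$boot_n_starts
  ctrl$n_final <- fit$control$boot_n_final
  ctrl$max_iter <- fit$control$boot_max_iter
  ctrl$short_iter <- min(fit$control$short_iter, 15L)
  ref <- cbind(fit$model$intercepts, fit$model$slopes)
  seeds <- derive_seeds(seed, B)
  est <- purrr::map(seq_len(B), function(b) {
    sub <- derive_seeds(seeds[b], 2L)
    bpanel <- simulate_from_model(fit$panel, fit$model, seed = sub[1])
    f <- refit_quiet(bpanel, fit$K, ctrl, sub[2], init = fit$model)
    if (is.null(f)) return(NULL)
    bmat <- cbind(f$model$intercepts, f$model$slopes)
    perm <- tryCatch(match_classes(ref, bmat), error = function(e) NULL)
    if (is.null(perm)) return(NULL)
    bmat[perm, , drop = FALSE]
  })
  est <- purrr::compact(est)
  if (length(est) < B / 2) {
    abort("Too many bootstrap refits failed; increase `B` or EM starts.")
  }
  arr <- simplify2array(est)                       # K x 2 x B_ok
  tibble::tibble(
    class = seq_len(fit$K),
    intercept_se = apply(arr[, 1, , drop = FALSE], 1, sd),
    slope_se = apply(arr[, 2, , drop = FALSE], 1, sd),
    n_replicates = length(est)
  )
}

# Unconstrained parameter vector <-> model, for numeric information.
pack_model <- function(model) {
  psis <- if (model$classwise_psi) model$growth_cov else list(model$growth_cov)
  chp <- unlist(lapply(psis, function(p) {
    ch <- chol_psd(p + diag(1e-10, 2))
    c(log(ch[1, 1]), ch[1, 2], log(ch[2, 2]))
  }))
  c(model$intercepts, model$slopes,
    log(model$weights[-model$K] / model$weights[model$K]),
    chp, log(model$residual_var))
}

unpack_model <- function(par, K, classwise_psi) {
  intercepts <- par[seq_len(K)]
  slopes <- par[K + seq_len(K)]
  eta <- if (K > 1L) par[2L * K + seq_len(K - 1L)] else numeric(0)
  w <- exp(c(eta, 0))
  w <- w / sum(w)
  npsi <- if (classwise_psi) K else 1L
  chp <- par[2L * K + (K - 1L) + seq_len(3L * npsi)]
  psis <- lapply(seq_len(npsi), function(j) {
    v <- chp[3L * (j - 1L) + 1:3]
    ch <- matrix(c(exp(v[1]), 0, v[2], exp(v[3])), 2, 2)
    crossprod(ch)
  })
  theta <- exp(par[length(par)])
  gmm_model(w, intercepts, slopes,
            if (classwise_psi) psis else psis[[1]], theta, classwise_psi)
}

se_hessian <- function(fit) {
  K <- fit$K
  cw <- fit$model$classwise_psi
  par0 <- pack_model(fit$model)
  negll <- function(par) {
    m <- tryCatch(unpack_model(par, K, cw), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    tryCatch(-e_step(fit$panel, m)$loglik, error = function(e) 1e10)
  }
  H <- pracma::hessian(negll, par0)
  inv <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(inv) || any(diag(inv)[seq_len(2L * K)] <= 0)) {
    abort(paste0("Observed information is singular or indefinite at the ",
                 "estimates; use method = 'bootstrap'."))
  }
  se <- sqrt(diag(inv))
  tibble::tibble(
    class = seq_len(K),
    intercept_se = se[seq_len(K)],
    slope_se = se[K + seq_len(K)]
  )
}
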