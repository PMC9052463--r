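#' Information criteria for a fitted mixture
#'
#' Standard definitions: `AIC = -2 ll + 2 p`, `BIC = -2 ll + p log(n)`, and
#' the sample-size-adjusted BIC `SSBIC = -2 ll + p log((n + 2) / 24)`,
#' where `n` is the number of units (not unit-year observations).
#'
#' @param loglik Log-likelihood (vectorized).
#' @param n_params Number of free parameters.
#' @param n_units Number of units.
#' @return A tibble with columns `AIC`, `BIC`, `SSBIC`.
#' @examples
#' information_criteria(-1000, 5, 39)
#' @export
information_criteria <- function(loglik, n_params, n_units) {
  stopifnot(all(n_units >= 1), all(n_params >= 0))
  tibble::tibble(
    AIC = -2 * loglik + 2 * n_params,
    BIC = -2 * loglik + n_params * log(n_units),
    SSBIC = -2 * loglik + n_params * log((n_units + 2) / 24)
  )
}

#' Relative entropy of a posterior classification
#'
#' `1 - sum_ik(-p_ik log p_ik) / (n log K)`: 1 when every unit is assigned
#' to a class with certainty, 0 when every posterior row is uniform.
#' Values near 1 indicate near-deterministic class membership.
#'
#' @param posteriors A `trajmix_fit` or an n x K posterior matrix with
#'   `K >= 2`.
#' @return A scalar in `[0, 1]`.
#' @export
entropy <- function(posteriors) {
  if (inherits(posteriors, "trajmix_fit")) posteriors <- posteriors$posteriors
  p <- as.matrix(posteriors)
  if (ncol(p) < 2L) abort("Entropy is undefined for a single class.")
  plogp <- ifelse(p > 0, p * log(p), 0)
  1 - sum(-plogp) / (nrow(p) * log(ncol(p)))
}

#' Parametric bootstrap likelihood-ratio test for K vs K - 1 classes
#'
#' Computes the likelihood-ratio statistic
#' `LR = 2 (loglik_K - loglik_{K-1})` on the data, then simulates `B`
#' panels from the fitted `(K-1)`-class model, refits both models on each
#' (warm-started from the observed-data estimates plus reduced random
#' starts), and reports the bootstrap p-value
#' `(1 + #\{LR_b >= LR_obs\}) / (B + 1)`. The naive chi-square p-value
#' (df = parameter difference) is also returned but is invalid at the
#' boundary of the parameter space and should not be used for selection.
#'
#' @param panel A `trajmix_panel`.
#' @param K Alternative number of classes (`>= 2`).
#' @param B Number of bootstrap replicates (`>= 19`).
#' @param control A [gmm_control()] list.
#' @param seed Integer seed.
#' @param fit_k,fit_km1 Optional pre-computed fits of the `K`- and
#'   `(K-1)`-class models on `panel` (refitted here if absent).
#' @return A list of class `trajmix_lrt`: `statistic`, `p_value`,
#'   `lr_boot`, `B`, `df`, `naive_p`, `K`.
#' @export
bootstrap_lrt <- function(panel, K, B = 99L, control = gmm_control(), seed,
                          fit_k = NULL, fit_km1 = NULL) {
  stopifnot(inherits(panel, "trajmix_panel"))
  if (!is_count(K) || K < 2L) abort("`K` must be an integer >= 2.")
  if (!is_count(B) || B < 19L) abort("`B` must be an integer >= 19.")
  if (missing(seed) || !is_count(seed)) abort("`seed` (integer) is required.")

  seeds <- derive_seeds(seed, 2L + B)
  if (is.null(fit_km1)) {
    fit_km1 <- fit_growth_mixture(panel, K - 1L, control, seed = seeds[1])
  }
  if (is.null(fit_k)) {
    fit_k <- fit_growth_mixture(panel, K, control, seed = seeds[2])
  }
  lr_obs <- 2 * (fit_k$loglik - fit_km1$loglik)
  if (lr_obs < -1e-6) {
    abort(paste0(
      "K-class log-likelihood is below the (K-1)-class one; ",
      "the K-class fit is under-optimized -- increase `n_starts`."
    ))
  }
  lr_obs <- max(lr_obs, 0)

  boot_ctrl <- control
  boot_ctrl$n_starts <- control$boot_n_starts
  boot_ctrl$n_final <- control$boot_n_final
  boot_ctrl$max_iter <- control$boot_max_iter
  boot_ctrl$short_iter <- min(control$short_iter, 15L)

  lr_boot <- vapply(seq_len(B), function(b) {
    sub <- derive_seeds(seeds[2L + b], 3L)
    bpanel <- simulate_from_model(panel, fit_km1$model, seed = sub[1])
    f0 <- refit_quiet(bpanel, K - 1L, boot_ctrl, sub[2], init = fit_km1$model)
    f1 <- refit_quiet(bpanel, K, boot_ctrl, sub[3], init = fit_k$model)
    if (is.null(f0) || is.null(f1)) return(NA_real_)
    max(2 * (f1$loglik - f0$loglik), 0)
  }, numeric(1))
  lr_boot <- lr_boot[!is.na(lr_boot)]
  if (length(lr_boot) < B / 2) {
    abort("Too many bootstrap refits failed; increase starts or reduce K.")
  }
  df <- gmm_n_params(K, control$classwise_psi) -
    gmm_n_params(K - 1L, control$classwise_psi)
  structure(
    list(
      statistic = lr_obs,
      p_value = (1 + sum(lr_boot >= lr_obs)) / (length(lr_boot) + 1),
      lr_boot = lr_boot, B = length(lr_boot), K = as.integer(K),
      df = df, naive_p = stats::pchisq(lr_obs, df, lower.tail = FALSE)
    ),
    class = "trajmix_lrt"
  )
}

#' @export
print.trajmix_lrt <- function(x, ...) {
  cat(sprintf(
    paste0("<trajmix_lrt> %d vs %d classes: LR = %.3f, bootstrap p = %.4g ",
           "(B = %d)\nnaive chi-square p = %.4g ",
           "(df = %d; invalid at the boundary)\n"),
    x$K, x$K - 1L, x$statistic, x$p_value, x$B, x$naive_p, x$df
  ))
  invisible(x)
}

# fit_growth_mixture that converts degenerate failures to NULL and mutes
# non-convergence warnings (bootstrap replicates tolerate both).
refit_quiet <- function(panel, K, control, seed, init = NULL) {
  tryCatch(
    suppressWarnings(
      fit_growth_mixture(panel, K, control, seed = seed, init = init)
    ),
    error = function(e) NULL
  )
}

# Draw a panel with the original panel's shape (years, time scores,
# missingness pattern) from a fitted model. Values are clipped to the
# percent scale the panel contract requires.
simulate_from_model <- function(panel, model, seed) {
  lambda <- panel$time_scores
  n <- nrow(panel$values)
  Tn <- length(lambda)
  withr::with_seed(seed, {
    cls <- sample.int(model$K, n, replace = TRUE, prob = model$weights)
    vals <- matrix(NA_real_, n, Tn)
    for (i in seq_len(n)) {
      psi <- psi_k(model, cls[i])
      b <- drop(crossprod(chol_psd(psi), rnorm(2))) +
        c(model$intercepts[cls[i]], model$slopes[cls[i]])
      vals[i, ] <- b[1] + b[2] * lambda +
        rnorm(Tn, sd = sqrt(model$residual_var))
    }
    vals[panel$missing_mask] <- NA_real_
    vals <- pmin(pmax(vals, 0), 100)
    new_panel(panel$unit_ids, panel$years, vals, panel$time_scores)
  })
}

# Upper Cholesky-like factor valid for singular PSD matrices.
chol_psd <- function(m) {
  ch <- suppressWarnings(tryCatch(chol(m), error = function(e) NULL))
  if (!is.null(ch)) return(ch)
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  t(eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(m)))
}

#' Class enumeration sweep
#'
#' Fits growth mixture models with `K = 1 .. K_max` classes and assembles
#' the fit-index table (log-likelihood, AIC, BIC, SSBIC, entropy, and the
#' bootstrap likelihood-ratio test of each `K` against `K - 1`). The
#' selected `K` is the largest one whose own LRT rejects at level `alpha`
#' while the next test (`K + 1` vs `K`) does not; if no `K >= 2` qualifies
#' the selection falls back to 1 class and is flagged.
#'
#' @param panel A `trajmix_panel`.
#' @param K_max Largest number of classes to consider (`>= 2`).
#' @param control A [gmm_control()] list.
#' @param alpha LRT significance level (default 0.10).
#' @param B Bootstrap replicates per LRT.
#' @param seed Integer seed.
#' @param lrt Run the bootstrap LRTs? When `FALSE` only information
#'   criteria and entropy are tabulated and selection falls back to BIC.
#' @return An object of class `trajmix_enumeration`: a list with `table`
#'   (tibble of fit indices), `selected_K`, `selection_flag`, `alpha`, and
#'   `fits` (the per-K `trajmix_fit` objects).
#' @export
enumerate_classes <- function(panel, K_max = 5L, control = gmm_control(),
                              alpha = 0.10, B = 99L, seed, lrt = TRUE) {
  stopifnot(inherits(panel, "trajmix_panel"))
  if (!is_count(K_max) || K_max < 2L) abort("`K_max` must be an integer >= 2.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (missing(seed) || !is_count(seed)) abort("`seed` (integer) is required.")
  seeds <- derive_seeds(seed, 2L * K_max)

  fits <- vector("list", K_max)
  for (K in seq_len(K_max)) {
    fits[[K]] <- refit_quiet(panel, K, control, seeds[K])
  }

  n <- nrow(panel$values)
  rows <- purrr::map(seq_len(K_max), function(K) {
    f <- fits[[K]]
    if (is.null(f)) {
      return(tibble::tibble(
        K = K, loglik = NA_real_, n_params = gmm_n_params(K, control$classwise_psi),
        AIC = NA_real_, BIC = NA_real_, SSBIC = NA_real_,
        lrt_p = NA_real_, entropy = NA_real_, fit_failed = TRUE
      ))
    }
    ic <- information_criteria(f$loglik, f$n_params, n)
    tibble::tibble(
      K = K, loglik = f$loglik, n_params = f$n_params,
      AIC = ic$AIC, BIC = ic$BIC, SSBIC = ic$SSBIC,
      lrt_p = NA_real_,
      entropy = if (K >= 2L) entropy(f$posteriors) else NA_real_,
      fit_failed = FALSE
    )
  })
  table <- dplyr::bind_rows(rows)

  if (lrt) {
    for (K in 2:K_max) {
      if (is.null(fits[[K]]) || is.null(fits[[K - 1L]])) next
      res <- tryCatch(
        bootstrap_lrt(panel, K, B = B, control = control,
                      seed = seeds[K_max + K],
                      fit_k = fits[[K]], fit_km1 = fits[[K - 1L]]),
        error = function(e) NULL
      )
      if (!is.null(res)) table$lrt_p[K] <- res$p_value
    }
    qual <- which(!is.na(table$lrt_p) & table$lrt_p < alpha)
    qual <- qual[vapply(qual, function(K) {
      K == K_max || is.na(table$lrt_p[K + 1L]) || table$lrt_p[K + 1L] >= alpha
    }, logical(1))]
    if (length(qual)) {
      selected <- max(qual)
      flag <- "lrt"
    } else {
      selected <- 1L
      flag <- "no_K_passed_lrt"
    }
  } else {
    selected <- table$K[which.min(table$BIC)]
    flag <- "bic"
  }

  structure(
    list(table = table, selected_K = as.integer(selected),
         selection_flag = flag, alpha = alpha, fits = fits),
    class = "trajmix_enumeration"
  )
}

#' @export
print.trajmix_enumeration <- function(x, ...) {
  cat(sprintf("<trajmix_enumeration> selected K = %d (%s, alpha = %g)\n",
              x$selected_K, x$selection_flag, x$alpha))
  print(x$table)
  invisible(x)
}

#' @rdname enumerate_classes
#' @param x A `trajmix_enumeration`.
#' @param ... Unused.
#' @export
tidy.trajmix_enumeration <- function(x, ...) x$table

#' Plot an enumeration sweep
#'
#' Information criteria against the number of classes.
#'
#' @param object A `trajmix_enumeration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajmix_enumeration <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$table[c("K", "AIC", "BIC", "SSBIC")],
    -"K", names_to = "criterion", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$K, .data$value,
                                   colour = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_K, linetype = 2) +
    ggplot2::labs(x = "Number of classes", y = "Criterion value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
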