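#' Fit a growth mixture model by multi-start EM
#'
#' Runs `control$n_starts` random-partition initializations for
#' `control$short_iter` EM sweeps each, carries the `control$n_final` best
#' to convergence, and keeps the solution with the highest observed-data
#' log-likelihood. Classes are relabelled canonically (descending
#' intercept). The whole procedure is deterministic given `seed`.
#'
#' @param panel A `trajmix_panel` (or a long data frame coercible with
#'   [as_panel()]).
#' @param K Number of latent classes (`>= 1`).
#' @param control A [gmm_control()] list.
#' @param seed Integer seed driving all initialization randomness.
#' @param init Optional `trajmix_model` (or list of models) used as
#'   additional warm starts alongside the random ones.
#' @return An object of class `trajmix_fit` with elements `model`,
#'   `posteriors`, `loglik`, `loglik_trace`, `converged`, `n_starts_used`,
#'   `seed`, `panel`, and `se` (filled by [standard_errors()]).
#' @examples
#' sim <- simulate_panel(asia_underweight_spec(), seed = 1)
#' fit <- fit_growth_mixture(sim$panel, K = 3, seed = 1)
#' tidy(fit)
#' glance(fit)
#' @export
fit_growth_mixture <- function(panel, K, control = gmm_control(), seed,
                               init = NULL) {
  if (is.data.frame(panel)) panel <- as_panel(panel)
  stopifnot(inherits(panel, "trajmix_panel"))
  if (!is_count(K) || K < 1L) abort("`K` must be a positive integer.")
  n <- nrow(panel$values)
  if (n < K) abort("Need at least as many units as classes.")
  if (missing(seed) || !is_count(seed)) abort("`seed` (integer) is required.")
  if (inherits(init, "trajmix_model")) init <- list(init)

  n_rand <- if (K == 1L) 1L else control$n_starts
  start_seeds <- derive_seeds(seed, n_rand)

  short <- vector("list", n_rand + length(init))
  for (s in seq_len(n_rand)) {
    short[[s]] <- withr::with_seed(start_seeds[s], {
      tryCatch({
        m0 <- init_model(panel, K, control,
                         partition = if (s == 1L) kmeans_partition(panel, K)
                                     else NULL)
        run_em(panel, m0, control, max_iter = control$short_iter)
      }, trajmix_degenerate = function(e) NULL, error = function(e) NULL)
    })
  }
  for (j in seq_along(init)) {
    stopifnot(inherits(init[[j]], "trajmix_model"), init[[j]]$K == K)
    short[[n_rand + j]] <- tryCatch(
      run_em(panel, init[[j]], control, max_iter = control$short_iter),
      trajmix_degenerate = function(e) NULL, error = function(e) NULL
    )
  }
  ok <- !vapply(short, is.null, logical(1))
  if (!any(ok)) {
    abort(sprintf(
      "All %d starts ended with a degenerate class; try a smaller K.",
      length(short)
    ), class = "trajmix_all_degenerate")
  }
  short <- short[ok]
  lls <- vapply(short, `[[`, numeric(1), "loglik")
  keep <- order(lls, decreasing = TRUE)[seq_len(min(control$n_final,
                                                    length(short)))]

  best <- NULL
  for (idx in keep) {
    res <- tryCatch(
      run_em(panel, short[[idx]]$model, control, max_iter = control$max_iter),
      trajmix_degenerate = function(e) NULL, error = function(e) NULL
    )
    if (is.null(res)) next
    res$trace <- c(short[[idx]]$trace, res$trace[-1L])
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best)) {
    abort("All finalist starts ended with a degenerate class; try a smaller K.",
          class = "trajmix_all_degenerate")
  }
  if (!best$converged) {
    warn(sprintf("EM did not converge in %d iterations; best iterate returned.",
                 control$max_iter))
  }

  canon <- canonicalize_model(best$model, best$posteriors)
  structure(
    list(
      model = canon$model, posteriors = canon$posteriors,
      loglik = best$loglik, loglik_trace = best$trace,
      converged = best$converged, n_starts_used = length(short),
      K = as.integer(K), n_params = gmm_n_params(K, control$classwise_psi),
      seed = as.integer(seed), control = control, panel = panel, se = NULL
    ),
    class = "trajmix_fit"
  )
}

# Deterministic quasi-k-means partition on per-unit OLS coefficients, used
# as the first (non-random) start.
kmeans_partition <- function(panel, K) {
  co <- unit_ols(panel)$coefs
  sc <- scale(co)
  sc[, apply(co, 2, function(v) var(v) == 0)] <- 0
  if (K == 1L) return(rep(1L, nrow(co)))
  ord <- order(sc[, 1])
  grp <- integer(nrow(co))
  grp[ord] <- rep(seq_len(K), each = ceiling(nrow(co) / K))[seq_len(nrow(co))]
  cl <- tryCatch(
    stats::kmeans(sc, centers = K, nstart = 1,
                  iter.max = 20)$cluster,
    error = function(e) grp
  )
  cl
}

#' @export
print.trajmix_fit <- function(x, ...) {
  cat(sprintf(
    "<trajmix_fit> %d-class growth mixture; loglik %.3f (%s, %d EM sweeps)\n",
    x$K, x$loglik, if (x$converged) "converged" else "not converged",
    length(x$loglik_trace) - 1L
  ))
  print(tidy(x))
  invisible(x)
}

#' Classify units by modal posterior probability
#'
#' Assigns each unit to its highest-posterior class; an exact tie is broken
#' toward the lowest class index and flagged.
#'
#' @param x A `trajmix_fit` or a posterior matrix.
#' @return A tibble with columns `unit`, `class`, `posterior` (the maximal
#'   posterior probability) and `tie`.
#' @export
classify <- function(x) {
  if (inherits(x, "trajmix_fit")) {
    post <- x$posteriors
    units <- x$panel$unit_ids
  } else {
    post <- as.matrix(x)
    units <- rownames(post) %||% as.character(seq_len(nrow(post)))
  }
  if (any(post < -1e-12 | post > 1 + 1e-12) ||
      any(abs(rowSums(post) - 1) > 1e-8)) {
    abort("`x` must be a posterior matrix with rows summing to 1.")
  }
  cls <- max.col(post, ties.method = "first")
  mx <- post[cbind(seq_len(nrow(post)), cls)]
  tie <- rowSums(abs(post - mx) < 1e-12) > 1L
  tibble::tibble(unit = units, class = cls, posterior = mx, tie = tie)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy per-class estimates of a growth mixture fit
#'
#' @param x A `trajmix_fit`.
#' @param ... Unused.
#' @return A tibble with one row per class: `class`, `n` (modal count),
#'   `weight`, `intercept`, `intercept_se`, `slope`, `slope_se` (SE columns
#'   are `NA` until [standard_errors()] has been run).
#' @export
tidy.trajmix_fit <- function(x, ...) {
  counts <- tabulate(classify(x)$class, x$K)
  out <- tibble::tibble(
    class = seq_len(x$K), n = counts, weight = x$model$weights,
    intercept = x$model$intercepts,
    intercept_se = NA_real_,
    slope = x$model$slopes,
    slope_se = NA_real_
  )
  if (!is.null(x$se)) {
    out$intercept_se <- x$se$intercept_se
    out$slope_se <- x$se$slope_se
  }
  out
}

#' One-row summary of a growth mixture fit
#'
#' @param x A `trajmix_fit`.
#' @param ... Unused.
#' @return A tibble with `K`, `loglik`, `n_params`, `AIC`, `BIC`, `SSBIC`,
#'   `entropy` (`NA` for `K = 1`), `converged`, `n_iter`.
#' @export
glance.trajmix_fit <- function(x, ...) {
  ic <- information_criteria(x$loglik, x$n_params, nrow(x$panel$values))
  tibble::tibble(
    K = x$K, loglik = x$loglik, n_params = x$n_params,
    AIC = ic$AIC, BIC = ic$BIC, SSBIC = ic$SSBIC,
    entropy = if (x$K >= 2L) entropy(x$posteriors) else NA_real_,
    converged = x$converged, n_iter = length(x$loglik_trace) - 1L
  )
}

#' Per-unit classification details
#'
#' @param x A `trajmix_fit`.
#' @param ... Unused.
#' @return A tibble with one row per unit: modal class, maximal posterior,
#'   tie flag, and one posterior column per class.
#' @export
augment.trajmix_fit <- function(x, ...) {
  out <- classify(x)
  post <- tibble::as_tibble(x$posteriors,
                            .name_repair = ~ paste0("p_class", seq_len(x$K)))
  dplyr::bind_cols(out, post)
}

#' Fitted class trajectories
#'
#' Evaluates each class's mean line at the panel years.
#'
#' @param fit A `trajmix_fit`.
#' @return A tibble with columns `class`, `year`, `time_score`, `fitted`.
#' @export
class_trajectories <- function(fit) {
  stopifnot(inherits(fit, "trajmix_fit"))
  tidyr::expand_grid(
    class = seq_len(fit$K),
    tibble::tibble(year = fit$panel$years, time_score = fit$panel$time_scores)
  ) |>
    dplyr::mutate(fitted = fit$model$intercepts[.data$class] +
                    fit$model$slopes[.data$class] * .data$time_score)
}

#' Plot a growth mixture fit
#'
#' Observed trajectories coloured by modal class, overlaid with the
#' estimated class mean lines.
#'
#' @param object A `trajmix_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajmix_fit <- function(object, ...) {
  memb <- classify(object)
  df <- panel_data(object$panel, drop_missing = TRUE) |>
    dplyr::left_join(memb[c("unit", "class")], by = "unit") |>
    dplyr::mutate(class = factor(.data$class))
  lines <- class_trajectories(object) |>
    dplyr::mutate(class = factor(.data$class))
  ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$value,
                                   colour = .data$class)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$unit), alpha = 0.35) +
    ggplot2::geom_line(data = lines, ggplot2::aes(y = .data$fitted),
                       linewidth = 1.2) +
    ggplot2::labs(x = "Year", y = "Prevalence (%)", colour = "Class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
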