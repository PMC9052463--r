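#' Specify a synthetic panel-generating truth
#'
#' Defines the generating parameters of a synthetic longitudinal panel:
#' fixed per-class unit counts, per-class mean intercepts (percent at the
#' first year) and slopes (percent per year), a shared growth-factor
#' covariance, an occasion residual SD, the calendar years, and an
#' optional missingness rate.
#'
#' @param class_sizes Positive integers, units per class (fixed, not
#'   sampled).
#' @param intercept_means,slope_means Per-class generating means.
#' @param growth_cov 2x2 positive semi-definite growth-factor covariance.
#' @param residual_sd Occasion residual standard deviation, `>= 0`.
#' @param years Integer calendar years of the panel.
#' @param missing_rate Probability a cell is missing, in `[0, 1)`.
#' @return An object of class `trajmix_spec`.
#' @export
sim_spec <- function(class_sizes, intercept_means, slope_means,
                     growth_cov = diag(c(9, 0.01)), residual_sd = 2,
                     years = 1987:2016, missing_rate = 0) {
  K <- length(class_sizes)
  if (K < 1L) abort("Need at least one class.")
  if (length(intercept_means) != K || length(slope_means) != K) {
    abort("Mean vectors must match `class_sizes` in length.")
  }
  if (any(class_sizes < 1L) || any(class_sizes != round(class_sizes))) {
    abort("`class_sizes` must be positive integers.")
  }
  check_psd(growth_cov)
  if (!is.numeric(residual_sd) || length(residual_sd) != 1L ||
      residual_sd < 0) {
    abort("`residual_sd` must be a single nonnegative number.")
  }
  if (is.unsorted(years, strictly = TRUE) || any(years != round(years))) {
    abort("`years` must be strictly increasing integers.")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1).")
  }
  structure(
    list(
      class_sizes = as.integer(class_sizes),
      intercept_means = as.numeric(intercept_means),
      slope_means = as.numeric(slope_means),
      growth_cov = growth_cov, residual_sd = as.numeric(residual_sd),
      years = as.integer(years),
      time_scores = as.numeric(years - years[1]),
      missing_rate = missing_rate
    ),
    class = "trajmix_spec"
  )
}

#' @export
print.trajmix_spec <- function(x, ...) {
  cat(sprintf(
    "<trajmix_spec> %d units in %d classes (%s), years %d-%d\n",
    sum(x$class_sizes), length(x$class_sizes),
    paste(x$class_sizes, collapse = "/"), min(x$years), max(x$years)
  ))
  invisible(x)
}

#' Built-in three-class under-five underweight scenario
#'
#' The package's reference scenario: 39 units observed annually over
#' 1987-2016, drawn from three latent linear-trend classes with sizes
#' 10/20/9, intercepts 32.73/10.76/54.26 percent and slopes
#' -0.64/-0.29/-0.93 percent per year -- the configuration of the
#' published three-class clustering of Asian countries' under-five
#' underweight prevalence that this package is designed to reproduce on
#' synthetic data. The variance components are chosen, not published:
#' growth-factor covariance `diag(9, 0.01)` (intercept SD 3, slope SD 0.1,
#' no covariance) and residual SD 2, which place the classes many residual
#' SDs apart and make classification near-deterministic.
#'
#' @param ... Overrides passed to [sim_spec()] (e.g. `missing_rate`).
#' @return A `trajmix_spec`.
#' @examples
#' asia_underweight_spec()
#' asia_underweight_spec(missing_rate = 0.05)
#' @export
asia_underweight_spec <- function(...) {
  defaults <- list(
    class_sizes = c(10L, 20L, 9L),
    intercept_means = c(32.73, 10.76, 54.26),
    slope_means = c(-0.64, -0.29, -0.93),
    growth_cov = diag(c(9, 0.01)),
    residual_sd = 2,
    years = 1987:2016,
    missing_rate = 0
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown override `%s`.", unknown[1]))
  }
  do.call(sim_spec, utils::modifyList(defaults, overrides))
}

#' Generate a synthetic panel from a generating spec
#'
#' Runs the growth model forward: for each unit of class k, draws growth
#' factors from a bivariate normal around the class means, evaluates the
#' unit's line at the time scores, and adds independent occasion noise.
#' Values are clipped to the `[0, 100]` percent scale (clips are counted);
#' missing cells are drawn independently at `missing_rate` but never push a
#' unit below 2 observations.
#'
#' @param spec A [sim_spec()] object.
#' @param seed Integer seed; the output is a deterministic function of
#'   `(spec, seed)`.
#' @return A list of class `trajmix_sim`: `panel` (a `trajmix_panel`),
#'   `membership` (tibble `unit`, `class`), `growth_factors` (tibble
#'   `unit`, `class`, `intercept`, `slope`), and `n_clipped`.
#' @examples
#' sim <- simulate_panel(asia_underweight_spec(), seed = 42)
#' sim$panel
#' dplyr::count(sim$membership, class)
#' @export
simulate_panel <- function(spec, seed) {
  stopifnot(inherits(spec, "trajmix_spec"))
  if (missing(seed) || !is_count(seed)) abort("`seed` (integer) is required.")
  n <- sum(spec$class_sizes)
  K <- length(spec$class_sizes)
  Tn <- length(spec$years)
  cls <- rep(seq_len(K), times = spec$class_sizes)
  units <- sprintf("unit%02d", seq_len(n))

  withr::with_seed(seed, {
    ch <- chol_psd(spec$growth_cov)
    eps <- matrix(rnorm(2L * n), 2L, n)
    b <- t(crossprod(ch, eps)) +
      cbind(spec$intercept_means[cls], spec$slope_means[cls])
    raw <- b[, 1] + outer(b[, 2], spec$time_scores) +
      matrix(rnorm(n * Tn, sd = spec$residual_sd), n, Tn)
    n_clipped <- sum(raw < 0 | raw > 100)
    vals <- pmin(pmax(raw, 0), 100)
    if (spec$missing_rate > 0) {
      drop <- matrix(runif(n * Tn) < spec$missing_rate, n, Tn)
      # never delete below 2 observations per unit
      for (i in which(rowSums(!drop) < 2L)) {
        keep <- sample.int(Tn, 2L)
        drop[i, keep] <- FALSE
      }
      vals[drop] <- NA_real_
    }
    panel <- new_panel(units, spec$years, vals, spec$time_scores)
  })

  structure(
    list(
      panel = panel,
      membership = tibble::tibble(unit = units, class = cls),
      growth_factors = tibble::tibble(
        unit = units, class = cls, intercept = b[, 1], slope = b[, 2]
      ),
      n_clipped = n_clipped,
      spec = spec, seed = as.integer(seed)
    ),
    class = "trajmix_sim"
  )
}

#' @export
print.trajmix_sim <- function(x, ...) {
  cat(sprintf("<trajmix_sim> seed %d, %d clipped cell(s)\n",
              x$seed, x$n_clipped))
  print(x$panel)
  invisible(x)
}

#' Match estimated classes to generating classes
#'
#' Mixture class labels are arbitrary; recovery checks need the
#' permutation of estimated classes that best matches the generating ones.
#' The permutation minimizing the total squared distance between
#' (intercept, slope) pairs is found by exhaustive search over all `K!`
#' candidates; an exact tie between two permutations is an error (the test
#' configuration is degenerate).
#'
#' @param true_params,est_params K x 2 matrices (or data frames) of
#'   (intercept, slope) per class.
#' @return An integer permutation `perm` such that estimated class
#'   `perm[k]` corresponds to generating class `k`.
#' @examples
#' truth <- cbind(c(30, 10), c(-0.5, -0.2))
#' est <- truth[2:1, ]
#' match_classes(truth, est)
#' @export
match_classes <- function(true_params, est_params) {
  tp <- as.matrix(true_params)
  ep <- as.matrix(est_params)
  K <- nrow(tp)
  if (nrow(ep) != K || ncol(tp) != ncol(ep)) {
    abort("Parameter matrices must have equal dimensions.")
  }
  if (K > 8L) abort("Exhaustive matching supports K <= 8.")
  perms <- all_permutations(K)
  cost <- vapply(perms, function(p) sum((tp - ep[p, , drop = FALSE])^2),
                 numeric(1))
  best <- which(cost <= min(cost) + 1e-12)
  if (length(best) > 1L) {
    abort("Two class permutations match equally well; configuration is degenerate.")
  }
  perms[[best]]
}

all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- all_permutations(K - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(K)) {
      out[[length(out) + 1L]] <- append(p, K, after = pos - 1L)
    }
  }
  out
}
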