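#' Specify a growth mixture model
#'
#' A K-class growth mixture model for linear trajectories. Each latent
#' class k has a mean intercept (level at time score 0) and mean slope
#' (change per unit time score); units deviate from their class line
#' through bivariate-normal random growth factors with covariance matrix
#' `growth_cov`, and each occasion adds independent normal noise with
#' variance `residual_var`. By default the growth-factor covariance and the
#' residual variance are shared across classes; set `classwise_psi = TRUE`
#' (and supply a list of matrices) to free the growth-factor covariance
#' per class.
#'
#' @param weights Class proportions, positive, summing to 1.
#' @param intercepts,slopes Per-class growth-factor means (percent and
#'   percent per unit time score).
#' @param growth_cov 2x2 positive semi-definite covariance of the random
#'   intercept and slope, or a list of K such matrices when
#'   `classwise_psi = TRUE`.
#' @param residual_var Occasion-level residual variance, `> 0`.
#' @param classwise_psi Is `growth_cov` class-specific?
#' @return An object of class `trajmix_model`.
#' @examples
#' gmm_model(
#'   weights = c(0.5, 0.5), intercepts = c(30, 10), slopes = c(-0.5, -0.2),
#'   growth_cov = diag(c(9, 0.01)), residual_var = 4
#' )
#' @export
gmm_model <- function(weights, intercepts, slopes, growth_cov, residual_var,
                      classwise_psi = FALSE) {
  K <- length(weights)
  if (K < 1L) abort("Need at least one class.")
  if (length(intercepts) != K || length(slopes) != K) {
    abort("`intercepts` and `slopes` must have one entry per class.")
  }
  if (any(weights <= 0)) abort("Class weights must be positive.")
  if (abs(sum(weights) - 1) > 1e-10) abort("Class weights must sum to 1.")
  if (!all(is.finite(c(intercepts, slopes)))) {
    abort("Class means must be finite.")
  }
  if (classwise_psi) {
    if (!is.list(growth_cov) || length(growth_cov) != K) {
      abort("With `classwise_psi`, `growth_cov` must be a list of K matrices.")
    }
    purrr::walk(growth_cov, check_psd)
  } else {
    check_psd(growth_cov)
  }
  if (!is.numeric(residual_var) || length(residual_var) != 1L ||
      residual_var <= 0) {
    abort("`residual_var` must be a single positive number.")
  }
  structure(
    list(
      K = as.integer(K), weights = as.numeric(weights),
      intercepts = as.numeric(intercepts), slopes = as.numeric(slopes),
      growth_cov = growth_cov, residual_var = as.numeric(residual_var),
      classwise_psi = isTRUE(classwise_psi)
    ),
    class = "trajmix_model"
  )
}

# Unvalidated constructor for hot paths (the EM updates produce valid
# parameters by construction).
new_gmm_model <- function(weights, intercepts, slopes, growth_cov,
                          residual_var, classwise_psi) {
  structure(
    list(
      K = length(weights), weights = as.numeric(weights),
      intercepts = as.numeric(intercepts), slopes = as.numeric(slopes),
      growth_cov = growth_cov, residual_var = residual_var,
      classwise_psi = classwise_psi
    ),
    class = "trajmix_model"
  )
}

# growth_cov of class k regardless of sharing.
psi_k <- function(model, k) {
  if (model$classwise_psi) model$growth_cov[[k]] else model$growth_cov
}

# Reorder classes by descending intercept so labels are canonical: class 1
# is the highest-level class at time score 0.
canonicalize_model <- function(model, posteriors = NULL) {
  ord <- order(model$intercepts, decreasing = TRUE)
  model$weights <- model$weights[ord]
  model$intercepts <- model$intercepts[ord]
  model$slopes <- model$slopes[ord]
  if (model$classwise_psi) model$growth_cov <- model$growth_cov[ord]
  if (is.null(posteriors)) return(list(model = model, order = ord))
  list(model = model, posteriors = posteriors[, ord, drop = FALSE], order = ord)
}

#' @export
print.trajmix_model <- function(x, ...) {
  cat(sprintf("<trajmix_model> %d-class linear growth mixture\n", x$K))
  print(tibble::tibble(
    class = seq_len(x$K), weight = x$weights,
    intercept = x$intercepts, slope = x$slopes
  ))
  cat(sprintf("residual_var = %.4g; growth_cov %s\n", x$residual_var,
              if (x$classwise_psi) "class-specific" else "shared"))
  invisible(x)
}

#' Number of free parameters of a growth mixture model
#'
#' Counts 2K growth-factor means, K - 1 free class weights, the
#' growth-factor covariance (3 entries per covariance matrix, shared or
#' per class) and one residual variance.
#'
#' @param K Number of classes.
#' @param classwise_psi Class-specific growth-factor covariance?
#' @return Integer parameter count.
#' @export
gmm_n_params <- function(K, classwise_psi = FALSE) {
  K <- as.integer(K)
  2L * K + (K - 1L) + (if (classwise_psi) 3L * K else 3L) + 1L
}
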