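test_that("single-class fit matches an independent direct maximizer", {
  spec <- sim_spec(class_sizes = 12L, intercept_means = 40,
                   slope_means = -0.5, growth_cov = diag(c(4, 0.04)),
                   residual_sd = 1.5, years = 2000:2007)
  pan <- simulate_panel(spec, seed = 9)$panel
  fit <- fit_growth_mixture(pan, K = 1, seed = 10)

  # independent route: BFGS on the brute-force marginal likelihood over
  # (a0, a1, chol(psi), log theta)
  obj <- function(par) {
    ch <- matrix(c(exp(par[3]), 0, par[4], exp(par[5])), 2, 2)
    psi <- crossprod(ch)
    theta <- exp(par[6])
    -sum(sapply(seq_len(nrow(pan$values)), function(i) {
      mom <- bf_implied_moments(par[1], par[2], psi, theta, pan$time_scores)
      bf_mvn_loglik(pan$values[i, ], mom$mean, mom$cov)
    }))
  }
  ols <- trajmix:::unit_ols(pan)
  start <- c(mean(ols$coefs[, 1]), mean(ols$coefs[, 2]),
             log(sd(ols$coefs[, 1])), 0, log(max(sd(ols$coefs[, 2]), 0.05)),
             log(1))
  opt <- optim(start, obj, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 5000))
  expect_equal(fit$model$intercepts, opt$par[1], tolerance = 1e-6)
  expect_equal(fit$model$slopes, opt$par[2], tolerance = 1e-6)
  expect_equal(fit$loglik, -opt$value, tolerance = 1e-7)
})

test_that("fitting twice with the same seed is bit-identical", {
  sim <- simulate_panel(asia_underweight_spec(), seed = 6)
  f1 <- fit_growth_mixture(sim$panel, K = 3, seed = 7)
  f2 <- fit_growth_mixture(sim$panel, K = 3, seed = 7)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$posteriors, f2$posteriors)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
})

test_that("rescaling the panel rescales means and leaves posteriors alone", {
  sim <- simulate_panel(asia_underweight_spec(), seed = 12)
  f1 <- fit_growth_mixture(sim$panel, K = 3, seed = 13)
  c0 <- 0.5
  pan2 <- trajmix:::new_panel(sim$panel$unit_ids, sim$panel$years,
                              sim$panel$values * c0, sim$panel$time_scores)
  f2 <- fit_growth_mixture(pan2, K = 3, seed = 13)
  expect_equal(f2$model$intercepts, c0 * f1$model$intercepts,
               tolerance = 1e-4)
  expect_equal(f2$model$slopes, c0 * f1$model$slopes, tolerance = 1e-4)
  expect_equal(f2$posteriors, f1$posteriors, tolerance = 1e-6)
})

test_that("permuting unit rows permutes posteriors and not the model", {
  sim <- simulate_panel(asia_underweight_spec(), seed = 14)
  pan <- sim$panel
  f1 <- fit_growth_mixture(pan, K = 3, seed = 15)
  perm <- withr::with_seed(2, sample(nrow(pan$values)))
  pan2 <- trajmix:::new_panel(pan$unit_ids[perm], pan$years,
                              pan$values[perm, ], pan$time_scores)
  f2 <- fit_growth_mixture(pan2, K = 3, seed = 16)
  expect_equal(f2$model$intercepts, f1$model$intercepts, tolerance = 1e-6)
  expect_equal(f2$model$slopes, f1$model$slopes, tolerance = 1e-6)
  expect_equal(unname(f2$posteriors), unname(f1$posteriors[perm, ]),
               tolerance = 1e-6)
})

test_that("modal classification follows the stated argmax and tie rules", {
  post <- rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0))
  cl <- classify(post)
  expect_equal(cl$class, c(2L, 1L))
  expect_equal(cl$posterior, c(0.7, 0.5))
  expect_equal(cl$tie, c(FALSE, TRUE))
})

test_that("classification recovers the generating memberships", {
  sim <- simulate_panel(asia_underweight_spec(), seed = 17)
  fit <- fit_growth_mixture(sim$panel, K = 3, seed = 18)
  truth <- cbind(sim$spec$intercept_means, sim$spec$slope_means)
  est <- cbind(fit$model$intercepts, fit$model$slopes)
  perm <- match_classes(truth, est)
  mapped <- match(classify(fit)$class, perm)
  expect_gte(sum(mapped == sim$membership$class), 38)
})

test_that("tidy, glance and augment expose the fit in tabular form", {
  sim <- simulate_panel(asia_underweight_spec(), seed = 19)
  fit <- fit_growth_mixture(sim$panel, K = 3, seed = 20)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$n), 39)
  expect_equal(sum(td$weight), 1, tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$K, 3L)
  expect_true(gl$entropy > 0.9)
  au <- augment(fit)
  expect_equal(nrow(au), 39)
  expect_equal(rowSums(as.matrix(au[paste0("p_class", 1:3)])),
               rep(1, 39), tolerance = 1e-10)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("freeing the growth covariance per class nests the shared fit", {
  spec <- sim_spec(class_sizes = c(10L, 10L), intercept_means = c(20, 60),
                   slope_means = c(-0.2, -0.8), growth_cov = diag(c(4, 0.02)),
                   residual_sd = 1.5, years = 2000:2011)
  pan <- simulate_panel(spec, seed = 23)$panel
  ctrl_shared <- gmm_control(n_starts = 10, n_final = 3)
  ctrl_free <- gmm_control(n_starts = 10, n_final = 3, classwise_psi = TRUE)
  f_shared <- fit_growth_mixture(pan, K = 2, ctrl_shared, seed = 24)
  f_free <- suppressWarnings(fit_growth_mixture(pan, K = 2, ctrl_free,
                                                seed = 24))
  expect_true(f_free$model$classwise_psi)
  expect_length(f_free$model$growth_cov, 2)
  expect_equal(f_free$n_params, 6L * 2L)
  expect_equal(f_shared$n_params, 3L * 2L + 3L)
  # the richer model can only improve the maximized likelihood
  expect_gte(f_free$loglik, f_shared$loglik - 1e-6)
  expect_true(all(diff(f_free$loglik_trace) >= -1e-8))
})

test_that("overly ambitious K on tiny separated data fails with advice", {
  spec <- sim_spec(class_sizes = c(3L, 3L), intercept_means = c(20, 80),
                   slope_means = c(0, 0), growth_cov = matrix(0, 2, 2),
                   residual_sd = 0.5, years = 2000:2004)
  pan <- simulate_panel(spec, seed = 21)$panel
  expect_error(
    fit_growth_mixture(pan, K = 6, gmm_control(n_starts = 5, n_final = 2),
                       seed = 22),
    "smaller K"
  )
})
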