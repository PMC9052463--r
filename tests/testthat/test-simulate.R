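test_that("the reference scenario carries the published class structure", {
  spec <- asia_underweight_spec()
  expect_equal(spec$class_sizes, c(10L, 20L, 9L))
  expect_equal(sum(spec$class_sizes), 39L)
  expect_equal(spec$intercept_means, c(32.73, 10.76, 54.26))
  expect_equal(spec$slope_means, c(-0.64, -0.29, -0.93))
  expect_equal(spec$years, 1987:2016)
  expect_equal(spec$time_scores, 0:29)

  two <- asia_underweight_spec(class_sizes = c(5L, 5L),
                               intercept_means = c(30, 10),
                               slope_means = c(-0.5, -0.2))
  expect_equal(sum(two$class_sizes), 10L)

  expect_error(asia_underweight_spec(residual_sd = -1), "nonnegative")
  expect_error(asia_underweight_spec(nonsense = 1), "Unknown")
  expect_error(sim_spec(c(2L, 2L), c(1, 2), c(0, 0),
                        growth_cov = matrix(c(1, 2, 2, 1), 2, 2)),
               "positive semi-definite")
})

test_that("the noise-free limit reproduces exact class lines", {
  spec <- asia_underweight_spec(growth_cov = matrix(0, 2, 2), residual_sd = 0)
  sim <- simulate_panel(spec, seed = 40)
  for (k in 1:3) {
    rows <- which(sim$membership$class == k)
    line <- spec$intercept_means[k] + spec$slope_means[k] * spec$time_scores
    for (i in rows) {
      expect_equal(unname(sim$panel$values[i, ]), line)
    }
  }
  expect_equal(sim$n_clipped, 0L)
})

test_that("generation is deterministic and respects panel invariants", {
  s1 <- simulate_panel(asia_underweight_spec(missing_rate = 0.1), seed = 41)
  s2 <- simulate_panel(asia_underweight_spec(missing_rate = 0.1), seed = 41)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$growth_factors, s2$growth_factors)

  pan <- s1$panel
  expect_true(all(pan$values[!pan$missing_mask] >= 0))
  expect_true(all(pan$values[!pan$missing_mask] <= 100))
  expect_true(all(rowSums(!pan$missing_mask) >= 2))
  expect_equal(as.integer(table(s1$membership$class)), c(10L, 20L, 9L))
})

test_that("per-class OLS slopes concentrate on the generating slopes", {
  # intercepts shifted off the 0% floor so no trajectory clips and the
  # generator is exactly the linear model it advertises
  spec <- asia_underweight_spec(class_sizes = c(200L, 200L, 200L),
                                intercept_means = c(52.73, 30.76, 74.26))
  sim <- simulate_panel(spec, seed = 42)
  ols <- trajmix:::unit_ols(sim$panel)
  for (k in 1:3) {
    rows <- which(sim$membership$class == k)
    m <- mean(ols$coefs[rows, 2])
    se <- sd(ols$coefs[rows, 2]) / sqrt(length(rows))
    expect_lt(abs(m - spec$slope_means[k]), 3 * se)
  }
})

test_that("reference classes are separated far beyond the residual noise", {
  spec <- asia_underweight_spec()
  gaps <- abs(outer(spec$intercept_means, spec$intercept_means, `-`))
  gaps <- gaps[upper.tri(gaps)]
  expect_true(all(gaps > 5 * spec$residual_sd))
})

test_that("clipping at the prevalence floor stays rare and is reported", {
  rates <- sapply(1:10, function(s) {
    sim <- simulate_panel(asia_underweight_spec(), seed = 100 + s)
    sim$n_clipped / length(sim$panel$values)
  })
  # the low-prevalence class brushes the 0% floor late in the panel, so a
  # few percent of cells clip; the count is surfaced for every draw
  expect_true(all(rates < 0.10))
  expect_true(all(rates > 0))
})

test_that("class matching finds the brute-force optimal permutation", {
  truth <- cbind(c(30, 10), c(-0.5, -0.2))
  expect_equal(match_classes(truth, truth[2:1, ]), c(2L, 1L))
  expect_equal(match_classes(truth[1, , drop = FALSE],
                             truth[1, , drop = FALSE]), 1L)

  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  withr::with_seed(43, {
    for (r in 1:10) {
      tp <- cbind(runif(3, 0, 60), runif(3, -1, 0))
      ep <- tp[sample(3), ] + matrix(rnorm(6, sd = 0.05), 3, 2)
      got <- match_classes(tp, ep)
      costs <- sapply(perms3, function(p) sum((tp - ep[p, ])^2))
      expect_equal(unname(got), perms3[[which.min(costs)]])
    }
  })

  expect_error(match_classes(cbind(c(1, 1), c(2, 2)),
                             cbind(c(0, 2), c(2, 2))), "degenerate")
})
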