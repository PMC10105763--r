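test_that("fit_line recovers exact lines and matches the normal equations", {
  x <- seq(0.1, 1.2, length.out = 20)
  f <- fit_line(x, 0.206 + 0.870 * x)
  expect_equal(f$slope, 0.870, tolerance = 1e-12)
  expect_equal(f$intercept, 0.206, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  f2 <- fit_line(1:10, 1:10)
  expect_equal(unname(c(f2$slope, f2$intercept)), c(1, 0), tolerance = 1e-12)

  set.seed(8)
  x <- rnorm(50)
  y <- 0.3 + 0.9 * x + rnorm(50, sd = 0.2)
  f3 <- fit_line(x, y)
  # independent normal-equation solve
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f3$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f3$slope, beta[2], tolerance = 1e-10)
  expect_true(f3$r_squared >= 0 && f3$r_squared <= 1)

  expect_error(fit_line(rep(2, 5), 1:5), "constant")
  expect_error(fit_line(1:2, 1:2), "at least 3")
})

test_that("regression tidiers expose broom-shaped summaries", {
  f <- fit_line(1:10, 2 + 3 * (1:10))
  td <- generics::tidy(f)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate, c(2, 3), tolerance = 1e-10)
  gl <- generics::glance(f)
  expect_named(gl, c("slope", "intercept", "r_squared", "residual_sd", "n"))
  expect_equal(gl$n, 10)
})

test_that("coefficient of variation is 100 sd over mean and scale free", {
  expect_equal(coefficient_of_variation(c(10, 10, 10)), 0)
  expect_equal(coefficient_of_variation(c(8, 12)), 100 * sqrt(8) / 10,
               tolerance = 1e-12)
  v <- c(3, 5, 9, 4)
  expect_equal(coefficient_of_variation(7 * v), coefficient_of_variation(v),
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(-5, 3)), "positive")
  expect_error(coefficient_of_variation(4), "at least 2")
})

test_that("noise-free replicates show no method difference", {
  spec <- phantom_spec(30, 30, regions = list(region_background(30, 0)))
  bx <- bias_experiment(spec, rb_rect(c(1, 1), 30, 30),
                        params = slic_params(S = 8), n_replicates = 2,
                        seed = 5)
  expect_true(all(abs(bx$replicates$diff) < 1e-9))
  expect_equal(bx$p_value, 1)
})

test_that("a small noisy bias experiment is positive, deterministic and
           tidyable", {
  spec <- phantom_spec(60, 60, regions = list(region_background(30, 0)),
                       noise_shape = 50)
  run <- function() bias_experiment(spec, rb_rect(c(1, 1), 60, 60),
                                    params = slic_params(S = 8),
                                    n_replicates = 6, seed = 17)
  bx <- run()
  expect_gt(bx$mean_diff, 0)
  expect_true(all(bx$replicates$diff > 0))
  bx2 <- run()
  expect_identical(bx$replicates, bx2$replicates)
  td <- generics::tidy(bx)
  expect_named(td, c("replicate", "bom_rb", "bom_sp", "diff"))
  gl <- generics::glance(bx)
  expect_true(is.finite(gl$cov_rb) && is.finite(gl$cov_sp))
  expect_error(bias_experiment(spec, rb_rect(c(1, 1), 5, 5),
                               n_replicates = 2, seed = 1),
               "smaller than one superpixel")
})

test_that("spatial mean variance follows the 1/n law", {
  spec <- phantom_spec(60, 60, regions = list(region_background(30, 0)),
                       noise_shape = 50, seed = 2)
  frame <- generate_sequence(spec)$values[, , 1]
  tab <- spatial_mean_convergence(frame, c(1, 100, 400), n_draws = 400,
                                  seed = 6)
  expect_equal(tab$n, c(1, 100, 400))
  expect_true(all(diff(tab$var_mean) < 0))
  # n = 1 reproduces the single-pixel variance
  expect_lt(abs(tab$var_mean[tab$n == 1] / var(as.vector(frame)) - 1), 0.3)
  r <- tab$var_mean[tab$n == 400] / tab$var_mean[tab$n == 100]
  expect_lt(abs(r / 0.25 - 1), 0.3)
  tab2 <- spatial_mean_convergence(frame, c(1, 100, 400), n_draws = 400,
                                   seed = 6)
  expect_identical(tab, tab2)
  expect_error(spatial_mean_convergence(frame, 10000), "pixel count")
})
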