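test_that("noise-free, zero-D data degenerates to OLS and zero BLUPs", {
  spec <- small_spec(I = 6, J = 2, sigma_eps = 0, D_scale = 0)
  sim <- simulate_dataset(spec, seed = 3)
  des <- build_design(sim$data, quad_basis())
  y <- response_matrix(sim$data)[, 1]

  fit <- fit_univariate(y, des)
  ols <- qr.solve(des$X, y)
  expect_equal(fit$beta, ols, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$beta, spec$beta_tilde[1, ], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(max(abs(fit$gamma)), 1e-6)
  expect_lt(fit$sigma2_eps, 1e-12)
})

test_that("fit reconstruction is exact and flags are populated", {
  sim <- simulate_dataset(small_spec(), seed = 5)
  des <- build_design(sim$data, quad_basis())
  y <- response_matrix(sim$data)[, 2]
  fit <- fit_univariate(y, des)

  recon <- fit$fitted_fixed + fit$fitted_random + fit$residuals
  expect_equal(recon, y, tolerance = 1e-12)
  expect_true(isSymmetric(unname(fit$D_hat), tol = 1e-10))
  expect_gte(min(eigen(fit$D_hat, only.values = TRUE)$values), -1e-10)
  expect_gte(fit$sigma2_eps, 0)
  expect_type(fit$converged, "logical")
  expect_type(fit$singular, "logical")
  expect_equal(dim(fit$gamma), c(8, 5))
})

test_that("missing cells are excluded from the fit but predicted", {
  sim <- simulate_dataset(small_spec(I = 10), seed = 6)
  des <- build_design(sim$data, quad_basis())
  y <- response_matrix(sim$data)[, 1]
  y_miss <- y
  y_miss[c(4, 17, 50)] <- NA
  fit <- fit_univariate(y_miss, des)
  expect_equal(fit$n_obs, length(y) - 3)
  # predictions exist for all design rows; residuals missing where y is
  expect_false(anyNA(fit$fitted_fixed + fit$fitted_random))
  expect_equal(which(is.na(fit$residuals)), c(4L, 17L, 50L),
               ignore_attr = TRUE)
  expect_error(fit_univariate(rep(NA_real_, nrow(des$X)), des),
               "entirely missing")
})

test_that("residual variance is consistently estimated at large I", {
  # generating sigma2 = 1; REML at I = 200 should land within 20%
  spec <- simulation_spec(I = 200, H = 2, K = 11, J = 1, t = 0:10,
                          beta_tilde = matrix(c(5, 0.5, -0.05, 0.2, -0.02), 1),
                          D_tilde = {
                            sdv <- c(0.5, 0.05, 0.01, 0.03, 0.005)
                            cr <- matrix(0.2, 5, 5); diag(cr) <- 1
                            outer(sdv, sdv) * cr
                          },
                          sigma_eps = 1)
  sim <- simulate_dataset(spec, seed = 7)
  des <- build_design(sim$data, quad_basis())
  fit <- fit_univariate(response_matrix(sim$data)[, 1], des)
  expect_gt(fit$sigma2_eps, 0.8)
  expect_lt(fit$sigma2_eps, 1.2)
})

test_that("fit_all assembles B and Gamma consistently with single fits", {
  sim <- simulate_dataset(small_spec(J = 3), seed = 8)
  des <- build_design(sim$data, quad_basis())
  mfit <- fit_all(sim$data, des)

  expect_equal(dim(mfit$B), c(5, 3))
  expect_equal(dim(mfit$Gamma), c(8 * 5, 3))
  for (j in 1:3)
    expect_equal(mfit$B[, j], mfit$per_variable[[j]]$beta,
                 ignore_attr = TRUE)
  # Gamma stacks subject-major q-blocks
  g2 <- mfit$per_variable[[2]]$gamma
  expect_equal(mfit$Gamma[, 2], as.vector(t(g2)), ignore_attr = TRUE)

  # a column fitted alone matches its fit inside fit_all (cold start)
  solo <- fit_univariate(response_matrix(sim$data)[, 1], des)
  expect_equal(solo$beta, mfit$per_variable[[1]]$beta, tolerance = 1e-8)
  expect_equal(solo$sigma2_eps, mfit$per_variable[[1]]$sigma2_eps,
               tolerance = 1e-6)

  # J = 1 wraps exactly one univariate fit
  sim1 <- simulate_dataset(small_spec(J = 1), seed = 9)
  des1 <- build_design(sim1$data, quad_basis())
  m1 <- fit_all(sim1$data, des1)
  expect_length(m1$per_variable, 1)
  expect_equal(dim(m1$B), c(5, 1))
})

test_that("estimates are invariant to input row permutation", {
  df <- make_grid_df(I = 6, H = 2, K = 5, J = 1, seed = 11)
  set.seed(12)
  df$met01 <- df$met01 + 0.3 * df$time
  ld_a <- long_dataset(df, "subject", "treatment", "time")
  ld_b <- long_dataset(df[sample(nrow(df)), ], "subject", "treatment", "time")
  f_a <- fit_univariate(ld_a$met01, build_design(ld_a, quad_basis()))
  f_b <- fit_univariate(ld_b$met01, build_design(ld_b, quad_basis()))
  expect_equal(f_a$beta, f_b$beta, tolerance = 1e-8)
  expect_equal(f_a$gamma, f_b$gamma, tolerance = 1e-6)
})

test_that("fit_summary reports one row per response", {
  sim <- simulate_dataset(small_spec(J = 2), seed = 13)
  mfit <- fit_all(sim$data, build_design(sim$data, quad_basis()))
  fs <- fit_summary(mfit)
  expect_equal(nrow(fs), 2)
  expect_named(fs, c("response", "converged", "singular", "sigma2_eps",
                     "reml_crit"))
})
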