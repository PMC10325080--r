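test_that("bootstrap_subjects resamples whole subjects with fresh ids", {
  ld <- make_ld(I = 5, H = 2, K = 3, J = 2)
  reps <- bootstrap_subjects(ld, n_boot = 4, seed = 41)
  expect_length(reps, 4)
  for (b in reps) {
    d <- asca_dims(b)
    expect_equal(d$I, 5)           # always I subjects
    expect_equal(nrow(b), nrow(ld))
    # every resampled subject carries a complete cross-over series
    expect_silent(assert_complete_grid(b))
    # relabelled ids are unique even when a subject is drawn twice
    expect_equal(length(unique(b$subject)), 5)
  }
  # determinism from the master seed
  reps2 <- bootstrap_subjects(ld, n_boot = 4, seed = 41)
  expect_identical(lapply(reps, as.data.frame),
                   lapply(reps2, as.data.frame))
  # replicates differ in general (bootstrap depends only on the drawn
  # multiset of subjects, so occasional coincidences are legitimate;
  # all four agreeing would not be)
  cols <- lapply(reps, function(b) as.data.frame(b)$met01)
  expect_gt(length(unique(cols)), 1)

  # degenerate: single subject duplicated
  ld1 <- make_ld(I = 1, H = 2, K = 3, J = 1)
  r1 <- bootstrap_subjects(ld1, 2, seed = 1)[[1]]
  expect_equal(asca_dims(r1)$I, 1)
  expect_equal(as.data.frame(r1)$met01, as.data.frame(ld1)$met01)
})

test_that("procrustes_align recovers a planted rotation", {
  set.seed(42)
  P_ref <- matrix(rnorm(12 * 3), 12, 3)
  Tm <- matrix(rnorm(30 * 3), 30, 3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  al <- procrustes_align(P_ref %*% Q, P_ref, Tm %*% Q)
  expect_lt(max(abs(al$loadings - P_ref)), 1e-10)
  expect_lt(max(abs(al$scores - Tm)), 1e-10)
  expect_lt(max(abs(al$rotation - t(Q))), 1e-10)

  # identity when already aligned
  al2 <- procrustes_align(P_ref, P_ref, Tm)
  expect_lt(max(abs(al2$rotation - diag(3))), 1e-10)
  expect_error(procrustes_align(P_ref, P_ref[-1, ], Tm), "shapes")
})

test_that("procrustes misfit beats 1000 random orthogonal rotations", {
  set.seed(43)
  P_ref <- matrix(rnorm(10 * 3), 10, 3)
  P_boot <- P_ref + 0.3 * matrix(rnorm(30), 10, 3)
  al <- procrustes_align(P_boot, P_ref, matrix(0, 2, 3))
  best <- norm(al$loadings - P_ref, "F")
  random_misfit <- replicate(1000, {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    norm(P_boot %*% Q - P_ref, "F")
  })
  expect_lte(best, min(random_misfit) + 1e-12)
})

test_that("rotation preserves explained variance of a replicate", {
  set.seed(44)
  M <- center_columns(matrix(rnorm(40 * 6), 40, 6))$centered
  res <- pca_svd(M, 3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  # variance captured by the rotated subspace is unchanged
  expect_equal(norm(res$scores %*% t(res$loadings), "F"),
               norm((res$scores %*% Q) %*% t(res$loadings %*% Q), "F"),
               tolerance = 1e-12)
})

test_that("percentile_ci takes entrywise type-1 percentiles", {
  vals <- array(0, dim = c(100, 1, 1))
  vals[, 1, 1] <- 1:100
  ci <- percentile_ci(vals, vals, level = 0.95)
  expect_equal(ci$score_bounds$lower[1, 1],
               quantile(1:100, 0.025, type = 1, names = FALSE))
  expect_equal(ci$score_bounds$upper[1, 1],
               quantile(1:100, 0.975, type = 1, names = FALSE))
  expect_true(all(ci$score_bounds$lower <= ci$score_bounds$upper))

  # constant replicates collapse bounds to the constant
  cst <- array(7, dim = c(10, 2, 2))
  cic <- percentile_ci(cst, cst)
  expect_true(all(cic$score_bounds$lower == 7) &&
              all(cic$score_bounds$upper == 7))
  expect_error(percentile_ci(array(0, c(1, 2, 2)), array(0, c(1, 2, 2))),
               "at least 2")
})

test_that("percentile CIs approximately cover a known mean", {
  # Gaussian resampling oracle: nominal 90% CI for a sample mean
  set.seed(45)
  n <- 40
  hits <- 0L
  for (rep in 1:60) {
    x <- rnorm(n, mean = 2)
    boots <- replicate(80, mean(sample(x, n, replace = TRUE)))
    arr <- array(boots, dim = c(80, 1, 1))
    ci <- percentile_ci(arr, arr, level = 0.9)
    if (ci$score_bounds$lower[1, 1] <= 2 &&
        ci$score_bounds$upper[1, 1] >= 2) hits <- hits + 1L
  }
  expect_gt(hits / 60, 0.75)  # nominal 0.9 within Monte-Carlo slack
})

test_that("bootstrap_pipeline end-to-end on a small scenario", {
  sim <- simulate_dataset(small_spec(I = 10, J = 2, sigma_eps = 0.2),
                          seed = 46)
  bp <- bootstrap_pipeline(sim$data, quad_basis(), effects = "MTf",
                           A = 2, n_boot = 2, level = 0.95, seed = 47)
  ref <- bp$reference
  ci <- bp$ci
  expect_s3_class(ref, "sca_result")
  expect_equal(ci$n_boot, 2)
  # n_boot = 2: percentile bounds are the elementwise min/max
  expect_true(all(ci$score_bounds$lower <= ci$score_bounds$upper))
  expect_equal(dim(ci$loading_bounds$lower), dim(ref$loadings))

  # shared-replicate multi-selection API agrees with single selection
  bp2 <- bootstrap_pipeline(sim$data, quad_basis(),
                            effects = list("MTf", c("MTf", "MTGf")),
                            A = 2, n_boot = 2, seed = 47)
  expect_named(bp2$results, c("MTf", "MTf+MTGf"))
  expect_equal(bp2$results$MTf$ci$score_bounds,
               bp$ci$score_bounds, tolerance = 1e-6)
})

test_that("near-noise-free data gives tight intervals containing the reference", {
  sim <- simulate_dataset(small_spec(I = 10, J = 2, sigma_eps = 1e-3,
                                     D_scale = 1e-3), seed = 48)
  bp <- bootstrap_pipeline(sim$data, quad_basis(), effects = "MTf",
                           A = 1, n_boot = 5, seed = 49)
  wid <- bp$ci$loading_bounds$upper - bp$ci$loading_bounds$lower
  expect_lt(max(wid), 0.05 * max(abs(bp$reference$loadings)))
  inside <- bp$reference$loadings >= bp$ci$loading_bounds$lower - 1e-9 &
    bp$reference$loadings <= bp$ci$loading_bounds$upper + 1e-9
  expect_true(all(inside))
})
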