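stim <- stimulus_spec()

test_that("the Gaussian tuning function has peak, scale, and symmetry", {
  expect_equal(gaussian_response(0.5, 0.5, 0.1), 1.0)
  expect_equal(gaussian_response(0.4, 0.5, 0.1), exp(-0.5))
  x <- runif(20, 0, 0.4)
  expect_equal(gaussian_response(0.5 + x, 0.5, 0.07),
               gaussian_response(0.5 - x, 0.5, 0.07))
  expect_error(gaussian_response(0.5, 0.5, 0), "sigma_d")
})

test_that("the stimulus tensor reproduces closed-form predictions exactly", {
  tens <- build_stimulus_tensor(stim)
  expect_equal(dim(tens), c(100L, 100L, 24L))
  ## same duration occupies the same duration-unit column at every position
  for (d in stim$durations) {
    ks <- which(stim$conditions$duration_s == d)
    cols <- vapply(ks, function(k) which(colSums(tens[, , k]) > 0), 0L)
    expect_true(all(cols == cols[1]))
  }
  set.seed(11)
  for (i in 1:100) {
    p <- list(mu_d = runif(1, 0.1, 0.9), sigma_d = runif(1, 0.02, 0.5),
              gain = rnorm(1), baseline = rnorm(1))
    expect_lt(max(abs(predict_via_tensor(p, stim, tens) -
                        predict_conditions(p, stim))), 1e-12)
  }
})

test_that("condition predictions are position invariant and degenerate correctly", {
  p0 <- list(mu_d = 0.5, sigma_d = 0.1, gain = 0, baseline = 0.3)
  expect_equal(predict_conditions(p0, stim), rep(0.3, 24))
  p1 <- list(mu_d = 0.5, sigma_d = 0.1, gain = 1, baseline = 0)
  pr <- predict_conditions(p1, stim)
  expect_equal(pr[stim$conditions$duration_s == 0.4],
               pr[stim$conditions$duration_s == 0.6])
  expect_equal(max(pr), max(pr[stim$conditions$duration_s %in% c(0.4, 0.6)]))
})

test_that("grid fit recovers grid nodes exactly and flags degenerate input", {
  grid <- default_prf_grid()
  node <- list(mu_d = 0.47, sigma_d = grid$sigma[17], gain = 1.3,
               baseline = 0.2)
  stopifnot(any(abs(grid$mu - 0.47) < 1e-12))
  betas <- predict_conditions(node, stim)
  fit <- grid_fit(betas, stim, grid)
  expect_equal(fit$mu_d, 0.47)
  expect_equal(fit$sigma_d, node$sigma_d)
  expect_equal(fit$gain, 1.3, tolerance = 1e-10)
  expect_equal(fit$r2_grid, 1, tolerance = 1e-10)

  flat <- grid_fit(rep(2.5, 24), stim, grid)
  expect_equal(flat$exclusion_reason, "fit_failure")
})

test_that("iterative refinement improves on the grid and recovers off-grid truth", {
  truth <- list(mu_d = 0.47, sigma_d = 0.13, gain = 1, baseline = 0)
  betas <- predict_conditions(truth, stim)
  seed_fit <- grid_fit(betas, stim)
  fit <- iterative_fit(betas, seed_fit, stim)
  expect_true(fit$valid)
  expect_gte(fit$r2_final, fit$r2_grid - 1e-12)
  expect_lt(abs(fit$mu_d - 0.47), 0.005)
  expect_lt(abs(fit$sigma_d - 0.13), 0.005)
  expect_equal(fit$r2_final, 1, tolerance = 1e-8)
})

test_that("exclusion rules fire: negative pRF, low grid r2, zero variance", {
  inv <- list(mu_d = 0.5, sigma_d = 0.12, gain = -1, baseline = 0.5)
  betas <- predict_conditions(inv, stim)
  fit <- iterative_fit(betas, grid_fit(betas, stim), stim)
  expect_false(fit$valid)
  expect_equal(fit$exclusion_reason, "negative_prf")

  weak <- grid_fit(rnorm(24), stim)
  weak$r2_grid <- 0.05
  out <- iterative_fit(rnorm(24), weak, stim)
  expect_false(out$valid)
  expect_equal(out$exclusion_reason, "low_r2")
})

test_that("field fitting is exact at zero noise and equivariant to vertex order", {
  p <- make_patch(5, 8, 2)
  tr <- plant_field(p, "white", seed = 5)
  tr$mu_true <- 0.25 + 0.5 * (tr$mu_true - 0.2) / 0.6  # keep interior
  b <- simulate_betas(tr, noise_sd = 0, seed = 1)
  f <- fit_field(b, p)
  expect_true(all(f$valid))
  expect_lt(max(abs(f$mu_d - tr$mu_true)), 1e-4)
  expect_lt(max(abs(1 - f$r2_final)), 1e-8)

  ## permutation equivariance
  perm <- sample(nrow(p))
  bm <- as.matrix(b[, stimulus_spec()$conditions$name])
  f2 <- fit_field(bm[perm, ], p)  # same rows, shuffled
  expect_equal(f2$mu_d[order(perm)], f$mu_d, tolerance = 1e-12)

  ## constant rows are all excluded
  fc <- fit_field(matrix(1, nrow(p), 24), p)
  expect_true(all(!fc$valid))
})

test_that("recovery error grows monotonically with beta noise", {
  p <- make_patch(5, 8, 2)
  rmse <- vapply(c(0, 0.05, 0.1, 0.2), function(ns) {
    errs <- unlist(lapply(1:5, function(s) {
      tr <- plant_field(p, "white", list(mu_range = c(0.25, 0.75)), seed = s)
      b <- simulate_betas(tr, noise_sd = ns, seed = 100 + s)
      f <- fit_field(b, p)
      (f$mu_d - tr$mu_true)[f$valid]
    }))
    sqrt(mean(errs^2))
  }, 0)
  expect_true(all(diff(rmse) > 0))
})
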