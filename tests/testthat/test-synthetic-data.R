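test_that("lattice patches have the requested geometry and ROI layout", {
  p <- make_patch(2, 2, 1.0)
  expect_equal(nrow(p), 4)
  expect_equal(max(patch_distances(p)), sqrt(2))

  p2 <- make_patch(10, 10, 2.0)
  expect_equal(nrow(p2), 100)
  D <- patch_distances(p2)
  diag(D) <- Inf
  expect_equal(min(D), 2.0)

  p3 <- make_patch(4, 8, 1.0,
                   roi_blocks = data.frame(roi = c("A", "B"), cols = c(4, 4)))
  expect_equal(as.vector(table(p3$roi)[c("A", "B")]), c(16L, 16L))
  expect_equal(p3$vertex_id, 0:31)

  expect_error(make_patch(1, 5, 1), "n_rows")
  expect_error(make_patch(3, 3, 0), "spacing")
})

test_that("planted fields realize their regime and stay in range", {
  p <- make_patch(20, 20, 1)

  const <- plant_field(p, "constant", list(mu = 0.5), seed = 1)
  expect_true(all(const$mu_true == 0.5))

  grad <- plant_field(p, "gradient", seed = 1)
  expect_equal(cor(p$x_mm, grad$mu_true), 1)
  expect_equal(range(grad$mu_true), c(0.2, 0.8))

  wht <- plant_field(p, "white", seed = 2)
  expect_true(all(wht$mu_true >= 0.2 & wht$mu_true <= 0.8))
  expect_true(all(wht$sigma_true > 0))

  bnd <- plant_field(p, "boundary", list(center = 0.5, spread = 0.01), seed = 3)
  expect_lt(max(abs(bnd$mu_true - 0.5)), 0.08)

  expect_error(plant_field(p, "fancy"), "arg")
  expect_error(plant_field(p, "grf", list(correlation_length_mm = -2)),
               "correlation_length")
})

test_that("generators are deterministic in the seed", {
  p <- make_patch(8, 8, 1)
  f1 <- plant_field(p, "grf", list(correlation_length_mm = 3), seed = 42)
  f2 <- plant_field(p, "grf", list(correlation_length_mm = 3), seed = 42)
  expect_identical(f1, f2)
  b1 <- simulate_betas(f1, noise_sd = 0.1, seed = 7)
  b2 <- simulate_betas(f1, noise_sd = 0.1, seed = 7)
  expect_identical(b1, b2)
  h1 <- simulate_behavior(0.5, 10, 20, seed = 9)
  h2 <- simulate_behavior(0.5, 10, 20, seed = 9)
  expect_identical(h1, h2)
  expect_false(identical(plant_field(p, "white", seed = 1),
                         plant_field(p, "white", seed = 2)))
})

test_that("smoothed random fields carry more short-range structure than white fields", {
  p <- make_patch(30, 30, 1)
  n_rows <- attr(p, "n_rows")
  lag1_ac <- function(mu) {  # along lattice columns
    m <- matrix(mu, nrow = n_rows)
    cor(as.vector(m[-1, ]), as.vector(m[-n_rows, ]))
  }
  wins <- vapply(1:20, function(s) {
    g <- plant_field(p, "grf",
                     list(correlation_length_mm = 6, nugget_fraction = 0),
                     seed = s)
    w <- plant_field(p, "white", seed = s)
    lag1_ac(g$mu_true) > lag1_ac(w$mu_true)
  }, TRUE)
  expect_true(all(wins))
})

test_that("forward betas follow the tuning model and position invariance", {
  p <- make_patch(2, 2, 1)
  tr <- plant_field(p, "constant", list(mu = 0.5), seed = 1)
  tr$sigma_true <- rep(0.1, 4)
  b <- simulate_betas(tr, noise_sd = 0, seed = 1)
  stim <- stimulus_spec()
  bm <- as.matrix(b[, stim$conditions$name])

  ## one sigma off the peak: exp(-0.5), at d = 0.4 and 0.6
  expect_equal(unname(bm[1, stim$conditions$duration_s == 0.4]),
               rep(exp(-0.5), 4))
  ## position invariance: identical across positions for every duration
  for (d in stim$durations) {
    cols <- stim$conditions$duration_s == d
    expect_equal(unname(apply(bm[, cols], 1, function(x) diff(range(x)))),
                 rep(0, 4))
  }
  expect_error(simulate_betas(tr, noise_sd = -1), "noise_sd")
})

test_that("exact peak response appears when the design contains the preferred duration", {
  p <- make_patch(2, 2, 1)
  tr <- plant_field(p, "constant", list(mu = 0.4), seed = 1)
  tr$sigma_true <- rep(0.1, 4)
  b <- simulate_betas(tr, noise_sd = 0, seed = 1)
  expect_equal(b$d400_p1, rep(1, 4))
  expect_equal(b$d400_p4, rep(1, 4))
})

test_that("simulated behavior follows the planted logistic", {
  ## near-step psychometric function
  b <- simulate_behavior(0.5, 1e6, 50, seed = 1)
  expect_true(all(b$response_longer[b$duration_s < 0.5] == 0))
  expect_true(all(b$response_longer[b$duration_s > 0.5] == 1))

  ## logistic symmetry of the generating probabilities around the PSE
  expect_equal(plogis(20 * (0.4 - 0.5)) + plogis(20 * (0.6 - 0.5)), 1)

  ## balanced design
  b2 <- simulate_behavior(0.55, 20, 17, seed = 2)
  expect_true(all(table(b2$duration_s) == 17))
  expect_error(simulate_behavior(0.5, -3, 10), "slope")
  expect_error(simulate_behavior(0.5, 3, 0), "n_per_duration")
})
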