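test_that("k-NN weights pick side-adjacent neighbors and standardize rows", {
  p <- make_patch(2, 2, 1)
  w <- knn_weights(p, 2)
  ## sides (1.0 mm) beat the diagonal (1.414 mm) at every vertex
  D <- patch_distances(p)
  for (i in 1:4) {
    expect_equal(unname(sort(D[i, w$neighbors[i, ]])), c(1, 1))
  }
  ## neighborhood rule: one-fourth of the smallest ROI
  p2 <- make_patch(12, 60, 1,
                   roi_blocks = data.frame(roi = c("A", "B"),
                                           cols = c(20, 40)))
  expect_equal(local_k_rule(p2), 60L)  # ROIs of 240/480 -> k = 60
  expect_error(knn_weights(p, 4), "k")
})

test_that("local Moran's I matches the brute-force definition", {
  ## 3-vertex path: middle vertex neighbors both ends, ends neighbor middle
  p <- make_patch(3, 2, 1)[1:3, ]  # first lattice column: a 3-vertex path
  vals <- c(1, 2, 3)
  w <- graph_weights(p, list(2L, c(1L, 3L), 2L))
  res <- local_morans_i(vals, w, center = "scope_mean", n_perm = 99, seed = 1)
  z <- vals - mean(vals)
  expect_equal(res$local_i, local_moran_brute(z, weights_dense(w)))

  ## random fields on a lattice, k-NN weights
  p <- make_patch(7, 8, 1.5)
  for (s in 1:10) {
    set.seed(s)
    v <- rnorm(nrow(p))
    w <- knn_weights(p, 6)
    res <- local_morans_i(v, w, center = "scope_mean", n_perm = 9, seed = s)
    expect_lt(max(abs(res$local_i -
                        local_moran_brute(v - mean(v), weights_dense(w)))),
              1e-10)
  }
  expect_error(
    local_morans_i(rep(1, nrow(p)), knn_weights(p, 6), n_perm = 9),
    "zero variance")
})

test_that("global Moran's I equals the textbook statistic and its oracles", {
  p <- make_patch(8, 8, 1)
  for (s in 1:20) {
    set.seed(100 + s)
    v <- rnorm(nrow(p))
    w <- knn_weights(p, if (s %% 2) 6 else 12)
    g <- global_morans_i(v, w, center = "scope_mean", n_perm = 9, seed = s)
    W <- weights_dense(w)
    expect_lt(abs(g$global_i - global_moran_brute(v - mean(v), W)), 1e-10)
    ## independent reference implementation
    expect_lt(abs(g$global_i - ape::Moran.I(v, W)$observed), 1e-10)
    ## the global statistic is the mean of the local ones
    expect_equal(g$global_i, mean(g$local_i), tolerance = 1e-12)
  }
})

test_that("a checkerboard with side-adjacent weights gives exactly -1", {
  p <- make_patch(6, 6, 1)
  w <- graph_weights(p, lattice_side_neighbors(6, 6))
  val <- 3 * (-1)^(p$x_mm + p$y_mm)
  g <- global_morans_i(val, w, center = "scope_mean", n_perm = 9, seed = 1)
  expect_equal(g$global_i, -1)
})

test_that("a smooth gradient is strongly positively autocorrelated", {
  p <- make_patch(20, 20, 1)
  f <- plant_field(p, "gradient", seed = 1)
  w <- knn_weights(p, 12)
  g <- global_morans_i(f$mu_true, w, center = "scope_mean",
                       n_perm = 99, seed = 2)
  expect_gt(g$global_i, 0.5)
  expect_lt(g$global_p, 0.05)
  expect_lt(abs(g$global_i -
                  global_moran_brute(f$mu_true - mean(f$mu_true),
                                     weights_dense(w))), 1e-10)
})

test_that("permutation p-values are deterministic in the seed and relabeling-invariant", {
  p <- make_patch(6, 6, 1)
  set.seed(3)
  v <- rnorm(36)
  w <- knn_weights(p, 5)
  a <- local_morans_i(v, w, center = "scope_mean", n_perm = 199, seed = 7)
  b <- local_morans_i(v, w, center = "scope_mean", n_perm = 199, seed = 7)
  expect_identical(a$pseudo_p, b$pseudo_p)

  ## consistent relabeling of vertices leaves the global statistic unchanged
  perm <- sample(36)
  p2 <- p[perm, , drop = FALSE]
  g1 <- global_morans_i(v, knn_weights(p, 5), center = "scope_mean",
                        n_perm = 9, seed = 1)
  g2 <- global_morans_i(v[perm], knn_weights(p2, 5), center = "scope_mean",
                        n_perm = 9, seed = 1)
  expect_equal(g2$global_i, g1$global_i, tolerance = 1e-12)
})

test_that("quadrant classification and ROI summaries behave per definition", {
  p <- make_patch(10, 12, 2,
                  roi_blocks = data.frame(roi = c("low", "mid"),
                                          cols = c(6, 6)))
  ## short-preferring ROI pulls the scope mean below the boundary ROI
  mu <- ifelse(p$roi == "low", 0.3, 0.5) + rep(c(-0.01, 0.01),
                                               length.out = nrow(p))
  w <- knn_weights(p, 8)
  res <- local_morans_i(mu, w, center = "hemisphere_mean",
                        n_perm = 199, alpha = 0.05, seed = 11)
  qs <- summarize_quadrants(res, p)
  expect_equal(qs$frac_ll + qs$frac_hh + qs$frac_hl + qs$frac_lh + qs$frac_ns,
               rep(1, 2), tolerance = 1e-12)
  ## the boundary ROI sits above the hemisphere mean: HH when significant
  mid <- qs[qs$roi == "mid", ]
  expect_gt(mid$frac_hh, 0.5)
  expect_equal(mid$frac_ll, 0)
  low <- qs[qs$roi == "low", ]
  expect_gt(low$frac_ll, 0.5)
  expect_equal(qs$ll_minus_hh, qs$frac_ll - qs$frac_hh)

  ## all-ns summary
  fake <- res
  fake$quadrant <- rep("ns", nrow(fake))
  qs2 <- summarize_quadrants(fake, p)
  expect_equal(qs2$frac_ns, rep(1, 2))
  expect_equal(qs2$ll_minus_hh, rep(0, 2))
})
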