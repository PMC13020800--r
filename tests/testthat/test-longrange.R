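test_that("the preference correlation matrix is a valid tau matrix", {
  set.seed(8)
  n <- 13
  u <- rnorm(n)
  m <- cbind(a = u, a2 = u + 1e-9 * rnorm(n), b = -u + 0.01 * rnorm(n),
             c = rnorm(n))
  cm <- preference_corr_matrix(m)
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_equal(unname(diag(cm)), rep(1, 4))
  expect_true(all(cm >= -1 & cm <= 1))
  expect_equal(cm["a", "a2"], 1)
  expect_lt(cm["a", "b"], -0.9)

  ## planted two-block structure: signs recovered
  blocks <- cbind(p1 = u + 0.1 * rnorm(n), p2 = u + 0.1 * rnorm(n),
                  q1 = -u + 0.1 * rnorm(n), q2 = -u + 0.1 * rnorm(n))
  cb <- preference_corr_matrix(blocks)
  expect_gt(cb["p1", "p2"], 0)
  expect_gt(cb["q1", "q2"], 0)
  expect_lt(cb["p1", "q1"], 0)
  expect_lt(cb["p2", "q2"], 0)

  ## constant region flagged
  m2 <- cbind(a = u, k = rep(0.5, n))
  expect_warning(cm2 <- preference_corr_matrix(m2), "constant")
  expect_true(is.na(cm2["a", "k"]))
})

test_that("correlation-to-distance conversion equals row-wise Euclidean distance", {
  m <- structure(diag(2), dimnames = list(c("A", "B"), c("A", "B")),
                 class = c("corr_matrix", "matrix", "array"))
  d <- corr_to_distance(m)
  expect_equal(as.numeric(d), sqrt(2))

  set.seed(9)
  for (rep in 1:5) {
    x <- matrix(runif(36, -1, 1), 6)
    x <- (x + t(x)) / 2
    diag(x) <- 1
    dimnames(x) <- list(letters[1:6], letters[1:6])
    d <- as.matrix(corr_to_distance(structure(x, class = c("corr_matrix", "matrix", "array"))))
    for (i in 1:6) for (j in 1:6) {
      expect_equal(unname(d[i, j]), sqrt(sum((x[i, ] - x[j, ])^2)),
                   tolerance = 1e-12)
    }
  }
  ## identical rows are at distance zero; 1 - tau option
  m3 <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(as.numeric(corr_to_distance(m3)), 0)
  expect_equal(as.numeric(corr_to_distance(m3, method = "one_minus_tau")), 0)
})

test_that("complete linkage matches the exhaustive agglomeration oracle", {
  ## forced merge order on three items
  D <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hierarchical_cluster(stats::as.dist(D))
  expect_equal(hc$height, c(1, 5))
  expect_equal(sort(cutree(hc, 2)[c("A", "B")]), c(A = 1, B = 1))

  set.seed(10)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    pts <- matrix(rnorm(n * 2), n)
    D <- as.matrix(dist(pts))
    hc <- hierarchical_cluster(stats::as.dist(D))
    coph <- as.matrix(stats::cophenetic(hc))
    oracle <- complete_linkage_brute(D)
    expect_lt(max(abs(coph - oracle)), 1e-10)
  }

  ## label permutation invariance (up to relabeling)
  set.seed(12)
  pts <- matrix(rnorm(12), 6)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(letters[1:6], letters[1:6])
  perm <- sample(6)
  hc1 <- hierarchical_cluster(stats::as.dist(D))
  hc2 <- hierarchical_cluster(stats::as.dist(D[perm, perm]))
  c1 <- cutree(hc1, 3)
  c2 <- cutree(hc2, 3)[names(c1)]
  expect_equal(length(unique(paste(c1, c2))), 3)  # one-to-one relabeling
  expect_error(hierarchical_cluster(matrix(1:6, 2, 3)), "symmetric")
})

test_that("a dendrogram round-trips to Newick", {
  set.seed(13)
  D <- dist(matrix(rnorm(10), 5))
  hc <- hierarchical_cluster(D)
  nwk <- dendrogram_newick(hc)
  expect_match(nwk, "^\\(.*\\);$")
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label), sort(as.character(1:5)))
})

test_that("three planted regimes are recovered as three clusters", {
  n_subj <- 13
  recovered <- vapply(1:50, function(s) {
    set.seed(3000 + s)
    u <- rnorm(n_subj)   # posterior-visual latent ordering
    w <- rnorm(n_subj)   # independent full-range latent
    med <- cbind(
      vis1  = 0.65 + 0.05 * u + 0.015 * rnorm(n_subj),
      vis2  = 0.65 + 0.05 * u + 0.015 * rnorm(n_subj),
      bnd1  = 0.50 - 0.04 * u + 0.012 * rnorm(n_subj),
      bnd2  = 0.50 - 0.04 * u + 0.012 * rnorm(n_subj),
      full1 = 0.50 + 0.05 * w + 0.015 * rnorm(n_subj),
      full2 = 0.50 + 0.05 * w + 0.015 * rnorm(n_subj)
    )
    cm <- preference_corr_matrix(med)
    hc <- hierarchical_cluster(corr_to_distance(cm))
    cl <- cutree(hc, 3)
    cl["vis1"] == cl["vis2"] && cl["bnd1"] == cl["bnd2"] &&
      cl["full1"] == cl["full2"] &&
      length(unique(cl[c("vis1", "bnd1", "full1")])) == 3
  }, TRUE)
  expect_gte(mean(recovered), 0.9)
})
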