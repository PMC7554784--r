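two_class <- c("control", "control", "trc", "trc")

test_that("t and w scores reproduce hand-evaluated values", {
  X <- cbind(a = c(0, 2, 4, 6), b = c(1, 1, 1, 1))
  t_rk <- score_t(X, two_class)
  w_rk <- score_w(X, two_class)
  # class0 = {0,2}, class1 = {4,6}: sd = sqrt(2) each, |mean gap| = 4
  expect_equal(t_rk$scores[1], 4 / sqrt(2))
  expect_equal(w_rk$scores[1], 4 / (2 * sqrt(2)))
  # identical class distributions score 0
  expect_equal(t_rk$scores[2], 0)
  expect_equal(w_rk$scores[2], 0)
})

test_that("degenerate denominators follow the stated policy", {
  X <- cbind(noisy = c(0, 2, 4, 6),
             const_sep = c(1, 1, 5, 5),   # sd 0, means differ
             const_eq = c(3, 3, 3, 3))    # sd 0, means equal
  for (score in list(score_t, score_w)) {
    rk <- score(X, two_class)
    expect_equal(rk$scores[3], 0)
    expect_equal(rk$scores[2], rk$scores[1] + 1)  # max finite + 1
    expect_equal(rk$flagged, 2L)
    expect_equal(rk$order[1], 2L)
  }
})

test_that("relief reproduces exhaustive neighbor enumeration", {
  X1 <- matrix(c(0, 1, 10, 11), 4, 1)
  expect_equal(score_relief(X1, two_class)$scores, 8.5)
  expect_equal(score_relief(matrix(3, 4, 1), two_class)$scores, 0)
  # perfectly interleaved identical classes
  X2 <- matrix(c(0, 1, 0, 1), 4, 1)
  expect_equal(score_relief(X2, two_class)$scores, -1)
  expect_error(score_relief(X1, c("control", "trc", "trc", "trc")),
               "at least 2")
})

test_that("all three scorers match brute-force oracles on random matrices", {
  labels <- c(rep("control", 3), rep("trc", 3))
  for (i in 1:30) {
    X <- withr::with_seed(i, matrix(rnorm(6 * 8), 6, 8))
    expect_lt(max(abs(score_t(X, labels)$scores - brute_t(X, labels))), 1e-10)
    expect_lt(max(abs(score_w(X, labels)$scores - brute_w(X, labels))), 1e-10)
    expect_lt(max(abs(score_relief(X, labels)$scores - brute_relief(X, labels))),
              1e-10)
  }
})

test_that("t/w rankings are invariant under positive per-feature affine maps, relief is not", {
  labels <- c(rep("control", 4), rep("trc", 4))
  X <- withr::with_seed(7, matrix(rnorm(8 * 6), 8, 6))
  scale_map <- withr::with_seed(8, runif(6, 0.5, 4))
  shift <- withr::with_seed(9, rnorm(6))
  X2 <- sweep(sweep(X, 2, scale_map, `*`), 2, shift, `+`)
  expect_equal(score_t(X2, labels)$order, score_t(X, labels)$order)
  expect_equal(score_w(X2, labels)$order, score_w(X, labels)$order)
  # relief weights scale with the feature, so its ranking can move
  expect_equal(score_relief(X2, labels)$scores,
               scale_map * score_relief(X, labels)$scores)
})

test_that("scores are invariant under sample permutation", {
  labels <- c(rep("control", 4), rep("trc", 4))
  X <- withr::with_seed(11, matrix(rnorm(8 * 5), 8, 5))
  perm <- withr::with_seed(12, sample(8))
  for (score in list(score_t, score_w, score_relief)) {
    expect_equal(score(X[perm, ], labels[perm])$scores, score(X, labels)$scores)
  }
})

test_that("ranking ties break by ascending feature index and top_features honors k", {
  X <- cbind(c(0, 1, 3, 4), c(0, 1, 3, 4), c(0, 1, 2, 3))
  rk <- score_w(X, two_class)
  expect_equal(rk$order[1:2], c(1L, 2L))
  expect_equal(top_features(rk, 2), c(1L, 2L))
  expect_error(top_features(rk, 4))
})

test_that("pca: collinear variance, orthonormality, trace identity, reconstruction", {
  X <- withr::with_seed(3, {x <- rnorm(20); cbind(x, x)})
  m <- fit_pca(X)
  expect_equal(m$eigenvalues[1] / sum(m$eigenvalues), 1)

  X2 <- withr::with_seed(4, matrix(rnorm(15 * 4), 15, 4))
  m2 <- fit_pca(X2)
  expect_equal(crossprod(m2$components), diag(4), ignore_attr = TRUE)
  expect_true(all(diff(m2$eigenvalues) <= 1e-12))
  # trace identity: eigenvalue sum = total variance of standardized data
  expect_equal(sum(m2$eigenvalues), 4)
  # full-rank round trip reproduces the standardized data
  Z <- scale(X2, m2$center, m2$scale)
  scores <- transform_pca(m2, X2, 4)
  expect_equal(scores %*% t(m2$components), Z, ignore_attr = TRUE)
  # sign convention: dominant loading positive
  for (k in 1:4) expect_gt(m2$components[which.max(abs(m2$components[, k])), k], 0)
  expect_error(transform_pca(m2, X2, 5), "exceeds")
})

test_that("pca agrees with an independent implementation up to sign", {
  X <- withr::with_seed(5, matrix(rnorm(12 * 5), 12, 5))
  m <- fit_pca(X)
  ref <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  expect_equal(m$eigenvalues, unname(ref$sdev^2))
  expect_equal(abs(m$components), abs(unname(ref$rotation)), tolerance = 1e-8)
})

test_that("selection chains behave as stated", {
  labels <- c(rep("control", 10), rep("trc", 6))
  X <- withr::with_seed(6, matrix(rnorm(16 * 40), 16, 40))
  # k_select = all features -> equals plain PCA on X
  ch <- chain_select_pca(X, labels, "t", k_select = 40, k_pca = 5)
  direct <- transform_pca(fit_pca(X[, ch$selected]), X[, ch$selected], 5)
  expect_equal(ch$reduced, direct)
  expect_setequal(ch$selected, 1:40)
  # k_pca = k_select on the selected set is a rotation: distances preserved
  ch2 <- chain_select_pca(X, labels, "w", k_select = 6, k_pca = 6)
  Z <- scale(X[, ch2$selected], ch2$pca$center, ch2$pca$scale)
  expect_equal(as.matrix(dist(ch2$reduced)), as.matrix(dist(Z)),
               tolerance = 1e-8)
  # 35 features in, 3 components out
  ch3 <- chain_select_pca(X, labels, "t", k_select = 35, k_pca = 3)
  expect_equal(dim(ch3$reduced), c(16L, 3L))
  expect_length(ch3$selected, 35L)
  expect_error(chain_select_pca(X, labels, "t", k_select = 3, k_pca = 5))
})
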