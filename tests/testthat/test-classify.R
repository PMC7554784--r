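imbalanced_labels <- c(rep("control", 37), rep("trc", 14))

test_that("constrained folds on a 37/14 design give 14 folds, 1 trc + 2-3 controls", {
  plan <- make_folds(imbalanced_labels, seed = 4)
  expect_equal(plan$fold_count, 14L)
  per_fold <- table(factor(imbalanced_labels, c("control", "trc")),
                    plan$assignment)
  expect_true(all(per_fold["trc", ] == 1L))
  expect_true(all(per_fold["control", ] %in% 2:3))
  # round-robin arithmetic: 37 = 14 * 2 + 9
  expect_equal(sum(per_fold["control", ] == 3L), 9L)
  expect_equal(sum(per_fold["control", ] == 2L), 5L)
})

test_that("balanced 4+4 with 4 folds puts exactly one of each class per fold", {
  plan <- make_folds(rep(c("control", "trc"), each = 4), fold_count = 4, seed = 1)
  per_fold <- table(rep(c("control", "trc"), each = 4), plan$assignment)
  expect_true(all(per_fold == 1L))
})

test_that("fold construction is seed-deterministic and validates inputs", {
  expect_identical(make_folds(imbalanced_labels, seed = 7),
                   make_folds(imbalanced_labels, seed = 7))
  expect_false(identical(make_folds(imbalanced_labels, seed = 7)$assignment,
                         make_folds(imbalanced_labels, seed = 8)$assignment))
  expect_error(make_folds(imbalanced_labels, fold_count = 15), "minority")
  expect_error(make_folds(rep("control", 10)), "both classes")
})

test_that("fold plans are label-permutation equivariant in composition", {
  perm <- withr::with_seed(2, sample(51))
  a <- make_folds(imbalanced_labels, seed = 3)
  b <- make_folds(imbalanced_labels[perm], seed = 3)
  comp <- function(plan, labels) table(labels, plan$assignment)
  expect_equal(unname(comp(a, imbalanced_labels)),
               unname(comp(b, imbalanced_labels[perm])))
})

test_that("kNN votes, ties and degenerate cases follow the stated rules", {
  train <- matrix(c(0, 10), 2, 1)
  lab <- c("A", "B")
  expect_equal(as.character(knn_classify(train, lab, matrix(1), k = 1)), "A")
  # k = whole training set -> majority class everywhere
  train3 <- matrix(c(0, 1, 10), 3, 1)
  expect_equal(as.character(knn_classify(train3, c("A", "A", "B"),
                                         matrix(c(9, 0), 2, 1), k = 3)),
               c("A", "A"))
  # even-k vote tie -> nearest neighbour's class
  expect_equal(as.character(knn_classify(train, lab, matrix(2), k = 2)), "A")
  expect_equal(as.character(knn_classify(train, lab, matrix(9), k = 2)), "B")
  # equal distances -> lower training index
  expect_equal(as.character(knn_classify(matrix(c(-1, 1), 2, 1), lab,
                                         matrix(0), k = 1)), "A")
  expect_error(knn_classify(train[0, , drop = FALSE], character(0), matrix(1)),
               "empty training")
})

test_that("1-NN scored on its own distinct training points is always perfect", {
  X <- withr::with_seed(5, matrix(rnorm(30 * 4), 30, 4))
  lab <- rep(c("control", "trc"), 15)
  pred <- knn_classify(X, lab, X, k = 1)
  expect_equal(mean(as.character(pred) == lab), 1)
})

test_that("svm separates separable clusters and ignores duplicated points", {
  train <- matrix(c(0, 0.5, 1, 9, 9.5, 10), 6, 1)
  lab <- rep(c("class0", "class1"), each = 3)
  pred <- svm_classify(train, lab, matrix(c(1, 9), 2, 1), kernel = "linear")
  expect_equal(as.character(pred), c("class0", "class1"))
  dup <- svm_classify(rbind(train, train), c(lab, lab),
                      matrix(c(1, 9), 2, 1), kernel = "linear")
  expect_equal(as.character(dup), as.character(pred))
  expect_error(svm_classify(train, lab, train, kernel = "wiggly"),
               "unknown kernel")
})

test_that("rbf kernel fits XOR-arranged points to training accuracy 1", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  lab <- c("A", "A", "B", "B")
  pred <- svm_classify(X, lab, X, kernel = "rbf", cost = 100)
  expect_equal(as.character(pred), lab)
})

test_that("cv aggregation reproduces the printed fold arithmetic", {
  s <- cv_summary(c(rep(1, 13), 0.75))
  expect_equal(round(s$cv_acc, 3), 0.982)
  expect_equal(round(s$cv_std, 3), 0.064)
  # the sample-SD formula would give 0.067; population SD is the convention
  expect_equal(round(stats::sd(c(rep(1, 13), 0.75)), 3), 0.067)
  expect_equal(round(cv_summary(c(rep(1, 13), 2 / 3))$cv_acc, 3), 0.976)
  all1 <- cv_summary(rep(1, 14), rep(1, 14))
  expect_equal(all1$cv_acc, 1)
  expect_equal(all1$cv_std, 0)
  expect_false(all1$overfit)
  expect_true(cv_summary(c(0.8, 0.9), c(1, 1))$overfit)
})

test_that("cross_validate aggregates fold accuracies exactly and echoes config", {
  sim <- generate_spectra(quiet_config(seed = 2, noise_sd = 0.05,
                                       n_control = 10, n_trc = 5))
  pm <- build_peak_matrix(sim$spectra, min_prominence = 0.05)
  plan <- make_folds(pm$labels, seed = 1)
  res <- cross_validate(pm$values, pm$labels, plan,
                        list(reduction = "w", dims = 4,
                             classifier = "knn", knn_k = 1L),
                        wavenumbers = pm$peak_grid)
  expect_equal(res$cv_acc, mean(res$fold_accuracies))
  expect_equal(res$cv_std, sqrt(mean((res$fold_accuracies - res$cv_acc)^2)))
  expect_true(all(res$fold_accuracies >= 0 & res$fold_accuracies <= 1))
  expect_equal(res$mode, "leakage_safe")
  # per-fold selections are unioned, so provenance can exceed dims
  expect_gte(length(res$selected_wavenumbers), 4L)
  row <- as.data.frame(res)
  expect_equal(row$classifier, "kNN k = 1")
  expect_equal(row$reduction, "MIT")
  # paper_mode records its provenance and selects once, globally
  resp <- cross_validate(pm$values, pm$labels, plan,
                         list(reduction = "w", dims = 4,
                              classifier = "knn", knn_k = 1L),
                         paper_mode = TRUE, wavenumbers = pm$peak_grid)
  expect_equal(resp$mode, "paper")
  expect_length(resp$selected_wavenumbers, 4L)
})

test_that("chained reduction labels render in the results-table dialect", {
  sim <- generate_spectra(quiet_config(seed = 6, noise_sd = 0.05,
                                       n_control = 10, n_trc = 5))
  pm <- build_peak_matrix(sim$spectra, min_prominence = 0.05)
  plan <- make_folds(pm$labels, seed = 1)
  res <- cross_validate(pm$values, pm$labels, plan,
                        list(reduction = "t+pca", dims = 5, pca_dims = 3,
                             classifier = "knn", knn_k = 1L))
  expect_equal(as.data.frame(res)$reduction, "t-score + PCA = 3")
})

test_that("run_grid enumerates the cartesian grid and sorts by accuracy", {
  sim <- generate_spectra(quiet_config(seed = 4, noise_sd = 0.05,
                                       n_control = 10, n_trc = 5))
  spec <- grid_spec(data_types = "peaks", normalize = FALSE,
                    reductions = c("w", "t"), dims = c(3L, 5L),
                    classifiers = list(list(classifier = "knn", knn_k = 1L),
                                       list(classifier = "svm", kernel = "linear")))
  res <- run_grid(sim$spectra, spec, seed = 2, min_prominence = 0.05)
  expect_equal(nrow(res), 8L)   # 2 methods x 2 dims x 2 classifiers
  expect_true(all(diff(res$cv_acc) <= 0))
  expect_equal(res$overfit, res$train_cv > res$cv_acc)
  expect_error(run_grid(sim$spectra, grid_spec(dims = 10000L),
                        min_prominence = 0.05), "runnable")
})

test_that("majority baseline equals the fold-weighted majority fraction", {
  plan <- make_folds(imbalanced_labels, seed = 1)
  sizes <- table(plan$assignment)
  manual <- mean((sizes - 1) / sizes)  # one trc per fold, rest control
  expect_equal(majority_baseline(imbalanced_labels, plan), manual)
})
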