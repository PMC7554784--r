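#' Class-constrained fold plan for k-fold cross-validation
#'
#' Builds test folds for a small imbalanced two-class design so that every
#' test fold contains at least one spectrum of each class: minority-class
#' spectra are shuffled and dealt round-robin (one per fold when
#' `fold_count` equals the minority count, the default), then the majority
#' class is shuffled and dealt round-robin on top. Within each class, fold
#' sizes differ by at most one. Deterministic for a given seed.
#'
#' With 37 + 14 labels this yields 14 folds, each holding exactly one
#' minority spectrum and two or three majority spectra.
#'
#' @param labels Two-level class labels, one per spectrum.
#' @param fold_count Number of folds; defaults to the minority-class count,
#'   which is also its maximum.
#' @param seed Integer seed for the shuffles.
#' @return A `fold_plan`: list with `fold_count` and `assignment` (test-fold
#'   index per spectrum).
#' @export
make_folds <- function(labels, fold_count = NULL, seed = 1L) {
  labels <- as.factor(as.character(labels))
  counts <- table(labels)
  if (nlevels(labels) != 2L || any(counts == 0L))
    stop("both classes must be present", call. = FALSE)
  m <- min(counts)
  if (is.null(fold_count)) fold_count <- m
  fold_count <- as.integer(fold_count)
  if (fold_count > m)
    stop("fold_count (", fold_count, ") exceeds the minority-class count (",
         m, "); every test fold needs one spectrum of each class",
         call. = FALSE)
  if (fold_count < 2L) stop("need at least 2 folds", call. = FALSE)
  minority <- names(counts)[which.min(counts)]
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(minority, setdiff(levels(labels), minority))) {
      idx <- sample(which(labels == cl))
      assignment[idx] <- rep_len(seq_len(fold_count), length(idx))
    }
  })
  structure(list(fold_count = fold_count, assignment = assignment),
            class = "fold_plan")
}

#' Per-fold accuracy of the always-majority baseline
#'
#' The rate an uninformative classifier attains under a constrained fold
#' plan: the mean over test folds of the majority-class fraction in that
#' fold. This is the correct null reference for permutation checks on
#' imbalanced data.
#'
#' @param labels Class labels.
#' @param plan A [make_folds()] plan for those labels.
#' @return A single rate in `[0, 1]`.
#' @export
majority_baseline <- function(labels, plan) {
  labels <- as.factor(as.character(labels))
  maj <- names(which.max(table(labels)))
  mean(vapply(seq_len(plan$fold_count), function(f) {
    mean(labels[plan$assignment == f] == maj)
  }, 0))
}

#' k-nearest-neighbour classification
#'
#' Euclidean-distance majority vote. Tie rules: equal distances are broken
#' by the lower training-sample index; an even vote split is resolved in
#' favour of the single nearest neighbour's class. Scoring a 1-NN on its own
#' (distinct) training points therefore always returns accuracy 1, since
#' each point is its own nearest neighbour at distance 0.
#'
#' @param train_x Training matrix (samples x features).
#' @param train_labels Label per training row.
#' @param test_x Query matrix on the same features.
#' @param k Number of neighbours, `<= nrow(train_x)`.
#' @return Factor of predicted labels, one per query row.
#' @export
knn_classify <- function(train_x, train_labels, test_x, k = 1L) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (nrow(train_x) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(k >= 1L, k <= nrow(train_x), ncol(train_x) == ncol(test_x))
  train_labels <- as.factor(as.character(train_labels))
  preds <- vapply(seq_len(nrow(test_x)), function(i) {
    d2 <- rowSums((train_x - matrix(test_x[i, ], nrow(train_x),
                                    ncol(train_x), byrow = TRUE))^2)
    ord <- order(d2, seq_along(d2))
    votes <- table(train_labels[ord[seq_len(k)]])
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) > 1L) as.character(train_labels[ord[1L]])
    else winners
  }, "")
  factor(preds, levels = levels(train_labels))
}

#' Soft-margin SVM classification
#'
#' Thin wrapper around a standard soft-margin SVM solver with the four usual
#' kernels. Defaults: cost 1, polynomial degree 3, and
#' `gamma = 1 / (n_features * var(train_x))` (falling back to
#' `1 / n_features` for constant data).
#'
#' @param train_x,train_labels Training data (two classes).
#' @param test_x Query matrix.
#' @param kernel `"linear"`, `"poly"`, `"sigmoid"` or `"rbf"`
#'   (aliases `"polynomial"`, `"radial"` accepted).
#' @param cost Soft-margin cost parameter.
#' @param degree Polynomial kernel degree.
#' @param gamma Kernel coefficient; `NULL` for the default above.
#' @param coef0 Independent kernel term (poly/sigmoid).
#' @return Factor of predicted labels.
#' @export
svm_classify <- function(train_x, train_labels, test_x,
                         kernel = "linear", cost = 1, degree = 3L,
                         gamma = NULL, coef0 = 0) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_labels <- as.factor(as.character(train_labels))
  if (nlevels(train_labels) != 2L)
    stop("training data must contain both classes", call. = FALSE)
  kern <- switch(tolower(kernel),
                 linear = "linear",
                 poly = , polynomial = "polynomial",
                 sigmoid = "sigmoid",
                 rbf = , radial = "radial",
                 stop("unknown kernel: ", kernel, call. = FALSE))
  if (is.null(gamma)) {
    v <- stats::var(as.vector(train_x))
    gamma <- if (is.na(v) || v == 0) 1 / ncol(train_x)
             else 1 / (ncol(train_x) * v)
  }
  fit <- e1071::svm(x = train_x, y = train_labels, kernel = kern,
                    cost = cost, degree = degree, gamma = gamma,
                    coef0 = coef0, scale = FALSE)
  stats::predict(fit, test_x)
}

#' Aggregate per-fold accuracies into a CV summary
#'
#' The mean and the population (divide-by-fold-count) standard deviation of
#' the fold accuracies; e.g. thirteen folds at 1.0 plus one at 0.75 give
#' mean 0.982 and SD 0.064 (to 3 decimals). Overfitting is flagged when the
#' mean training accuracy exceeds the mean test accuracy.
#'
#' @param fold_accuracies Test accuracy per fold.
#' @param train_accuracies Optional training accuracy per fold.
#' @return List with `cv_acc`, `cv_std`, `train_cv`, `train_std`, `overfit`.
#' @export
cv_summary <- function(fold_accuracies, train_accuracies = NULL) {
  out <- list(cv_acc = mean(fold_accuracies),
              cv_std = pop_sd(fold_accuracies),
              train_cv = NA_real_, train_std = NA_real_, overfit = NA)
  if (!is.null(train_accuracies)) {
    out$train_cv <- mean(train_accuracies)
    out$train_std <- pop_sd(train_accuracies)
    out$overfit <- out$train_cv > out$cv_acc
  }
  out
}

# fit the configured dimension reduction on train_x, apply to both portions
apply_reduction <- function(train_x, train_labels, test_x, reduction,
                            dims, pca_dims) {
  if (reduction == "none") {
    return(list(train = train_x, test = test_x, selected = NULL))
  }
  if (reduction == "pca") {
    model <- fit_pca(train_x)
    return(list(train = transform_pca(model, train_x, dims),
                test = transform_pca(model, test_x, dims),
                selected = NULL))
  }
  chained <- grepl("\\+pca$", reduction)
  method <- sub("\\+pca$", "", reduction)
  ch <- chain_select_pca(train_x, train_labels, method, k_select = dims,
                         k_pca = if (chained) pca_dims else NULL)
  test_sel <- test_x[, ch$selected, drop = FALSE]
  list(
    train = ch$reduced,
    test = if (chained) transform_pca(ch$pca, test_sel, pca_dims) else test_sel,
    selected = ch$selected
  )
}

classifier_call <- function(config) {
  if (config$classifier == "knn") {
    function(trx, trl, tex) knn_classify(trx, trl, tex, k = config$knn_k)
  } else {
    function(trx, trl, tex) svm_classify(trx, trl, tex,
                                         kernel = config$kernel,
                                         cost = config$cost %||% 1,
                                         degree = config$degree %||% 3L)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validate one pipeline configuration
#'
#' For every fold of the plan, fits the configured dimension reduction,
#' trains the classifier, and scores both the held-out test fold and the
#' training portion itself (the training accuracy is the overfitting
#' indicator). By default the reduction is fit on the training portion only
#' (leakage-safe); `paper_mode = TRUE` instead fits selection/PCA once on
#' the full dataset before splitting, the common shortcut in small-sample
#' chemometrics studies. The mode used is recorded in the result.
#'
#' @param X Samples x features data matrix.
#' @param labels Two-level class labels.
#' @param plan A [make_folds()] fold plan.
#' @param config List describing the pipeline:
#'   `reduction` (`"none"`, `"t"`, `"w"`, `"relief"`, `"pca"`, `"t+pca"`,
#'   `"w+pca"`, `"relief+pca"`), `dims` (selected feature count, or
#'   component count for plain `"pca"`), `pca_dims` (components for chained
#'   reductions), `classifier` (`"knn"` or `"svm"`), `knn_k`, `kernel`,
#'   and optional `cost`, `degree`.
#' @param paper_mode Fit the reduction on the full dataset before splitting.
#' @param wavenumbers Optional wavenumber per column of `X`; when given, the
#'   wavenumbers selected by a univariate reduction are recorded for marker
#'   reporting.
#' @return A `cv_result`: per-fold test/train accuracies, their means and
#'   population SDs, the overfit flag, the configuration echo, and
#'   `selected_wavenumbers` provenance.
#' @export
cross_validate <- function(X, labels, plan, config, paper_mode = FALSE,
                           wavenumbers = NULL) {
  X <- as.matrix(X)
  labels <- as.factor(as.character(labels))
  stopifnot(inherits(plan, "fold_plan"), length(labels) == nrow(X),
            length(plan$assignment) == nrow(X))
  config$reduction <- config$reduction %||% "none"
  config$pca_dims <- config$pca_dims %||% 3L

  selected <- integer(0)
  if (paper_mode && config$reduction != "none") {
    full <- apply_reduction(X, labels, X, config$reduction,
                            config$dims, config$pca_dims)
    X <- full$train
    selected <- full$selected %||% integer(0)
  }
  predict_fun <- classifier_call(config)

  folds <- seq_len(plan$fold_count)
  test_acc <- numeric(plan$fold_count)
  train_acc <- numeric(plan$fold_count)
  for (f in folds) {
    te <- plan$assignment == f
    trx <- X[!te, , drop = FALSE]; trl <- droplevels(labels[!te])
    tex <- X[te, , drop = FALSE]; tel <- labels[te]
    if (nlevels(trl) < 2L)
      stop("training portion of fold ", f, " contains a single class",
           call. = FALSE)
    if (!paper_mode && config$reduction != "none") {
      red <- apply_reduction(trx, trl, tex, config$reduction,
                             config$dims, config$pca_dims)
      selected <- union(selected, red$selected %||% integer(0))
      trx <- red$train; tex <- red$test
    }
    test_acc[f] <- mean(as.character(predict_fun(trx, trl, tex)) ==
                          as.character(tel))
    train_acc[f] <- mean(as.character(predict_fun(trx, trl, trx)) ==
                           as.character(trl))
  }

  summ <- cv_summary(test_acc, train_acc)
  structure(
    c(list(fold_accuracies = test_acc, train_accuracies = train_acc),
      summ,
      list(config = config,
           mode = if (paper_mode) "paper" else "leakage_safe",
           selected_wavenumbers = if (!is.null(wavenumbers) && length(selected))
             sort(wavenumbers[selected]) else numeric(0))),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s | %s dims=%s | cv_acc=%.3f (sd %.3f), train=%.3f%s\n",
              describe_classifier(x$config), x$config$reduction,
              x$config$dims, x$cv_acc, x$cv_std, x$train_cv,
              if (isTRUE(x$overfit)) " [overfit]" else ""))
  invisible(x)
}

describe_classifier <- function(config) {
  if (config$classifier == "knn") sprintf("kNN k = %d", config$knn_k)
  else sprintf("SVM %s", config$kernel)
}

describe_reduction <- function(config) {
  base <- c(t = "t-score", w = "MIT", relief = "RELIEF", pca = "PCA",
            none = "none")
  red <- config$reduction
  if (grepl("\\+pca$", red)) {
    sprintf("%s + PCA = %d", base[[sub("\\+pca$", "", red)]], config$pca_dims)
  } else base[[red]]
}

#' @export
as.data.frame.cv_result <- function(x, ...) {
  data.frame(
    classifier = describe_classifier(x$config),
    reduction = describe_reduction(x$config),
    dimensions = x$config$dims %||% NA_integer_,
    cv_acc = x$cv_acc, cv_std = x$cv_std,
    train_cv = x$train_cv, train_std = x$train_std,
    overfit = x$overfit, mode = x$mode,
    stringsAsFactors = FALSE
  )
}

#' Specification of a combinatorial classification grid
#'
#' @param data_types Subset of `"raw"`, `"corrected"` (background-removed),
#'   `"peaks"` (peak matrix of the background-removed spectra).
#' @param normalize Logical vector: whether to max-normalize spectra first.
#' @param reductions Character vector of reduction names (see
#'   [cross_validate()]).
#' @param dims Integer vector of dimension counts to try.
#' @param pca_dims Component count used by chained `*+pca` reductions.
#' @param classifiers List of classifier descriptors, each a list with
#'   `classifier = "knn"` and `knn_k`, or `classifier = "svm"` and `kernel`.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(data_types = "peaks",
                      normalize = FALSE,
                      reductions = c("t", "w", "t+pca", "w+pca"),
                      dims = c(10L, 20L, 35L),
                      pca_dims = 3L,
                      classifiers = list(
                        list(classifier = "knn", knn_k = 1L),
                        list(classifier = "knn", knn_k = 3L),
                        list(classifier = "svm", kernel = "linear"),
                        list(classifier = "svm", kernel = "sigmoid")
                      )) {
  stopifnot(length(data_types) > 0, length(reductions) > 0,
            length(dims) > 0, length(classifiers) > 0)
  structure(list(data_types = data_types, normalize = normalize,
                 reductions = reductions, dims = as.integer(dims),
                 pca_dims = as.integer(pca_dims), classifiers = classifiers),
            class = "grid_spec")
}

#' Run every configuration of a classification grid
#'
#' The combinatorial search over data representation x normalization x
#' dimension reduction x dimension count x classifier. Each combination is
#' cross-validated under one shared class-constrained fold plan, and the
#' rows are returned sorted by descending CV accuracy. Deterministic for a
#' fixed seed.
#'
#' @param set A raw [spectrum_set()].
#' @param spec A [grid_spec()].
#' @param seed Seed for the fold plan.
#' @param paper_mode Passed to [cross_validate()].
#' @param fold_count Passed to [make_folds()] (default: minority count).
#' @param baseline_cfg [baseline_config()] used for the `"corrected"` and
#'   `"peaks"` representations.
#' @param min_prominence,merge_tol Passed to [build_peak_matrix()].
#' @return Data frame with one row per combination: classifier, reduction,
#'   dimensions, cv_acc, cv_std, train_cv, train_std, overfit, plus
#'   data_type, normalized, mode and seed provenance columns. Combinations
#'   requesting more dimensions than the representation offers are skipped.
#' @export
run_grid <- function(set, spec = grid_spec(), seed = 1L, paper_mode = FALSE,
                     fold_count = NULL, baseline_cfg = baseline_config(),
                     min_prominence = 0, merge_tol = 0) {
  stopifnot(inherits(set, "spectrum_set"), inherits(spec, "grid_spec"))
  plan <- make_folds(set$labels, fold_count, seed)

  corrected <- NULL
  representation <- function(data_type, normalized) {
    s <- set
    if (normalized) s <- normalize_max(s)
    if (data_type == "raw")
      return(list(X = s$intensities, wn = s$grid))
    if (is.null(corrected)) corrected <<- correct_baseline(set, baseline_cfg)
    cs <- corrected
    if (normalized) cs <- normalize_max(cs)
    if (data_type == "corrected")
      return(list(X = cs$intensities, wn = cs$grid))
    pm <- build_peak_matrix(cs, min_prominence, merge_tol)
    list(X = pm$values, wn = pm$peak_grid)
  }

  combos <- expand.grid(
    data_type = spec$data_types, normalized = spec$normalize,
    reduction = spec$reductions, dims = spec$dims,
    clf = seq_along(spec$classifiers),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  if (nrow(combos) == 0L) stop("empty grid", call. = FALSE)

  reps <- list()
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    key <- paste(cb$data_type, cb$normalized)
    if (is.null(reps[[key]])) reps[[key]] <- representation(cb$data_type,
                                                           cb$normalized)
    rep_i <- reps[[key]]
    if (cb$dims > ncol(rep_i$X)) next
    config <- c(list(reduction = cb$reduction, dims = cb$dims,
                     pca_dims = spec$pca_dims),
                spec$classifiers[[cb$clf]])
    res <- cross_validate(rep_i$X, set$labels, plan, config,
                          paper_mode = paper_mode, wavenumbers = rep_i$wn)
    row <- as.data.frame(res)
    row$data_type <- cb$data_type
    row$normalized <- cb$normalized
    row$seed <- seed
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    stop("no grid combination was runnable at the requested dimensions",
         call. = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(-out$cv_acc, out$classifier, out$reduction, out$dimensions), ]
  rownames(out) <- NULL
  out
}
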