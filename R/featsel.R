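#' @title Univariate feature scoring for two-class spectra
#' @description
#' Three per-wavenumber class-separation scores used for dimension selection:
#'
#' * t-statistic: `|mu0 - mu1| / sqrt(s1^2/n1 + s0^2/n0)`
#' * MIT correlation (signal-to-noise ratio): `|mu0 - mu1| / (s1 + s0)`
#' * RELIEF: mean over samples of `|x - miss(x)| - |x - hit(x)|`, where hit
#'   and miss are the nearest other sample of the same / opposite class *in
#'   that feature alone*.
#'
#' `mu` and `s` are per-class mean and sample (n-1) standard deviation.
#' Higher scores indicate features that separate the classes better.
#'
#' Degenerate denominators: a feature whose denominator is 0 scores 0 when
#' the class means are also equal, and `max(finite scores) + 1` (flagged)
#' when the means differ — a perfectly noiseless separator outranks every
#' finite score.
#'
#' @param X Numeric matrix, samples in rows, features (wavenumbers) in
#'   columns.
#' @param labels Two-level class factor/vector, one per row of `X`.
#' @return A `feature_ranking`: list with `scores` (per feature), `order`
#'   (feature indices by descending score, ties broken by ascending
#'   wavenumber/column index), `method`, and `flagged` (indices scored by
#'   the degenerate rule).
#' @name feature_scores
NULL

two_class_split <- function(X, labels, min_per_class = 2L) {
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L)
    stop("exactly two classes required, got ", nlevels(labels), call. = FALSE)
  counts <- table(labels)
  if (any(counts < min_per_class))
    stop("each class needs at least ", min_per_class, " samples", call. = FALSE)
  lv <- levels(labels)
  list(X0 = X[labels == lv[1L], , drop = FALSE],
       X1 = X[labels == lv[2L], , drop = FALSE],
       labels = labels)
}

ranking <- function(scores, method, flagged = integer(0)) {
  structure(
    list(scores = scores,
         order = order(-scores, seq_along(scores)),
         method = method, flagged = flagged),
    class = "feature_ranking"
  )
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> method=%s, %d features; top: %s\n",
              x$method, length(x$scores),
              paste(utils::head(x$order, 5L), collapse = ", ")))
  invisible(x)
}

# shared mean/sd machinery for the two ratio scores
mean_gap_score <- function(X, labels, denom_fun, method) {
  sp <- two_class_split(as.matrix(X), labels)
  m0 <- colMeans(sp$X0); m1 <- colMeans(sp$X1)
  s0 <- apply(sp$X0, 2L, stats::sd); s1 <- apply(sp$X1, 2L, stats::sd)
  num <- unname(abs(m0 - m1))
  den <- unname(denom_fun(s0, s1, nrow(sp$X0), nrow(sp$X1)))
  scores <- ifelse(den > 0, num / den, 0)
  flagged <- unname(which(den == 0 & num > 0))
  if (length(flagged)) {
    finite_max <- if (all(den == 0)) 0 else max(scores[den > 0])
    scores[flagged] <- finite_max + 1
  }
  ranking(scores, method, flagged)
}

#' @rdname feature_scores
#' @export
score_t <- function(X, labels) {
  mean_gap_score(X, labels,
                 function(s0, s1, n0, n1) sqrt(s1^2 / n1 + s0^2 / n0), "t")
}

#' @rdname feature_scores
#' @export
score_w <- function(X, labels) {
  mean_gap_score(X, labels, function(s0, s1, n0, n1) s1 + s0, "w")
}

#' @rdname feature_scores
#' @export
score_relief <- function(X, labels) {
  X <- as.matrix(X)
  sp <- two_class_split(X, labels)
  lab <- sp$labels
  n <- nrow(X)
  scores <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    contrib <- vapply(seq_len(n), function(i) {
      same <- which(lab == lab[i]); same <- same[same != i]
      opp <- which(lab != lab[i])
      # nearest in this feature alone; distance ties -> lowest sample index
      hit <- x[same[which.min(abs(x[same] - x[i]))]]
      miss <- x[opp[which.min(abs(x[opp] - x[i]))]]
      abs(x[i] - miss) - abs(x[i] - hit)
    }, 0)
    mean(contrib)
  }, 0)
  ranking(scores, "relief")
}

#' Indices of the top-k features of a ranking
#' @param ranking A `feature_ranking`.
#' @param k Number of features to keep, `<=` feature count.
#' @return Integer vector of k feature indices, best first.
#' @export
top_features <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"),
            k >= 1, k <= length(ranking$scores))
  ranking$order[seq_len(k)]
}

#' Principal component analysis by covariance eigendecomposition
#'
#' Standardizes the data (per-feature mean 0, sample SD 1; constant features
#' get scale 1 so they map to 0), eigendecomposes the covariance matrix of
#' the standardized data, and orders components by descending eigenvalue.
#' Sign convention: each component's largest-magnitude loading is positive.
#'
#' @param X Numeric matrix, samples x features, >= 2 rows.
#' @return A `pca_model`: list with `center`, `scale`, `components`
#'   (columns = eigenvectors), `eigenvalues`.
#' @export
fit_pca <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2L)
  center <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(X, center = center, scale = scl)
  eg <- eigen(stats::cov(Z), symmetric = TRUE)
  V <- eg$vectors
  for (k in seq_len(ncol(V))) {
    lead <- which.max(abs(V[, k]))
    if (V[lead, k] < 0) V[, k] <- -V[, k]
  }
  structure(
    list(center = center, scale = scl, components = V,
         eigenvalues = pmax(eg$values, 0)),
    class = "pca_model"
  )
}

#' Project data onto the top-k principal components
#' @param model A `pca_model` from [fit_pca()].
#' @param X Data matrix on the same features the model was fit on.
#' @param k Number of components, `<=` feature count.
#' @return Samples x k score matrix.
#' @export
transform_pca <- function(model, X, k) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  if (k > ncol(model$components))
    stop("k exceeds the number of available components", call. = FALSE)
  Z <- scale(X, center = model$center, scale = model$scale)
  Z %*% model$components[, seq_len(k), drop = FALSE]
}

#' Chained dimension reduction: univariate selection, then PCA
#'
#' Selects the `k_select` best features by one of the univariate scores, then
#' fits and applies a `k_pca`-component PCA on the selected submatrix. The
#' selected feature indices are kept as provenance so reduced dimensions can
#' be traced back to wavenumbers for marker reporting.
#'
#' @param X Samples x features matrix.
#' @param labels Two-level class labels.
#' @param method `"t"`, `"w"` or `"relief"`.
#' @param k_select Number of features to select.
#' @param k_pca Number of principal components, `<= k_select`; `NULL` skips
#'   the PCA step (plain selection).
#' @return List with `reduced` (the reduced matrix), `selected` (feature
#'   indices), `ranking`, and `pca` (the fitted model or NULL).
#' @export
chain_select_pca <- function(X, labels, method = c("t", "w", "relief"),
                             k_select, k_pca = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  rk <- switch(method, t = score_t(X, labels), w = score_w(X, labels),
               relief = score_relief(X, labels))
  sel <- top_features(rk, k_select)
  Xs <- X[, sel, drop = FALSE]
  if (is.null(k_pca)) {
    list(reduced = Xs, selected = sel, ranking = rk, pca = NULL)
  } else {
    stopifnot(k_pca <= k_select)
    model <- fit_pca(Xs)
    list(reduced = transform_pca(model, Xs, k_pca), selected = sel,
         ranking = rk, pca = model)
  }
}
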