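#' Restrict a spectrum set to wavenumber windows
#'
#' Dimension elimination by region: keeps only the grid points falling inside
#' at least one `(lo, hi)` window (inclusive), e.g. the biological
#' fingerprint region 600-1800 cm^-1 plus the high-energy C-H region
#' 2500-3400 cm^-1, dropping the silent band in between.
#'
#' @param set A [spectrum_set()].
#' @param windows List of `c(lo, hi)` pairs, or a 2-column matrix with one
#'   window per row (cm^-1).
#' @return A [spectrum_set()] on the reduced grid, point order preserved.
#' @export
restrict_windows <- function(set, windows) {
  stopifnot(inherits(set, "spectrum_set"))
  if (is.matrix(windows)) windows <- asplit(windows, 1L)
  keep <- Reduce(`|`, lapply(windows, function(w) {
    stopifnot(length(w) == 2L, w[2L] >= w[1L])
    set$grid >= w[1L] & set$grid <= w[2L]
  }))
  if (!any(keep))
    stop("no grid points fall inside the requested windows", call. = FALSE)
  spectrum_set(set$intensities[, keep, drop = FALSE], set$grid[keep],
               set$labels, set$ids)
}

#' Detect local-maximum peaks in one spectrum
#'
#' An interior point is a peak when its value is strictly greater than both
#' neighbours; a flat plateau higher than both its surrounds reports its
#' leftmost point; the first and last grid points are never peaks (boundary
#' values are artifacts of window choice). Peaks whose topographic prominence
#' falls below `min_prominence * (max - min)` of the spectrum are dropped;
#' the default 0 keeps every bare local maximum.
#'
#' @param y Numeric intensity vector, length >= 3.
#' @param min_prominence Prominence threshold as a fraction of the
#'   spectrum's intensity range, in `[0, 1]`.
#' @return Integer vector of peak indices into `y` (ascending).
#' @export
detect_peaks <- function(y, min_prominence = 0) {
  stopifnot(length(y) >= 3L, min_prominence >= 0)
  r <- rle(y)
  n_run <- length(r$values)
  if (n_run < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-n_run]))
  is_pk <- logical(n_run)
  is_pk[2:(n_run - 1L)] <- r$values[2:(n_run - 1L)] > r$values[1:(n_run - 2L)] &
    r$values[2:(n_run - 1L)] > r$values[3:n_run]
  peaks <- starts[is_pk]
  if (min_prominence > 0 && length(peaks)) {
    thresh <- min_prominence * diff(range(y))
    peaks <- peaks[vapply(peaks, function(p) peak_prominence(y, p), 0) >= thresh]
  }
  peaks
}

# topographic prominence: drop from the peak to the higher of the two key
# saddles (lowest point on the way to the nearest higher ground, or to the
# boundary when no higher ground exists on that side)
peak_prominence <- function(y, p) {
  key <- function(side) {
    lo <- y[p]
    i <- p
    repeat {
      i <- i + side
      if (i < 1L || i > length(y)) return(lo)
      if (y[i] > y[p]) return(lo)
      if (y[i] < lo) lo <- y[i]
    }
  }
  y[p] - max(key(-1L), key(1L))
}

#' Build the peak-only representation of a spectrum set
#'
#' The peak grid is the union, over all spectra, of wavenumbers where a
#' spectrum has a local maximum. Each matrix entry is the spectrum's
#' intensity at that wavenumber if that spectrum has a peak there, and 0
#' otherwise — so every column is anchored by at least one genuine peak.
#'
#' With `merge_tol > 0`, union wavenumbers closer than `merge_tol` cm^-1 are
#' merged into a single column (labelled with their mean wavenumber; a
#' spectrum with several peaks inside one merged column contributes its
#' largest). This absorbs sub-grid peak-position jitter; the default keeps
#' the literal exact-grid rule.
#'
#' @param set A [spectrum_set()].
#' @param min_prominence Passed to [detect_peaks()].
#' @param merge_tol Column merge tolerance in cm^-1 (0 = off).
#' @return An object of class `peak_matrix`: list with `peak_grid`
#'   (wavenumbers), `values` (spectra x peaks matrix), `labels`, `ids`.
#' @export
build_peak_matrix <- function(set, min_prominence = 0, merge_tol = 0) {
  stopifnot(inherits(set, "spectrum_set"), merge_tol >= 0)
  peak_idx <- apply(set$intensities, 1L, detect_peaks,
                    min_prominence = min_prominence, simplify = FALSE)
  union_idx <- sort(unique(unlist(peak_idx)))
  if (!length(union_idx))
    stop("no local maxima found in any spectrum", call. = FALSE)

  n <- nrow(set$intensities)
  values <- matrix(0, n, length(union_idx),
                   dimnames = list(set$ids, NULL))
  col_of <- match(seq_along(set$grid), union_idx)
  for (i in seq_len(n)) {
    pk <- peak_idx[[i]]
    values[i, col_of[pk]] <- set$intensities[i, pk]
  }
  peak_grid <- set$grid[union_idx]

  if (merge_tol > 0 && length(peak_grid) > 1L) {
    grp <- cumsum(c(1, diff(peak_grid) > merge_tol))
    groups <- split(seq_along(peak_grid), grp)
    merged <- vapply(groups, function(cols) {
      apply(values[, cols, drop = FALSE], 1L, max)
    }, numeric(n))
    # merged column wavenumber: constituents weighted by how many spectra
    # actually peak there, so the label tracks the band center
    centers <- vapply(groups, function(cols) {
      wts <- colSums(values[, cols, drop = FALSE] != 0)
      sum(peak_grid[cols] * wts) / sum(wts)
    }, 0)
    values <- matrix(merged, nrow = n, dimnames = list(set$ids, NULL))
    peak_grid <- as.numeric(centers)
  }

  structure(
    list(peak_grid = peak_grid, values = values,
         labels = set$labels, ids = set$ids),
    class = "peak_matrix"
  )
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %d spectra x %d peak wavenumbers (%.1f-%.1f cm^-1)\n",
              nrow(x$values), length(x$peak_grid),
              min(x$peak_grid), max(x$peak_grid)))
  invisible(x)
}

#' @export
as.matrix.peak_matrix <- function(x, ...) {
  m <- x$values
  colnames(m) <- format(x$peak_grid, trim = TRUE)
  m
}
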