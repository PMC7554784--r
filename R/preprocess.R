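#' Baseline-correction configuration
#'
#' Parameters for section-wise iterative-clipping polynomial baseline
#' estimation (the modified-polyfit family): the grid is partitioned at
#' `section_bounds`, a degree-`degree` polynomial is fit per section, points
#' above the fit are clipped down to it, and the fit repeats until the curve
#' stabilizes. Neighbouring section fits are blended over a small window
#' around each cut point so the corrected spectrum is continuous.
#'
#' @param section_bounds Interior cut points (cm^-1) partitioning the grid;
#'   `NULL` places one cut every `section_width` cm^-1.
#' @param section_width Default section length when `section_bounds` is NULL.
#' @param degree Polynomial order per section.
#' @param max_iter Iteration cap for the clipping loop.
#' @param clip_tol Convergence tolerance, relative to the spectrum's
#'   intensity range: iteration stops when no point of the fitted curve moves
#'   by more than `clip_tol * range`.
#' @param blend_points Half-width (grid points) of the overlap window over
#'   which adjacent section fits are cross-faded.
#' @return A list of class `baseline_config`.
#' @export
baseline_config <- function(section_bounds = NULL, section_width = 500,
                            degree = 3L, max_iter = 100L, clip_tol = 1e-6,
                            blend_points = 5L) {
  stopifnot(degree >= 0, max_iter >= 1, clip_tol > 0, blend_points >= 1)
  structure(
    list(section_bounds = section_bounds, section_width = section_width,
         degree = as.integer(degree), max_iter = as.integer(max_iter),
         clip_tol = clip_tol, blend_points = as.integer(blend_points)),
    class = "baseline_config"
  )
}

# iterative clipping polynomial fit on one section;
# X is the precomputed Vandermonde basis; returns curve + coefficients
fit_clipped_poly <- function(y, X, max_iter, tol_abs) {
  qrX <- qr(X)
  work <- y
  curve <- rep(0, length(y))
  cf <- NULL
  for (it in seq_len(max_iter)) {
    cf <- qr.coef(qrX, work)
    fit <- drop(X %*% cf)
    delta <- max(abs(fit - curve))
    curve <- fit
    work <- pmin(work, curve)
    if (delta <= tol_abs) break
  }
  list(curve = curve, coef = cf)
}

#' Remove the baseline from every spectrum
#'
#' Per spectrum and per section, fits a polynomial by iterative clipping (the
#' fitted curve is re-fit to `pmin(data, curve)` until it stops moving), then
#' subtracts the blended section-wise curve. The construction guarantees the
#' estimated baseline hugs the lower envelope of the data, so Raman bands
#' survive subtraction while broad autofluorescence is removed.
#'
#' @param set A [spectrum_set()].
#' @param cfg A [baseline_config()].
#' @return A [spectrum_set()] of background-removed spectra (may contain
#'   small negative values).
#' @export
correct_baseline <- function(set, cfg = baseline_config()) {
  stopifnot(inherits(set, "spectrum_set"), inherits(cfg, "baseline_config"))
  grid <- set$grid
  bounds <- cfg$section_bounds
  if (is.null(bounds)) {
    bounds <- seq(min(grid), max(grid), by = cfg$section_width)
    bounds <- bounds[bounds > min(grid) & bounds < max(grid)]
  }
  section <- findInterval(grid, bounds) + 1L
  n_sec <- max(section)
  idx <- split(seq_along(grid), section)
  for (ix in idx)
    if (length(ix) < cfg$degree + 1L)
      stop("a baseline section has fewer points than degree + 1", call. = FALSE)

  # per-section Vandermonde bases on a scaled axis (conditioning)
  u <- (grid - mean(grid)) / (diff(range(grid)) / 2)
  bases <- lapply(idx, function(ix) outer(u[ix], 0:cfg$degree, `^`))

  corrected <- t(apply(set$intensities, 1L, function(y) {
    scale <- diff(range(y))
    if (scale == 0) return(y - y[1L])  # flat spectrum: its own baseline
    tol_abs <- cfg$clip_tol * scale
    fits <- lapply(seq_len(n_sec), function(s)
      fit_clipped_poly(y[idx[[s]]], bases[[s]], cfg$max_iter, tol_abs))
    baseline <- numeric(length(y))
    for (s in seq_len(n_sec)) baseline[idx[[s]]] <- fits[[s]]$curve
    # cross-fade adjacent fits over +/- blend_points around each cut
    if (n_sec > 1L) {
      for (s in seq_len(n_sec - 1L)) {
        win <- c(utils::tail(idx[[s]], cfg$blend_points),
                 utils::head(idx[[s + 1L]], cfg$blend_points))
        B <- outer(u[win], 0:cfg$degree, `^`)
        w <- seq(0, 1, length.out = length(win))
        baseline[win] <- (1 - w) * drop(B %*% fits[[s]]$coef) +
          w * drop(B %*% fits[[s + 1L]]$coef)
      }
    }
    y - baseline
  }))

  spectrum_set(corrected, grid, set$labels, set$ids)
}

#' Normalize each spectrum to its own maximum
#'
#' Divides every spectrum by its maximum intensity, so each normalized
#' spectrum peaks at exactly 1 — at whichever wavenumber its own maximum
#' happens to sit. No single band is a reliable normalization reference in
#' SERS data, which is why the per-spectrum maximum is used.
#'
#' @param set A [spectrum_set()].
#' @return A [spectrum_set()] with per-row maximum 1.
#' @export
normalize_max <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  mx <- apply(set$intensities, 1L, max)
  bad <- which(mx <= 0)
  if (length(bad))
    stop("non-positive maximum intensity for spectrum id(s): ",
         paste(set$ids[bad], collapse = ", "), call. = FALSE)
  spectrum_set(set$intensities / mx, set$grid, set$labels, set$ids)
}
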