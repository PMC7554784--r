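#' Spectrum set container
#'
#' Bundles an intensity matrix on a shared wavenumber grid with per-spectrum
#' class labels and identifiers. This is the unit of data every stage of the
#' pipeline consumes and returns: rows are individual spectra, columns are
#' wavenumber grid points in cm^-1.
#'
#' @param intensities Numeric matrix, spectra in rows, one column per grid
#'   point. Raw data are non-negative; baseline-corrected data may dip below
#'   zero.
#' @param grid Numeric vector of wavenumbers (cm^-1), strictly increasing,
#'   length >= 3, one per column of `intensities`.
#' @param labels Class label per spectrum; coerced to a factor. The pipeline
#'   expects the two levels `"control"` and `"trc"`.
#' @param ids Character identifier per spectrum (e.g. `"S03/L02"`, sample and
#'   probing location). Defaults to `"spec1"`, `"spec2"`, ...
#'
#' @return An object of class `spectrum_set`: a list with elements
#'   `intensities`, `grid`, `labels`, `ids`.
#' @export
#' @examples
#' s <- spectrum_set(matrix(1:10, 2, 5, byrow = TRUE), grid = seq(400, 440, 10),
#'                   labels = c("control", "trc"))
#' n_spectra(s)
spectrum_set <- function(intensities, grid, labels, ids = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  grid <- as.numeric(grid)
  if (length(grid) < 3L)
    stop("grid must have at least 3 points", call. = FALSE)
  if (any(diff(grid) <= 0))
    stop("grid wavenumbers must be strictly increasing", call. = FALSE)
  if (ncol(intensities) != length(grid))
    stop("ncol(intensities) must equal length(grid)", call. = FALSE)
  n <- nrow(intensities)
  if (length(labels) != n)
    stop("one label per spectrum required", call. = FALSE)
  labels <- as.factor(as.character(labels))
  if (is.null(ids)) ids <- paste0("spec", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n)
    stop("one id per spectrum required", call. = FALSE)
  dimnames(intensities) <- list(ids, NULL)
  structure(
    list(intensities = intensities, grid = grid, labels = labels, ids = ids),
    class = "spectrum_set"
  )
}

#' Number of spectra in a spectrum_set
#' @param x A `spectrum_set`.
#' @return Integer count of spectra (rows).
#' @export
n_spectra <- function(x) {
  stopifnot(inherits(x, "spectrum_set"))
  nrow(x$intensities)
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf(
    "<spectrum_set> %d spectra x %d wavenumbers (%.1f-%.1f cm^-1)\n",
    nrow(x$intensities), length(x$grid), min(x$grid), max(x$grid)
  ))
  print(table(x$labels))
  invisible(x)
}

#' Subset spectra
#'
#' @param x A `spectrum_set`.
#' @param i Row (spectrum) index.
#' @param ... Ignored.
#' @return A `spectrum_set` with the selected spectra, same grid.
#' @export
`[.spectrum_set` <- function(x, i, ...) {
  spectrum_set(x$intensities[i, , drop = FALSE], x$grid,
               droplevels(x$labels[i]), x$ids[i])
}

#' @export
as.matrix.spectrum_set <- function(x, ...) {
  m <- x$intensities
  colnames(m) <- format(x$grid, trim = TRUE)
  m
}

# run code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# population (divide-by-n) standard deviation; the CV aggregation convention
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
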