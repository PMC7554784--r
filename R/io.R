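#' Read spectra from disk
#'
#' Two plain-text layouts are supported, mirroring common spectrometer export
#' dialects:
#'
#' * `"wide"`: one delimiter-separated table; first column the class label,
#'   second column the spectrum id, remaining column headers numeric
#'   wavenumbers (cm^-1).
#' * `"per_file"`: a directory of two-column whitespace-separated text files
#'   (wavenumber, intensity), plus a `manifest.csv` with columns
#'   `filename,label,id` mapping each file to its class.
#'
#' If per-file grids differ, all spectra are resampled onto the first file's
#' grid by linear interpolation (constant extrapolation at the ends) and a
#' warning is issued.
#'
#' @param path File (wide layout) or directory (per-file layout).
#' @param layout `"wide"` or `"per_file"`.
#' @param manifest Manifest file name within `path` for the per-file layout.
#' @return A [spectrum_set()].
#' @export
read_spectra <- function(path, layout = c("wide", "per_file"),
                         manifest = "manifest.csv") {
  layout <- match.arg(layout)
  if (layout == "wide") read_spectra_wide(path) else
    read_spectra_dir(path, manifest)
}

valid_labels <- c("control", "trc")

check_labels <- function(labels) {
  bad <- setdiff(unique(as.character(labels)), valid_labels)
  if (length(bad))
    stop("unknown label token(s): ", paste(bad, collapse = ", "),
         " (expected control/trc)", call. = FALSE)
  factor(as.character(labels), levels = valid_labels)
}

read_spectra_wide <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) < 2L)
    stop("fewer than 2 spectra in ", path, call. = FALSE)
  labels <- check_labels(tab[[1L]])
  ids <- as.character(tab[[2L]])
  grid <- suppressWarnings(as.numeric(names(tab)[-(1:2)]))
  if (anyNA(grid))
    stop("non-numeric wavenumber column headers in ", path, call. = FALSE)
  if (any(diff(grid) <= 0))
    stop("wavenumber headers are not strictly increasing", call. = FALSE)
  spectrum_set(as.matrix(tab[, -(1:2), drop = FALSE]), grid, labels, ids)
}

read_spectra_dir <- function(path, manifest) {
  man <- utils::read.csv(file.path(path, manifest), stringsAsFactors = FALSE)
  if (!all(c("filename", "label") %in% names(man)))
    stop("manifest must have columns filename,label[,id]", call. = FALSE)
  if (nrow(man) < 2L)
    stop("fewer than 2 spectra listed in manifest", call. = FALSE)
  labels <- check_labels(man$label)
  ids <- if ("id" %in% names(man)) as.character(man$id) else
    sub("\\.[^.]*$", "", man$filename)
  curves <- lapply(file.path(path, man$filename), function(f) {
    d <- utils::read.table(f, header = FALSE)
    wn <- as.numeric(d[[1L]])
    if (any(diff(wn) <= 0))
      stop("non-monotone wavenumber column in ", f, call. = FALSE)
    list(grid = wn, y = as.numeric(d[[2L]]))
  })
  grid <- curves[[1L]]$grid
  resampled <- FALSE
  rows <- lapply(curves, function(cv) {
    if (identical(cv$grid, grid)) return(cv$y)
    resampled <<- TRUE
    stats::approx(cv$grid, cv$y, xout = grid, rule = 2)$y
  })
  if (resampled)
    warning("per-file grids differ; spectra resampled onto the first file's grid",
            call. = FALSE)
  spectrum_set(do.call(rbind, rows), grid, labels, ids)
}

#' Write spectra as a wide CSV table
#'
#' Inverse of `read_spectra(..., layout = "wide")`: columns `label`, `id`,
#' then one column per wavenumber.
#'
#' @param set A [spectrum_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  tab <- data.frame(label = as.character(set$labels), id = set$ids,
                    set$intensities, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[-(1:2)] <- format(set$grid, trim = TRUE, digits = 12)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# columns of a cross-validation results table that hold accuracies
accuracy_columns <- c("cv_acc", "cv_std", "train_cv", "train_std")

#' Write a cross-validation results table
#'
#' Serializes grid-run results as CSV with the schema
#' classifier, reduction, dimensions, cv_acc, cv_std, train_cv, train_std,
#' overfit (plus any provenance columns present). Accuracy columns are
#' rendered to 3 decimal places.
#'
#' @param results Data frame of CV result rows (one per configuration), as
#'   produced by [run_grid()] or [cross_validate()] via `as.data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L)
    stop("empty results table", call. = FALSE)
  for (cl in intersect(accuracy_columns, names(results)))
    results[[cl]] <- sprintf("%.3f", results[[cl]])
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path CSV file.
#' @return Data frame with numeric accuracy columns.
#' @export
read_results_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in intersect(accuracy_columns, names(tab)))
    tab[[cl]] <- as.numeric(tab[[cl]])
  tab
}
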