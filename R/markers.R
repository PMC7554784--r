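#' Bundled wavenumber annotation table
#'
#' A curated literature lookup of candidate molecular assignments for Raman
#' bands in the biologically active 1115-1665 cm^-1 region (Amide III,
#' nucleobase, tyrosine/collagen and Amide I territory), as used to
#' interpret the wavenumbers a feature-selection run picks out. Several
#' bands carry multiple plausible assignments; all are preserved, separated
#' by semicolons. The CSV under `inst/extdata` can be copied and edited by
#' users who want their own lookup.
#'
#' @param path Optional path to a user CSV with columns
#'   `wavenumber, assignment, reference` (extra columns are carried along).
#' @return Data frame ordered by ascending wavenumber.
#' @export
default_annotations <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "peak_annotations.csv",
                        package = "ramanclass", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("wavenumber", "assignment") %in% names(tab)),
            all(nzchar(tab$assignment)))
  tab[order(tab$wavenumber), , drop = FALSE]
}

#' Annotate selected wavenumbers with candidate molecular assignments
#'
#' Matches each selected wavenumber to every annotation-table row within
#' `tol` cm^-1, nearest first; wavenumbers with no match within tolerance
#' are reported with assignment `"unassigned"`. The default tolerance of
#' 2 cm^-1 (about two grid steps on a 600 g/mm grating) bridges the gap
#' between a ~1.1 cm^-1 instrument grid and sub-cm^-1 literature band
#' positions.
#'
#' @param wavenumbers Numeric vector of selected wavenumbers (cm^-1).
#' @param table Annotation table, see [default_annotations()].
#' @param tol Match tolerance in cm^-1, `>= 0`.
#' @return Data frame with columns `query` (the selected wavenumber),
#'   `matched` (table wavenumber or NA), `distance`, `assignment`,
#'   `reference`. One row per match; order-independent in its inputs.
#' @export
annotate_peaks <- function(wavenumbers, table = default_annotations(),
                           tol = 2) {
  stopifnot(tol >= 0, length(wavenumbers) > 0)
  wavenumbers <- sort(unique(as.numeric(wavenumbers)))
  rows <- lapply(wavenumbers, function(q) {
    d <- abs(table$wavenumber - q)
    hit <- which(d <= tol)
    if (!length(hit)) {
      return(data.frame(query = q, matched = NA_real_, distance = NA_real_,
                        assignment = "unassigned", reference = NA_character_,
                        stringsAsFactors = FALSE))
    }
    hit <- hit[order(d[hit], table$wavenumber[hit])]
    data.frame(query = q, matched = table$wavenumber[hit],
               distance = d[hit], assignment = table$assignment[hit],
               reference = if ("reference" %in% names(table))
                 table$reference[hit] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Band-clustering summary of selected wavenumbers
#'
#' Quantifies how strongly a selection concentrates in one spectral band:
#' the fraction of selected wavenumbers inside `band`, plus the maximal runs
#' of consecutive selected wavenumbers (in ascending order) that fall inside
#' the band. Duplicate selections are ignored.
#'
#' When `candidates` (the full list of available peak wavenumbers, e.g. the
#' peak-matrix grid) is supplied, a run is a maximal stretch of *adjacent*
#' in-band candidates that are all selected — adjacency among candidates is
#' what makes "clustering" visible. Without candidates the sorted selection
#' itself plays that role, so the in-band selections form a single run.
#'
#' @param wavenumbers Nonempty numeric vector of selected wavenumbers.
#' @param band `c(lo, hi)` in cm^-1.
#' @param candidates Optional full candidate wavenumber list the selection
#'   was drawn from.
#' @return List with `fraction` (share of selections inside the band) and
#'   `runs` (data frame `start, end, length` of each maximal run).
#' @export
cluster_summary <- function(wavenumbers, band, candidates = NULL) {
  stopifnot(length(band) == 2L, band[2L] >= band[1L])
  wavenumbers <- sort(unique(as.numeric(wavenumbers)))
  if (!length(wavenumbers)) stop("empty selection", call. = FALSE)
  inside <- wavenumbers >= band[1L] & wavenumbers <= band[2L]
  cand <- if (is.null(candidates)) wavenumbers else
    sort(unique(as.numeric(candidates)))
  in_band <- cand >= band[1L] & cand <= band[2L]
  flag <- in_band & cand %in% wavenumbers
  runs <- data.frame(start = numeric(0), end = numeric(0),
                     length = integer(0))
  if (any(flag)) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    runs <- data.frame(start = cand[starts[keep]], end = cand[ends[keep]],
                       length = r$lengths[keep])
  }
  list(fraction = mean(inside), runs = runs)
}

#' Fraction of planted marker bands recovered by a selection
#'
#' A planted band center counts as recovered when at least one selected
#' wavenumber lies within `tol` cm^-1 of it. Used to validate marker
#' reporting against the synthetic generator's ground truth.
#'
#' @param selected Selected wavenumbers (cm^-1).
#' @param centers True planted band centers.
#' @param tol Recovery tolerance in cm^-1; the default of 3 covers one
#'   default-width jitter plus two default grid steps.
#' @return Fraction in `[0, 1]` of centers recovered.
#' @export
marker_recovery <- function(selected, centers, tol = 3) {
  stopifnot(length(centers) > 0, tol >= 0)
  if (!length(selected)) return(0)
  mean(vapply(centers, function(cc) any(abs(selected - cc) <= tol), TRUE))
}
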