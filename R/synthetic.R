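#' Lorentzian line shape
#'
#' Standard Lorentzian profile used for Raman bands:
#' `A * (w/2)^2 / ((x - x0)^2 + (w/2)^2)`, so the value at the center is `A`
#' and the half maximum is reached at `x0 +/- w/2` (full width at half
#' maximum `w`). Its integral over the real line is `pi * w * A / 2`.
#'
#' @param center Band center x0 (cm^-1).
#' @param width Full width at half maximum w (cm^-1), > 0.
#' @param amplitude Peak height A.
#' @param grid Wavenumber grid to evaluate on.
#' @return Numeric intensity vector, one value per grid point.
#' @export
lorentzian <- function(center, width, amplitude, grid) {
  stopifnot(width > 0)
  hw2 <- (width / 2)^2
  amplitude * hw2 / ((grid - center)^2 + hw2)
}

#' Configuration for the synthetic spectrum generator
#'
#' Defines the statistical structure of a simulated SERS dataset: a shared
#' wavenumber grid, per-class spectrum counts with a nested biological-sample
#' structure, shared and class-differential Lorentzian bands, a per-spectrum
#' polynomial + fluorescence-hump baseline, and three noise terms
#' (multiplicative per-spectrum intensity scatter, peak-center jitter,
#' additive detector noise).
#'
#' The defaults emulate the study design the pipeline was built for: 51
#' spectra (37 control from 8 biological samples, 14 tumor repopulating cell
#' spectra from 5 samples) on a 350-1800 cm^-1 grid at 1.1 cm^-1 spacing,
#' with the differential bands planted in the biologically active
#' 1115-1665 cm^-1 region.
#'
#' @param grid_start,grid_end,grid_step Wavenumber grid in cm^-1.
#' @param n_control,n_trc Spectrum counts per class.
#' @param n_samples_control,n_samples_trc Biological-sample counts; spectra
#'   are assigned to samples round-robin and all spectra of one sample share
#'   a multiplicative amplitude effect (within-sample correlation).
#' @param shared_peaks Data frame `center, width, amplitude`: bands present
#'   with the same mean amplitude in both classes.
#' @param differential_peaks Data frame `center, width, amp_control,
#'   amp_trc`: bands whose mean amplitude differs by class; these centers are
#'   the planted ground-truth markers.
#' @param baseline_degree Polynomial order of the per-spectrum baseline.
#' @param baseline_scale Overall baseline magnitude; 0 switches the baseline
#'   (polynomial and fluorescence hump) off entirely.
#' @param fluorescence_scale Height of the broad autofluorescence hump.
#' @param intensity_jitter Log-scale SD of the per-spectrum multiplicative
#'   intensity factor (SERS absolute intensity is not reproducible).
#' @param sample_effect_sd Log-scale SD of the per-sample amplitude effect.
#' @param shift_jitter SD (cm^-1) of per-spectrum, per-band center jitter.
#' @param noise_sd SD of additive zero-mean Gaussian noise.
#' @param seed Root seed; fanned out to one sub-seed per spectrum.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(grid_start = 350, grid_end = 1800, grid_step = 1.1,
                             n_control = 37L, n_trc = 14L,
                             n_samples_control = 8L, n_samples_trc = 5L,
                             shared_peaks = default_shared_peaks(),
                             differential_peaks = default_differential_peaks(),
                             baseline_degree = 3L, baseline_scale = 1,
                             fluorescence_scale = 1.5,
                             intensity_jitter = 0.15, sample_effect_sd = 0.10,
                             shift_jitter = 1.0, noise_sd = 0.02,
                             seed = 1L) {
  cfg <- list(
    grid_start = grid_start, grid_end = grid_end, grid_step = grid_step,
    n_control = as.integer(n_control), n_trc = as.integer(n_trc),
    n_samples_control = as.integer(n_samples_control),
    n_samples_trc = as.integer(n_samples_trc),
    shared_peaks = as.data.frame(shared_peaks),
    differential_peaks = as.data.frame(differential_peaks),
    baseline_degree = as.integer(baseline_degree),
    baseline_scale = baseline_scale,
    fluorescence_scale = fluorescence_scale,
    intensity_jitter = intensity_jitter,
    sample_effect_sd = sample_effect_sd,
    shift_jitter = shift_jitter, noise_sd = noise_sd, seed = as.integer(seed)
  )
  stopifnot(cfg$grid_step > 0, cfg$grid_end > cfg$grid_start,
            cfg$n_control >= 1L, cfg$n_trc >= 1L,
            cfg$n_samples_control >= 1L, cfg$n_samples_trc >= 1L,
            all(cfg$shared_peaks$width > 0),
            all(cfg$differential_peaks$width > 0),
            cfg$baseline_degree >= 0L,
            cfg$intensity_jitter >= 0, cfg$sample_effect_sd >= 0,
            cfg$shift_jitter >= 0, cfg$noise_sd >= 0)
  grid <- generator_grid(cfg)
  out <- cfg$differential_peaks$center < min(grid) |
    cfg$differential_peaks$center > max(grid)
  if (any(out))
    stop("differential peak center(s) outside the grid: ",
         paste(cfg$differential_peaks$center[out], collapse = ", "),
         call. = FALSE)
  if (any(cfg$shared_peaks$center < min(grid) | cfg$shared_peaks$center > max(grid)))
    stop("shared peak center(s) outside the grid", call. = FALSE)
  class(cfg) <- "generator_config"
  cfg
}

generator_grid <- function(cfg) {
  seq(cfg$grid_start, cfg$grid_end, by = cfg$grid_step)
}

# characteristic cellular Raman bands (phenylalanine, nucleic acid PO2-,
# CH2 deformations, ...) present in both phenotypes
default_shared_peaks <- function() {
  data.frame(
    center    = c(622, 728, 782, 855, 1003, 1092, 1305, 1445, 1740),
    width     = c(8, 10, 9, 10, 7, 10, 14, 12, 10),
    amplitude = c(0.5, 1.0, 0.6, 0.5, 1.2, 0.9, 0.7, 1.0, 0.3)
  )
}

# planted class-differential bands at literature positions in the
# 1115-1665 cm^-1 region (CH bend, Amide III, CH2/nucleic acid, guanine,
# Amide I); trc amplitude >= 2x control
default_differential_peaks <- function() {
  data.frame(
    center      = c(1116.4, 1201.5, 1267.6, 1420.5, 1578.9, 1654.9),
    width       = c(9, 10, 10, 10, 9, 12),
    amp_control = c(0.35, 0.30, 0.40, 0.25, 0.30, 0.50),
    amp_trc     = c(0.80, 0.70, 0.90, 0.60, 0.65, 1.10)
  )
}

#' Generate a synthetic SERS spectrum set with planted markers
#'
#' Each spectrum is built as
#' `s_i * [ baseline_i(x) + sum_b e_sample(i) * A_b * L(x; c_b + d_ib, w_b) ] + eps`,
#' where `L` is the [lorentzian()] profile, `A_b` the class-appropriate band
#' amplitude, `d_ib` per-spectrum center jitter, `e_sample` a shared
#' per-sample log-normal amplitude effect, `s_i` a per-spectrum log-normal
#' intensity factor, and `eps` additive Gaussian noise. The baseline is a
#' random low-order polynomial plus a broad Gaussian autofluorescence hump.
#'
#' The root seed is fanned out to one sub-seed per spectrum, so output is
#' bit-reproducible for a given configuration.
#'
#' @param config A [generator_config()].
#' @return A list with elements `spectra` (a [spectrum_set()]) and `markers`
#'   (data frame of the planted differential bands: `center, width,
#'   amp_control, amp_trc` — the ground truth downstream marker recovery is
#'   judged against).
#' @export
generate_spectra <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  grid <- generator_grid(config)
  n <- config$n_control + config$n_trc
  labels <- c(rep("control", config$n_control), rep("trc", config$n_trc))

  # biological samples: controls fill S01..S<nc>, trcs continue the numbering
  sample_of <- c(
    rep_len(seq_len(config$n_samples_control), config$n_control),
    config$n_samples_control +
      rep_len(seq_len(config$n_samples_trc), config$n_trc)
  )
  loc <- stats::ave(seq_len(n), sample_of, FUN = seq_along)
  ids <- sprintf("S%02d/L%02d", sample_of, loc)

  n_samples <- config$n_samples_control + config$n_samples_trc
  draws <- with_seed(config$seed, list(
    spectrum_seeds = sample.int(.Machine$integer.max - 1L, n),
    sample_effect = exp(stats::rnorm(n_samples, 0, config$sample_effect_sd))
  ))

  peaks <- rbind(
    data.frame(center = config$shared_peaks$center,
               width = config$shared_peaks$width,
               amp_control = config$shared_peaks$amplitude,
               amp_trc = config$shared_peaks$amplitude),
    config$differential_peaks[, c("center", "width", "amp_control", "amp_trc")]
  )

  u <- (grid - mean(grid)) / (diff(range(grid)) / 2)  # [-1, 1] for conditioning
  fl_center <- 800
  fl_width <- 600

  rows <- vapply(seq_len(n), function(i) {
    with_seed(draws$spectrum_seeds[i], {
      amp <- if (labels[i] == "control") peaks$amp_control else peaks$amp_trc
      amp <- amp * draws$sample_effect[sample_of[i]]
      shift <- stats::rnorm(nrow(peaks), 0, config$shift_jitter)
      sig <- rowSums(vapply(seq_len(nrow(peaks)), function(b) {
        lorentzian(peaks$center[b] + shift[b], peaks$width[b], amp[b], grid)
      }, numeric(length(grid))))
      coefs <- stats::rnorm(config$baseline_degree + 1L, 0, 0.3)
      coefs[1L] <- coefs[1L] + 1  # keep the offset broadly positive
      base <- config$baseline_scale *
        (drop(outer(u, 0:config$baseline_degree, `^`) %*% coefs) +
           config$fluorescence_scale *
             exp(-(grid - fl_center)^2 / (2 * fl_width^2)))
      s_i <- exp(stats::rnorm(1, 0, config$intensity_jitter))
      s_i * (base + sig) + stats::rnorm(length(grid), 0, config$noise_sd)
    })
  }, numeric(length(grid)))

  list(
    spectra = spectrum_set(t(rows), grid, labels, ids),
    markers = config$differential_peaks
  )
}
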