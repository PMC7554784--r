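#!/usr/bin/env Rscript
# Stage 2: baseline correction and normalization.
#
# Removes the autofluorescence background from every spectrum by
# section-wise iterative-clipping polynomial fitting (sections of 500 cm^-1,
# cubic), and also writes the max-normalized variant used by the
# normalization arm of the classification grid.

library(ramanclass)

raw <- read_spectra("results/data/spectra_raw.csv", layout = "wide")
corrected <- correct_baseline(raw, baseline_config())
write_spectra(corrected, "results/data/spectra_corrected.csv")
write_spectra(normalize_max(corrected), "results/data/spectra_normalized.csv")

# how much signal the baseline carried, per class
removed <- raw$intensities - corrected$intensities
cat(sprintf("mean baseline fraction of raw intensity: %.2f\n",
            mean(rowMeans(removed) / rowMeans(raw$intensities))))
cat(sprintf("corrected intensities span [%.3f, %.3f]\n",
            min(corrected$intensities), max(corrected$intensities)))
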