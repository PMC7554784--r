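#!/usr/bin/env Rscript
# Stage 1: simulate the study dataset.
#
# Generates the 51-spectrum SERS dataset the rest of the workflow analyses:
# 37 parental-control spectra (8 biological samples) and 14 tumor
# repopulating cell (TRC) spectra (5 samples) on a 350-1800 cm^-1 grid at
# 1.1 cm^-1 spacing, with six class-differential Lorentzian bands planted in
# the 1115-1665 cm^-1 region as ground-truth markers.

library(ramanclass)

seed <- 101L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

sim <- generate_spectra(generator_config(seed = seed))
print(sim$spectra)

write_spectra(sim$spectra, "results/data/spectra_raw.csv")
write.csv(sim$markers, "results/data/true_markers.csv", row.names = FALSE)

cat(sprintf(
  "wrote %d spectra (%d control, %d trc) on %d grid points; %d planted markers at %s cm^-1\n",
  n_spectra(sim$spectra),
  sum(sim$spectra$labels == "control"), sum(sim$spectra$labels == "trc"),
  length(sim$spectra$grid), nrow(sim$markers),
  paste(sim$markers$center, collapse = ", ")))
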