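#!/usr/bin/env Rscript
# Calibrate every scene, segment the fruit ROI (800 nm threshold, 550/670
# stalk rule), and extract the modeling spectra: one mean ROI spectrum
# per sample and 400 random ROI pixels per sample (72,000 pixel spectra
# in total) for deep-feature training.
#
# Writes: results/mean_spectra.csv, results/pixel_rows.txt

library(anthomap)

seed <- 20230327
study <- generate_study(n_per_variety = 90, seed = seed)
spectra <- extract_study_spectra(study, n_pixels = 400, progress = TRUE)

write_spectra_csv(spectra$mean_spectra, "results/mean_spectra.csv")
writeLines(as.character(nrow(spectra$pixels$values)),
           "results/pixel_rows.txt")

cat(sprintf("extracted %d mean spectra and %d pixel spectra (%d bands)\n",
            nrow(spectra$mean_spectra$values),
            nrow(spectra$pixels$values),
            ncol(spectra$pixels$values)))
cat(sprintf("ROI sizes: median %d pixels (range %d-%d)\n",
            median(spectra$roi_sizes), min(spectra$roi_sizes),
            max(spectra$roi_sizes)))
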