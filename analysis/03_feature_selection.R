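#!/usr/bin/env Rscript
# Reduce the 379 SNV variables three ways: successive projections (SPA),
# competitive adaptive reweighted sampling (CARS, 50 runs, 10-fold CV),
# and a stacked auto-encoder (379-300-150-13-150-300-379).
#
# Writes: results/selection_spa.json, results/selection_cars.json,
#         results/sae_loss.csv

library(anthomap)
library(jsonlite)

seed <- 20230327
study <- generate_study(n_per_variety = 90, seed = seed)
spectra <- extract_study_spectra(study, n_pixels = 400, progress = TRUE)
Xs <- snv(crop_window(spectra$mean_spectra))
y <- study$reference$content_mg_g
split <- split_dataset(length(y),
                       paste(study$design$variety, study$design$stage),
                       0.7, seed = seed + 101L)
Xtr <- spectral_matrix(Xs$values[split$train, ], Xs$wavelengths)

spa <- spa_select(Xtr, y[split$train], max_vars = 25, seed = seed + 201L)
cat(sprintf("SPA: %d wavelengths: %s nm\n", length(spa$indices),
            paste(round(spa$wavelengths, 1), collapse = ", ")))

cars <- cars_select(Xtr, y[split$train], n_runs = 50, seed = seed + 301L)
cat(sprintf("CARS: %d wavelengths (best run %d): %s nm\n",
            length(cars$indices), cars$diagnostics$best_run,
            paste(round(cars$wavelengths, 1), collapse = ", ")))

Ps <- snv(crop_window(spectra$pixels))
set.seed(seed + 401L)
take <- sample(nrow(Ps$values), 16000)
sae <- train_sae(Ps$values[take, ], h = 13, epochs = 40, seed = seed + 402L)
cat(sprintf("SAE: final reconstruction loss %.5f (start %.5f)\n",
            tail(sae$loss$finetune, 1), sae$loss$finetune[1]))

keep <- function(s) s[c("method", "indices", "wavelengths", "diagnostics")]
write_json(keep(spa), "results/selection_spa.json", auto_unbox = TRUE,
           digits = NA)
write_json(keep(cars), "results/selection_cars.json", auto_unbox = TRUE,
           digits = NA)
write.csv(data.frame(epoch = seq_along(sae$loss$finetune),
                     mse = sae$loss$finetune),
          "results/sae_loss.csv", row.names = FALSE)
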