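#!/usr/bin/env Rscript
# Apply the best bundle per pixel to one representative scene per
# variety x stage and render the six anthocyanin distribution maps under
# a shared color scale.
#
# Writes: results/map_<sample>.png, results/map_stats.csv
# (re-uses the cached run from 04_models.R when present)

library(anthomap)

seed <- 20230327
run <- run_study(n_per_variety = 90, seed = seed,
                 ga_generations = list(elm = 150, lssvm = 50),
                 sae_epochs = 40, sae_pixel_cap = 16000,
                 out_dir = "results/run", progress = TRUE)

for (s in run$maps$scenes)
  render_map(s$map, file.path("results", paste0("map_", s$sample_id, ".png")),
             scale = run$maps$scale)
write.csv(run$maps$stats, "results/map_stats.csv", row.names = FALSE)

cat("per-scene map statistics (prediction vs true concentration field):\n")
print(run$maps$stats, digits = 3)
cat(sprintf("median pixelwise R2: %.3f\n", median(run$maps$stats$map_r2)))
cat("mean predicted content by variety x stage (mg/g):\n")
print(with(run$maps$stats, tapply(mean_pred, list(variety, stage), mean)),
      digits = 3)
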