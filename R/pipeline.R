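#' Extract modeling spectra from every scene of a synthetic study
#'
#' For each design row: materialize the scene from its seed, calibrate
#' with Eq.-style white/dark correction, segment the fruit at 800 nm,
#' remove the stalk with the 550/670 nm rule, then record the ROI mean
#' spectrum and `n_pixels` randomly sampled ROI pixel spectra. Cubes are
#' processed one at a time and discarded, so memory stays flat.
#'
#' @param study result of [generate_study()].
#' @param n_pixels pixels sampled per scene for the deep-learning matrix.
#' @param progress print a dot every 10 scenes.
#' @return List: `mean_spectra` (n x p [spectral_matrix()], row ids =
#'   sample ids), `pixels` (n*n_pixels x p [spectral_matrix()]),
#'   `pixel_scene` (sample id per pixel row), `roi_sizes`.
#' @export
extract_study_spectra <- function(study, n_pixels = 400, progress = FALSE) {
  specs <- study$scene_specs
  n <- length(specs)
  p <- length(specs[[1]]$wavelengths)
  wl <- specs[[1]]$wavelengths
  mean_mat <- matrix(0, n, p)
  px_mat <- matrix(0, n * n_pixels, p)
  px_scene <- character(n * n_pixels)
  roi_sizes <- integer(n)
  filled <- 0L
  for (i in seq_len(n)) {
    sc <- generate_scene(specs[[i]])
    refl <- calibrate(sc$raw, sc$white, sc$dark)
    mask <- segment_fruit(refl)
    mask <- remove_stalk(refl, mask)
    roi_sizes[i] <- mask$n_fruit_pixels
    mean_mat[i, ] <- mean_spectrum(refl, mask)$values
    px <- sample_pixels(refl, mask, n = n_pixels, seed = specs[[i]]$seed + 1L)
    k <- nrow(px$values)
    px_mat[filled + seq_len(k), ] <- px$values
    px_scene[filled + seq_len(k)] <- study$design$sample_id[i]
    filled <- filled + k
    if (progress && i %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  px_mat <- px_mat[seq_len(filled), , drop = FALSE]
  px_scene <- px_scene[seq_len(filled)]
  list(
    mean_spectra = spectral_matrix(mean_mat, wl,
                                   row_ids = study$design$sample_id),
    pixels = spectral_matrix(px_mat, wl,
                             row_ids = sprintf("px%06d", seq_len(filled))),
    pixel_scene = px_scene,
    roi_sizes = roi_sizes
  )
}

#' Run the full synthetic study: simulate, extract, select, model, map
#'
#' Executes the complete flow on the synthetic two-variety, three-stage
#' design: scene generation and spectral extraction, 450-1050 nm crop +
#' SNV, the requested variable selectors, GA-optimized ELM / LS-SVM
#' models over a stratified 7:3 split, an evaluation grid, and per-pixel
#' prediction maps of one representative scene per variety x stage cell
#' using the best model (lowest test RMSE).
#'
#' When `out_dir` is given, artifacts are written there (reference.csv,
#' grid.csv, map PNGs under a shared color scale, manifest.json) and the
#' expensive extraction stage is cached as an .rds keyed by the run
#' configuration, so an interrupted run resumes after the last completed
#' stage.
#'
#' @param n_per_variety samples per variety (divisible by 3).
#' @param seed master seed; all stage seeds derive from it.
#' @param selectors subset of `c("none", "spa", "cars", "sae")`.
#' @param models subset of `c("elm", "lssvm")`.
#' @param ga_generations named list, generations for `elm` and `lssvm`.
#' @param sae_epochs,sae_pixel_cap SAE training epochs and the maximum
#'   number of pixel rows used for SAE training (subsampled
#'   deterministically from the pooled pixel matrix).
#' @param n_pixels ROI pixels sampled per scene.
#' @param spa_max_vars,cars_runs selector settings.
#' @param out_dir optional run directory.
#' @param progress print stage progress.
#' @param ... extra per-scene arguments forwarded to [generate_study()]
#'   (e.g. `rows`, `cols`, `noise_sd`).
#' @return List of class `study_run`: `study`, `spectra_snv`, `split`,
#'   `selections`, `grid` (data.frame), `bundles`, `best` (selector,
#'   model), `maps` (per-scene stats + stage means), `config`.
#' @export
run_study <- function(n_per_variety = 90, seed = 1L,
                      selectors = c("none", "spa", "cars", "sae"),
                      models = c("elm", "lssvm"),
                      ga_generations = list(elm = 300, lssvm = 200),
                      sae_epochs = 40, sae_pixel_cap = 16000,
                      n_pixels = 400, spa_max_vars = 25, cars_runs = 50,
                      out_dir = NULL, progress = FALSE, ...) {
  config <- list(n_per_variety = n_per_variety, seed = seed,
                 selectors = selectors, models = models,
                 ga_generations = ga_generations, sae_epochs = sae_epochs,
                 sae_pixel_cap = sae_pixel_cap, n_pixels = n_pixels,
                 spa_max_vars = spa_max_vars, cars_runs = cars_runs,
                 scene_args = list(...))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  ## stage 1-2: design + spectra (cached when out_dir given)
  stage <- function(name, code) run_stage(out_dir, config, name, code)
  study <- stage("study", function()
    generate_study(n_per_variety, seed = seed, ...))
  spectra <- stage("spectra", function()
    extract_study_spectra(study, n_pixels = n_pixels, progress = progress))

  ## stage 3: preprocessing (crop to the analysis window, then SNV)
  Xs <- snv(crop_window(spectra$mean_spectra))
  Ps <- snv(crop_window(spectra$pixels))
  y <- study$reference$content_mg_g
  strata <- paste(study$design$variety, study$design$stage)
  split <- split_dataset(length(y), strata, 0.7, seed = seed + 101L)

  ## stage 4: variable selection (supervised selectors see training rows only)
  if (progress) message("selecting variables ...")
  Xtr <- spectral_matrix(Xs$values[split$train, , drop = FALSE],
                         Xs$wavelengths, Xs$row_ids[split$train])
  selections <- list()
  if ("spa" %in% selectors)
    selections$spa <- stage("spa", function()
      spa_select(Xtr, y[split$train], max_vars = spa_max_vars,
                 seed = seed + 201L))
  if ("cars" %in% selectors)
    selections$cars <- stage("cars", function()
      cars_select(Xtr, y[split$train], n_runs = cars_runs,
                  cv_folds = min(10, floor(length(split$train) / 2)),
                  seed = seed + 301L))
  if ("sae" %in% selectors) {
    selections$sae <- stage("sae", function() {
      Ptrain <- Ps$values
      if (nrow(Ptrain) > sae_pixel_cap) {
        take <- with_seed(seed + 401L, sample(nrow(Ptrain), sae_pixel_cap))
        Ptrain <- Ptrain[take, , drop = FALSE]
      }
      p <- ncol(Ptrain)
      hidden <- if (p > 300) c(300, 150)      # full-resolution default
                else pmax(c(round(0.75 * p), round(0.4 * p)), 14)
      train_sae(Ptrain, hidden = hidden, epochs = sae_epochs,
                seed = seed + 402L)
    })
  }

  ## pixel-consistency validation set for the ELM ridge selection:
  ## a capped subsample of training-scene pixels, each labelled with its
  ## scene's wet-chemistry reference content
  px_per_scene <- 40L
  train_ids <- study$design$sample_id[split$train]
  px_rows <- which(spectra$pixel_scene %in% train_ids)
  px_rows <- unlist(lapply(split(px_rows, spectra$pixel_scene[px_rows]),
                           function(r) r[seq_len(min(px_per_scene, length(r)))]),
                    use.names = FALSE)
  y_by_id <- stats::setNames(y, study$design$sample_id)
  px_y <- unname(y_by_id[spectra$pixel_scene[px_rows]])
  Ppx <- spectral_matrix(spectra$pixels$values[px_rows, , drop = FALSE],
                         spectra$pixels$wavelengths)

  ## stage 5: model grid
  if (progress) message("fitting model grid ...")
  feature_sets <- list(none = NULL)
  feature_sets <- c(feature_sets, selections)
  feature_sets <- feature_sets[intersect(selectors, names(feature_sets))]
  grid <- list(); bundles <- list()
  for (sel_name in selectors) {
    sel <- feature_sets[[sel_name]]
    bundle0 <- model_bundle(NULL, Xs$wavelengths, selector = sel)
    F_all <- bundle_features(bundle0, spectra$mean_spectra)
    Ftr <- F_all[split$train, , drop = FALSE]
    Fte <- F_all[split$test, , drop = FALSE]
    Fpx <- bundle_features(bundle0, Ppx)
    for (mod_name in models) {
      key <- paste(sel_name, mod_name, sep = "_")
      fit <- stage(paste0("fit_", key), function() {
        if (mod_name == "elm")
          fit_ga_elm(Ftr, y[split$train],
                     generations = ga_generations$elm, seed = seed + 501L,
                     pixel_val = list(features = Fpx, y_scene = px_y))
        else
          fit_ga_lssvm(Ftr, y[split$train],
                       generations = ga_generations$lssvm, seed = seed + 502L)
      })
      rep <- evaluate_model(fit$model, Ftr, y[split$train], Fte, y[split$test])
      bundles[[key]] <- model_bundle(fit$model, Xs$wavelengths, selector = sel)
      grid[[key]] <- data.frame(
        selector = sel_name, model = mod_name,
        n_features = ncol(F_all),
        r2_train = rep$r2_train, r2_test = rep$r2_test,
        rmse_train = rep$rmse_train, rmse_test = rep$rmse_test,
        cv_rmse = fit$ga$fitness,
        stringsAsFactors = FALSE)
      if (progress)
        message(sprintf("  %s: R2p=%.3f RMSEP=%.3f", key,
                        rep$r2_test, rep$rmse_test))
    }
  }
  grid <- do.call(rbind, c(grid, list(make.row.names = FALSE)))
  best_key <- paste(grid$selector[which.min(grid$rmse_test)],
                    grid$model[which.min(grid$rmse_test)], sep = "_")

  ## stage 6: prediction maps, one representative scene per cell.
  ## The mapping bundle is SAE + GA-ELM when both were fitted: the SAE
  ## is trained on noisy pixel spectra (so its features transfer from
  ## clean mean spectra to pixels) and the ELM's ridge is calibrated on
  ## pixel data; kernel models on raw bands degrade under per-pixel
  ## noise because every pixel moves far from the training points.
  map_key <- if ("sae_elm" %in% names(bundles)) "sae_elm" else best_key
  if (progress) message("mapping representative scenes (", map_key, ") ...")
  maps <- stage("maps", function()
    map_representative_scenes(study, bundles[[map_key]]))

  out <- structure(list(study = study, spectra = spectra,
                        mean_snv = Xs, split = split,
                        selections = selections, grid = grid,
                        bundles = bundles, best = best_key,
                        map_bundle = map_key, maps = maps,
                        config = config),
                   class = "study_run")
  if (!is.null(out_dir)) write_run_artifacts(out, out_dir)
  out
}

# predict + render one scene per variety x stage under a shared scale;
# maps are lightly smoothed (1 px) to suppress iid per-pixel sensor noise
map_representative_scenes <- function(study, bundle, out_dir = NULL,
                                      smooth_sigma = 1) {
  design <- study$design
  first <- design[design$rep == 1, ]
  per_scene <- lapply(seq_len(nrow(first)), function(i) {
    row <- first[i, ]
    idx <- match(row$sample_id, design$sample_id)
    sc <- generate_scene(study$scene_specs[[idx]])
    refl <- calibrate(sc$raw, sc$white, sc$dark)
    mask <- remove_stalk(refl, segment_fruit(refl))
    pm <- predict_map(refl, mask, bundle, smooth_sigma = smooth_sigma)
    stats <- map_statistics(pm, sc$truth)
    list(sample_id = row$sample_id, variety = row$variety, stage = row$stage,
         map = pm, stats = stats,
         mean_pred = mean(pm$values[pm$mask$grid]))
  })
  stats <- data.frame(
    sample_id = vapply(per_scene, `[[`, "", "sample_id"),
    variety = vapply(per_scene, `[[`, "", "variety"),
    stage = vapply(per_scene, `[[`, "", "stage"),
    mean_pred = vapply(per_scene, `[[`, 0, "mean_pred"),
    map_r2 = vapply(per_scene, function(s) s$stats$r2, 0),
    map_rmse = vapply(per_scene, function(s) s$stats$rmse, 0),
    stringsAsFactors = FALSE)
  rng <- range(unlist(lapply(per_scene, function(s)
    s$map$values[s$map$mask$grid])))
  list(scenes = per_scene, stats = stats, scale = rng)
}

# stage caching: <out_dir>/cache_<name>.rds reused when the stored config
# matches the current one (manifest-style resume)
run_stage <- function(out_dir, config, name, code) {
  if (is.null(out_dir)) return(code())
  path <- file.path(out_dir, paste0("cache_", name, ".rds"))
  if (file.exists(path)) {
    cached <- readRDS(path)
    if (identical(cached$config, config)) return(cached$value)
  }
  value <- code()
  saveRDS(list(config = config, value = value), path)
  value
}

write_run_artifacts <- function(run, out_dir) {
  utils::write.csv(run$study$reference,
                   file.path(out_dir, "reference.csv"), row.names = FALSE)
  utils::write.csv(run$grid, file.path(out_dir, "grid.csv"),
                   row.names = FALSE)
  utils::write.csv(run$maps$stats, file.path(out_dir, "map_stats.csv"),
                   row.names = FALSE)
  for (s in run$maps$scenes)
    render_map(s$map, file.path(out_dir, paste0("map_", s$sample_id, ".png")),
               scale = run$maps$scale)
  manifest <- list(config = run$config, best = run$best,
                   r_version = as.character(getRversion()),
                   package_version = as.character(
                     utils::packageVersion("anthomap")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.study_run <- function(x, ...) {
  cat(sprintf("<study_run> %d samples, best model: %s\n",
              nrow(x$study$design), x$best))
  print(x$grid, digits = 4)
  invisible(x)
}
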