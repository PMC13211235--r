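# split a year vector into k near-equal contiguous period ranges
.default_periods <- function(years, k = 4L) {
  idx <- split(seq_along(years), cut(seq_along(years), k, labels = FALSE))
  out <- lapply(idx, function(i) range(years[i]))
  names(out) <- paste0("P", seq_len(k))
  out
}

#' Pipeline run configuration
#'
#' Collects every parameter of the end-to-end synthetic-scene analysis in
#' one (YAML-serializable) list: scene and phenology settings, period
#' definitions, classification thresholds, module settings and all seeds
#' (each derived from the master scene seed).
#'
#' @param out_dir Output directory for reports and rasters.
#' @param grid_rows,grid_cols,years,seed Scene settings (see
#'   [scene_config()]).
#' @param noise_sd Observation noise of the synthetic cube.
#' @param periods Named list of `c(first_year, last_year)` ranges; default
#'   four near-equal chunks of `years`.
#' @param thresholds Vigor-class cutpoints.
#' @param n_points,inside_prob Occurrence generation settings.
#' @param n_breaks,min_len Segmentation settings.
#' @param ensemble_size,noise_sd_frac EEMD settings.
#' @param n_trees Random-forest size.
#' @param boot PLS-PM bootstrap resamples.
#' @param patch_size,cnn_epochs,cv_folds Projection-model settings.
#' @param scenario_deltas Named list of future deltas (default
#'   [default_scenario_deltas()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("ephemrun"),
                            grid_rows = 32L, grid_cols = 32L,
                            years = 2001:2022, seed = 1L, noise_sd = 0.02,
                            periods = NULL, class_method = "jenks",
                            thresholds = c(0.1564, 0.1878),
                            n_points = 185L, inside_prob = 0.8216,
                            n_breaks = 3L, min_len = 3L,
                            ensemble_size = 50L, noise_sd_frac = 0.2,
                            n_trees = 300L, boot = 50L,
                            patch_size = 5L, cnn_epochs = 40L, cv_folds = 5L,
                            scenario_deltas = default_scenario_deltas()) {
  if (is.null(periods)) periods <- .default_periods(years)
  structure(list(out_dir = out_dir, grid_rows = grid_rows,
                 grid_cols = grid_cols, years = years, seed = seed,
                 noise_sd = noise_sd, periods = periods,
                 class_method = class_method,
                 thresholds = thresholds, n_points = n_points,
                 inside_prob = inside_prob, n_breaks = n_breaks,
                 min_len = min_len, ensemble_size = ensemble_size,
                 noise_sd_frac = noise_sd_frac, n_trees = n_trees,
                 boot = boot, patch_size = patch_size,
                 cnn_epochs = cnn_epochs, cv_folds = cv_folds,
                 scenario_deltas = scenario_deltas),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `path` / the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), "periods")])
  if (!is.null(raw$periods))
    cfg$periods <- lapply(raw$periods, as.numeric)
  cfg
}

#' Run the full synthetic-scene analysis pipeline
#'
#' Executes generate -> extract -> mask/classify -> validate -> temporal
#' dynamics -> spatial dynamics -> drivers -> projection on a synthetic
#' scene, writing CSV/ASCII-grid/JSON reports and a structured log (every
#' seed and parameter) under `config$out_dir`. All stages are seeded from
#' the master seed, so a rerun with the same configuration reproduces every
#' report bit-for-bit.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of
#'   `c("validate", "temporal", "spatial", "drivers", "project")` to run in
#'   addition to the always-on generation/extraction/classification core.
#' @return Invisibly, a list with all intermediate objects and the report.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("validate", "temporal", "spatial",
                                    "drivers", "project")) {
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "log.txt")
  cat("", file = logf)
  logmsg <- function(...) cat(paste0(format(Sys.time(), "%H:%M:%S "), ...,
                                     "\n"), file = logf, append = TRUE)
  fail <- function(stage, e) stop("pipeline stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)
  report <- list(seed = config$seed)

  # --- generate ------------------------------------------------------------
  res <- tryCatch({
    sc <- scene_config(config$grid_rows, config$grid_cols, years = config$years,
                       seed = config$seed)
    preset <- phenology_preset(noise_sd = config$noise_sd)
    spec <- env_effect_spec()
    env <- gen_env_rasters(sc, spec)
    cube <- gen_ndvi_cube(sc, preset, env)
    logmsg("generate: grid ", sc$grid_rows, "x", sc$grid_cols, ", years ",
           min(sc$years), "-", max(sc$years), ", master seed ", sc$seed,
           " (cube substream seed+11, env seed+23+i, occurrences seed+41)")
    list(scene = sc, preset = preset, env = env, cube = cube)
  }, error = function(e) fail("generate", e))

  # --- extract / mask / classify -------------------------------------------
  res <- tryCatch({
    eph <- ephemeral_ndvi_map(res$cube)
    mask <- build_distribution_mask(eph)
    cmap <- classify_ndvi(eph, mask, thresholds = config$thresholds,
                          method = config$class_method)
    # scene-derived cutpoints (natural breaks by default) are reused for
    # the period maps and the scenario classification
    config$thresholds <- cmap$thresholds
    geometry <- eph$geometry
    write_ascii_grid(mask$mask * 1, file.path(config$out_dir, "mask.asc"),
                     geometry)
    write_ascii_grid(cmap$codes, file.path(config$out_dir, "classes.asc"),
                     geometry)
    logmsg("extract: mask threshold ", signif(mask$threshold_value, 6),
           ", in-mask pixels ", sum(mask$mask),
           ", class thresholds ", paste(config$thresholds, collapse = "/"))
    report$mask_threshold <- mask$threshold_value
    report$in_mask_pixels <- sum(mask$mask)
    report$class_thresholds <- cmap$thresholds
    c(res, list(eph = eph, mask = mask, class_map = cmap))
  }, error = function(e) fail("extract", e))

  # --- occurrence validation -----------------------------------------------
  if ("validate" %in% stages) res <- tryCatch({
    occ <- gen_occurrences(res$mask, config$n_points, config$inside_prob,
                           seed = config$seed)
    acc <- validate_occurrences(res$mask, occ)
    utils::write.csv(acc, file.path(config$out_dir, "accuracy.csv"),
                     row.names = FALSE)
    overall <- acc$accuracy_pct[acc$family == "Sum"]
    logmsg("validate: ", nrow(occ), " occurrence points, overall accuracy ",
           overall, "% (inside_prob ", config$inside_prob, ")")
    report$overall_accuracy_pct <- overall
    c(res, list(occurrences = occ, accuracy = acc))
  }, error = function(e) fail("validate", e))

  # --- temporal dynamics ---------------------------------------------------
  if ("temporal" %in% stages) res <- tryCatch({
    ser <- annual_mean_series(res$eph, res$mask)
    seg <- piecewise_segments(ser, n_breaks = config$n_breaks,
                              min_len = config$min_len)
    dec <- eemd(ser$value, ensemble_size = config$ensemble_size,
                noise_sd_frac = config$noise_sd_frac,
                seed = config$seed + 7L)
    vc <- variance_contribution(dec)
    per <- vapply(seq_len(ncol(dec$imfs)),
                  function(k) suppressWarnings(mean_period(dec$imfs[, k])),
                  numeric(1))
    utils::write.csv(seg$segments, file.path(config$out_dir, "segments.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(component = names(vc),
                 period_years = c(per, NA_real_),
                 variance_pct = as.numeric(vc)),
      file.path(config$out_dir, "imf.csv"), row.names = FALSE)
    logmsg("temporal: breaks at ", paste(seg$breaks, collapse = ", "),
           "; ", ncol(dec$imfs), " IMFs (ensemble ", config$ensemble_size,
           ", noise frac ", config$noise_sd_frac, ", seed ",
           config$seed + 7L, ")")
    report$breakpoints <- seg$breaks
    report$imf_variance_pct <- as.numeric(vc)
    report$residual_slope_sign <- sign(utils::tail(dec$residual, 1) -
                                       dec$residual[1])
    c(res, list(series = ser, segmentation = seg, imf = dec))
  }, error = function(e) fail("temporal", e))

  # --- spatial dynamics ----------------------------------------------------
  if ("spatial" %in% stages) res <- tryCatch({
    pmaps <- lapply(config$periods, function(rng) {
      sel <- res$eph$years >= rng[1] & res$eph$years <= rng[2]
      val <- apply(res$eph$eph[, , sel, drop = FALSE], c(1, 2), mean,
                   na.rm = TRUE)
      classify_ndvi(val, res$mask, thresholds = config$thresholds)
    })
    cell_area <- res$eph$geometry$cell_size_km^2
    trans <- list()
    tr_rows <- list()
    for (i in seq_len(length(pmaps) - 1L)) {
      lab <- paste0(names(pmaps)[i], "_to_", names(pmaps)[i + 1L])
      tm <- transition_matrix(pmaps[[i]], pmaps[[i + 1L]], cell_area,
                              periods = names(pmaps)[i + 0:1])
      trans[[lab]] <- tm
      tr_rows[[lab]] <- data.frame(pair = lab,
                                   source = rep(rownames(tm$area), 3L),
                                   destination = rep(colnames(tm$area),
                                                     each = 3L),
                                   area_km2 = as.vector(tm$area))
    }
    utils::write.csv(do.call(rbind, tr_rows),
                     file.path(config$out_dir, "transitions.csv"),
                     row.names = FALSE)
    track <- centroid_track(pmaps, "Medium")
    utils::write.csv(track, file.path(config$out_dir, "centroids.csv"),
                     row.names = FALSE)
    cv <- cv_map(res$eph)
    write_ascii_grid(cv, file.path(config$out_dir, "cv.asc"),
                     res$eph$geometry)
    logmsg("spatial: ", length(trans), " transition matrices; Medium centroid",
           " track over ", length(pmaps), " periods; CV map written")
    report$medium_track_km <- track$dist_km[-1]
    c(res, list(period_maps = pmaps, transitions = trans,
                centroid_track = track, cv = cv))
  }, error = function(e) fail("spatial", e))

  # --- drivers -------------------------------------------------------------
  if ("drivers" %in% stages) res <- tryCatch({
    dt <- build_driver_table(res$eph, res$env, res$mask)
    imp <- rf_group_importance(dt, n_trees = config$n_trees,
                               seed = config$seed + 4L)
    pm <- pearson_matrix(dt)
    cats <- attr(dt, "categories")
    blocks <- c(list(NDVI = "NDVIeph"),
                split(names(cats), cats)[c("snow", "precipitation",
                                           "temperature", "topography")])
    lat <- names(blocks)
    A <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
    # assumed causal ordering: topography exogenous; temperature mediates;
    # snow and precipitation are the proximate moisture supplies
    A["topography", "temperature"] <- 1
    A["temperature", "precipitation"] <- 1
    A["temperature", "snow"] <- 1
    A[c("snow", "precipitation", "temperature", "topography"), "NDVI"] <- 1
    sem <- plspm_fit(dt, blocks, A, boot = config$boot,
                     seed = config$seed + 5L)
    utils::write.csv(imp$variable, file.path(config$out_dir, "importance.csv"),
                     row.names = FALSE)
    utils::write.csv(sem$effects, file.path(config$out_dir, "effects.csv"),
                     row.names = FALSE)
    logmsg("drivers: RF seed ", config$seed + 4L, " (", config$n_trees,
           " trees); PLS-PM GoF ", signif(sem$gof, 4), ", boot ",
           config$boot, " (seed ", config$seed + 5L, ")")
    report$category_contribution <- stats::setNames(
      imp$category$contribution_pct, imp$category$category)
    report$gof <- sem$gof
    report$total_effects <- stats::setNames(
      sem$effects$total[sem$effects$latent != "NDVI"],
      sem$effects$latent[sem$effects$latent != "NDVI"])
    c(res, list(driver_table = dt, importance = imp, pearson = pm, sem = sem))
  }, error = function(e) fail("drivers", e))

  # --- projection ----------------------------------------------------------
  if ("project" %in% stages) res <- tryCatch({
    stack <- predictor_stack(res$env$historical[.projection_vars],
                             res$eph$geometry)
    target <- apply(res$eph$eph, c(1, 2), mean, na.rm = TRUE)
    samples <- extract_patches(stack, target, config$patch_size)
    cvfit <- train_cv(samples, folds = config$cv_folds,
                      seed = config$seed + 6L,
                      config = cnn_config(epochs = config$cnn_epochs))
    tabs <- list()
    for (nm in names(config$scenario_deltas)) {
      fut <- gen_env_rasters(res$scene, res$env$spec,
                             future_delta = config$scenario_deltas[[nm]])
      fstack <- predictor_stack(fut$future[.projection_vars],
                                res$eph$geometry)
      parts <- strsplit(nm, "_")[[1]]
      pr <- project_scenario(cvfit$model, fstack,
                             thresholds = config$thresholds,
                             cell_area_km2 = res$eph$geometry$cell_size_km^2,
                             scenario = parts[1],
                             period = parts[length(parts)])
      tabs[[nm]] <- cbind(pr$table, mean_ndvi = pr$mean_ndvi)
    }
    scen <- do.call(rbind, tabs); rownames(scen) <- NULL
    utils::write.csv(scen, file.path(config$out_dir, "scenarios.csv"),
                     row.names = FALSE)
    logmsg("project: CV R2 ", signif(cvfit$summary$mean[1], 4), " +- ",
           signif(cvfit$summary$sd[1], 3), " (seed ", config$seed + 6L,
           "); ", length(tabs), " scenario tables")
    report$cv_r2 <- cvfit$summary$mean[1]
    report$cv_rmse <- cvfit$summary$mean[2]
    c(res, list(cv = cvfit, scenario_table = scen))
  }, error = function(e) fail("project", e))

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("done in ", round(report$elapsed_s, 1), " s")
  res$report <- report
  res$config <- config
  invisible(res)
}
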