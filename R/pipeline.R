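#' Default pipeline configuration
#'
#' Assembles the nested configuration consumed by the `cmd_*` stage
#' drivers: radar profile, noise model, PFE and STFT parameters, training
#' hyperparameters, dataset size and the working directory.  The
#' configuration round-trips through YAML via [read_run_config()] /
#' [write_run_config()].
#'
#' @param workdir directory for cubes, maps and reports.
#' @param master_seed master seed; every stage derives its own sub-seed
#'   from it (see [derive_seed()]).
#' @param n_per_class cubes per class.
#' @param profile `"desk"` (reduced-scale, default) or `"full"` radar
#'   profile.
#' @param ... overrides for any nested entry, e.g. `noise =
#'   list(snr_db = 5)`, `train = list(epochs = 10)`.
#' @return an object of class `run_config`.
#' @export
default_run_config <- function(workdir = "radarfall-run", master_seed = 1L,
                               n_per_class = 20L, profile = "desk", ...) {
  cfg <- list(
    master_seed = as.integer(master_seed),
    paths = list(workdir = workdir),
    radar = list(profile = profile),
    noise = list(snr_db = 15, clutter_amplitude = 0.3,
                 outlier_rate = 0.005, outlier_gain_db = 15),
    pfe = list(a = 0.25, hampel_k = 5L, hampel_nth = 3),
    stft = list(window_length = 32L, hop = 8L, window = "hann",
                fft_length = 64L),
    train = list(learning_rate = 5e-4, epochs = 50L, step_size = 10L,
                 gamma = 0.5, batch_size = 32L, split_fraction = 0.8),
    dataset = list(n_per_class = as.integer(n_per_class),
                   height_range = c(1.5, 1.9), walk_speed = 1.0),
    image_size = 54L, rt_decimate = 8L, range_crop = c(0.5, 7))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' @rdname default_run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  do.call(default_run_config,
          c(list(workdir = raw$paths$workdir %||% "radarfall-run",
                 master_seed = raw$master_seed %||% 1L),
            raw[setdiff(names(raw), c("paths", "master_seed"))]))
}

#' @rdname default_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cfg_radar <- function(cfg) {
  extra <- cfg$radar[setdiff(names(cfg$radar), "profile")]
  if (identical(cfg$radar$profile, "full")) do.call(radar_config, extra)
  else do.call(desk_radar_config, extra)
}
.cfg_noise <- function(cfg) do.call(noise_spec, cfg$noise)
.cfg_pfe <- function(cfg) {
  do.call(pfe_params, cfg$pfe[setdiff(names(cfg$pfe), "enabled")])
}
.cfg_stft <- function(cfg) do.call(stft_params, cfg$stft)
.cfg_train <- function(cfg, seed) {
  do.call(train_config, c(cfg$train, list(seed = seed)))
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# ---------------------------------------------------------------------------

#' Build an in-memory image dataset, cube by cube
#'
#' The streaming counterpart of [generate_dataset()]: for every sample it
#' synthesises the cube, derives the range-time and Doppler-time maps,
#' optionally injects speckle outliers and applies PFE cleaning, converts
#' the maps to network input tensors, and discards the cube.  Memory use
#' is therefore bounded by a single cube regardless of dataset size.
#'
#' @param n_per_class samples per class.
#' @param config a [radar_config()].
#' @param noise a [noise_spec()] or `NULL`.
#' @param pfe a [pfe_params()], or `NULL` to skip cleaning.
#' @param stft an [stft_params()].
#' @param height_range subject height range (m).
#' @param seed master seed.
#' @param walk_speed nominal walking speed (m/s).
#' @param size image side length.
#' @param rt_decimate slow-time decimation of the RT map columns.
#' @param range_crop length-2 range window (m) the RT images are cropped
#'   to before resampling (`NULL` keeps the full axis).
#' @param ablation if `TRUE`, also return the images of the uncleaned
#'   maps (`x_rt_raw`, `x_dt_raw`) computed from the very same cubes, for
#'   with/without-PFE comparisons.
#' @return list with arrays `x_rt`, `x_dt` of dimension
#'   `c(size, size, 3, N)`, factor `labels`, the `manifest`, and (when
#'   `ablation`) `x_rt_raw`, `x_dt_raw`.
#' @export
build_image_dataset <- function(n_per_class, config = desk_radar_config(),
                                noise = noise_spec(), pfe = pfe_params(),
                                stft = stft_params(),
                                height_range = c(1.5, 1.9), seed = 1L,
                                walk_speed = 1.0, size = 54L,
                                rt_decimate = 8L, range_crop = c(0.5, 7),
                                ablation = FALSE) {
  manifest <- dataset_manifest(n_per_class, height_range, seed)
  n <- nrow(manifest)
  rt <- vector("list", n); dt <- vector("list", n)
  rt_raw <- vector("list", n); dt_raw <- vector("list", n)
  for (i in seq_len(n)) {
    maps <- .sample_maps(manifest[i, ], config, noise, stft, rt_decimate,
                         walk_speed, range_crop)
    if (ablation || is.null(pfe)) {
      rt_raw[[i]] <- preprocess_map(maps$rt, size)
      dt_raw[[i]] <- preprocess_map(maps$dt, size)
    }
    if (!is.null(pfe)) {
      rt[[i]] <- preprocess_map(pfe_clean(maps$rt, pfe), size)
      dt[[i]] <- preprocess_map(pfe_clean(maps$dt, pfe), size)
    }
  }
  out <- list(labels = factor(manifest$label, levels = fall_labels()),
              manifest = manifest)
  if (!is.null(pfe)) {
    out$x_rt <- stack_images(rt)
    out$x_dt <- stack_images(dt)
  } else {
    out$x_rt <- stack_images(rt_raw)
    out$x_dt <- stack_images(dt_raw)
  }
  if (ablation) {
    out$x_rt_raw <- stack_images(rt_raw)
    out$x_dt_raw <- stack_images(dt_raw)
  }
  out
}

# cube -> (RT, DT) maps with optional speckle injection
.sample_maps <- function(row, config, noise, stft, rt_decimate, walk_speed,
                         range_crop = NULL) {
  cube <- .cube_from_manifest_row(row, config, noise, walk_speed)
  rt <- range_time_map(cube, decimate = rt_decimate)
  if (!is.null(range_crop)) rt <- crop_map(rt, range_crop[1], range_crop[2])
  dt <- doppler_time_map(cube, stft)
  if (!is.null(noise) && noise$outlier_rate > 0) {
    rt <- inject_outliers(rt, noise$outlier_rate, noise$outlier_gain_db,
                          seed = derive_seed(row$seed, "rt_outliers"))
    dt <- inject_outliers(dt, noise$outlier_rate, noise$outlier_gain_db,
                          seed = derive_seed(row$seed, "dt_outliers"))
  }
  list(rt = rt, dt = dt)
}

# ---------------------------------------------------------------------------

#' Pipeline stage drivers
#'
#' `cmd_simulate()` writes the labelled data cubes and the manifest;
#' `cmd_featurize()` turns cubes into (optionally PFE-cleaned) RT/DT
#' maps; `cmd_train_eval()` trains the dual-branch network on the maps
#' and writes the evaluation artifacts; `verify_artifacts()` checks that
#' the on-disk artifacts match what the configuration would regenerate;
#' `run_all()` chains the three stages.  Every artifact is a
#' deterministic function of `(config, master_seed)`.
#'
#' @param config a [default_run_config()].
#' @param no_pfe skip the PFE cleaning stage (the ablation arm); maps and
#'   reports are then written alongside the cleaned ones under
#'   `*-nopfe` names.
#' @return `cmd_simulate()` the manifest; `cmd_featurize()` a status list
#'   with `n_ok` and `missing`; `cmd_train_eval()` a list with the fitted
#'   model and the report; `verify_artifacts()` a logical.
#' @name pipeline
NULL

.dirs <- function(cfg, no_pfe = FALSE) {
  wd <- cfg$paths$workdir
  list(wd = wd, cubes = file.path(wd, "cubes"),
       maps = file.path(wd, if (no_pfe) "maps-nopfe" else "maps"),
       reports = file.path(wd, "reports"),
       manifest = file.path(wd, "manifest.csv"))
}

#' @rdname pipeline
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  d <- .dirs(config)
  dir.create(d$cubes, recursive = TRUE, showWarnings = FALSE)
  radar <- .cfg_radar(config)
  noise <- .cfg_noise(config)
  manifest <- dataset_manifest(config$dataset$n_per_class,
                               config$dataset$height_range,
                               derive_seed(config$master_seed, "simulate"))
  t0 <- Sys.time()
  for (i in seq_len(nrow(manifest))) {
    cube <- .cube_from_manifest_row(manifest[i, ], radar, noise,
                                    config$dataset$walk_speed)
    saveRDS(cube, file.path(d$cubes, paste0(manifest$sample_id[i], ".rds")))
  }
  write.csv(manifest, d$manifest, row.names = FALSE)
  for (lb in fall_labels())
    log_stage("simulate", "%s: %d cubes", lb, sum(manifest$label == lb))
  log_stage("simulate", "seed %d, %d cubes in %.1f s",
            config$master_seed, nrow(manifest),
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(manifest)
}

#' @rdname pipeline
#' @export
cmd_featurize <- function(config, no_pfe = FALSE) {
  stopifnot(inherits(config, "run_config"))
  d <- .dirs(config, no_pfe)
  if (!file.exists(d$manifest)) stopf("no manifest at %s; run cmd_simulate first",
                                      d$manifest)
  manifest <- read.csv(d$manifest, stringsAsFactors = FALSE)
  dir.create(d$maps, recursive = TRUE, showWarnings = FALSE)
  noise <- .cfg_noise(config)
  stft <- .cfg_stft(config)
  pfe <- if (no_pfe) NULL else .cfg_pfe(config)
  missing <- character(0)
  n_ok <- 0L
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$sample_id[i]
    cube_path <- file.path(d$cubes, paste0(id, ".rds"))
    if (!file.exists(cube_path)) {
      missing <- c(missing, cube_path)
      next
    }
    cube <- readRDS(cube_path)
    rt <- range_time_map(cube, decimate = config$rt_decimate)
    if (!is.null(config$range_crop))
      rt <- crop_map(rt, config$range_crop[1], config$range_crop[2])
    dt <- doppler_time_map(cube, stft)
    if (noise$outlier_rate > 0) {
      rt <- inject_outliers(rt, noise$outlier_rate, noise$outlier_gain_db,
                            seed = derive_seed(manifest$seed[i], "rt_outliers"))
      dt <- inject_outliers(dt, noise$outlier_rate, noise$outlier_gain_db,
                            seed = derive_seed(manifest$seed[i], "dt_outliers"))
    }
    if (!is.null(pfe)) {
      rt <- pfe_clean(rt, pfe)
      dt <- pfe_clean(dt, pfe)
    }
    saveRDS(list(rt = rt, dt = dt, label = manifest$label[i]),
            file.path(d$maps, paste0(id, ".rds")))
    n_ok <- n_ok + 1L
  }
  if (length(missing) > 0)
    warnf("cmd_featurize: %d cube(s) missing, skipped:\n  %s",
          length(missing), paste(missing, collapse = "\n  "))
  log_stage("featurize", "%d cubes -> %d map pairs%s", nrow(manifest),
            n_ok, if (no_pfe) " (PFE disabled)" else "")
  invisible(list(n_ok = n_ok, missing = missing))
}

#' @rdname pipeline
#' @export
cmd_train_eval <- function(config, no_pfe = FALSE) {
  stopifnot(inherits(config, "run_config"))
  d <- .dirs(config, no_pfe)
  manifest <- read.csv(d$manifest, stringsAsFactors = FALSE)
  paths <- file.path(d$maps, paste0(manifest$sample_id, ".rds"))
  ok <- file.exists(paths)
  if (sum(ok) == 0L) stopf("no maps under %s; run cmd_featurize first", d$maps)
  labels <- manifest$label[ok]
  if (length(unique(labels)) < 2L)
    stopf("maps cover %d class(es); need at least 2", length(unique(labels)))
  size <- config$image_size
  rt <- vector("list", sum(ok)); dt <- vector("list", sum(ok))
  for (i in seq_along(which(ok))) {
    m <- readRDS(paths[which(ok)[i]])
    rt[[i]] <- preprocess_map(m$rt, size)
    dt[[i]] <- preprocess_map(m$dt, size)
  }
  x_rt <- stack_images(rt)
  x_dt <- stack_images(dt)
  seed <- derive_seed(config$master_seed, "train")
  tc <- .cfg_train(config, seed)
  split <- stratified_split(labels, tc$split_fraction, seed)
  if (min(table(labels[split$train])) < 1 || length(split$test) < 1)
    stopf("class imbalance: a class has no samples in one split")
  model <- fall_cnn(x_rt[, , , split$train, drop = FALSE],
                    x_dt[, , , split$train, drop = FALSE],
                    labels[split$train], tc,
                    validation = list(x_rt = x_rt[, , , split$test, drop = FALSE],
                                      x_dt = x_dt[, , , split$test, drop = FALSE],
                                      labels = labels[split$test]))
  report <- evaluate_classifier(model, x_rt[, , , split$test, drop = FALSE],
                                x_dt[, , , split$test, drop = FALSE],
                                labels[split$test])
  dir.create(d$reports, recursive = TRUE, showWarnings = FALSE)
  tag <- if (no_pfe) "-nopfe" else ""
  saveRDS(model, file.path(d$reports, paste0("model", tag, ".rds")))
  jsonlite::write_json(list(network = network_dims(size),
                            train = unclass(tc), split = split),
                       file.path(d$reports, paste0("model", tag, ".json")),
                       auto_unbox = TRUE, digits = NA)
  write.csv(model$history,
            file.path(d$reports, paste0("history", tag, ".csv")),
            row.names = FALSE)
  write_report(report,
               csv_path = file.path(d$reports, paste0("report", tag, ".csv")),
               json_path = file.path(d$reports, paste0("report", tag, ".json")))
  log_stage("train", "seed %d, %d train / %d test", seed,
            length(split$train), length(split$test))
  print(report)
  invisible(list(model = model, report = report))
}

#' @rdname pipeline
#' @export
verify_artifacts <- function(config) {
  stopifnot(inherits(config, "run_config"))
  d <- .dirs(config)
  if (!file.exists(d$manifest)) {
    log_stage("verify", "no manifest at %s", d$manifest)
    return(invisible(FALSE))
  }
  stored <- read.csv(d$manifest, stringsAsFactors = FALSE)
  expected <- dataset_manifest(config$dataset$n_per_class,
                               config$dataset$height_range,
                               derive_seed(config$master_seed, "simulate"))
  ok_manifest <- isTRUE(all.equal(stored, expected, tolerance = 1e-8))
  cube_files <- file.path(d$cubes, paste0(expected$sample_id, ".rds"))
  ok_cubes <- all(file.exists(cube_files))
  log_stage("verify", "manifest %s, cubes %s",
            if (ok_manifest) "ok" else "MISMATCH",
            if (ok_cubes) "complete" else "incomplete")
  invisible(ok_manifest && ok_cubes)
}

#' @rdname pipeline
#' @export
run_all <- function(config, no_pfe = FALSE) {
  cmd_simulate(config)
  cmd_featurize(config, no_pfe = no_pfe)
  cmd_train_eval(config, no_pfe = no_pfe)
}
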