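#' Beat frequency of a point target
#'
#' For a linear chirp of slope beta, an echo delayed by `td = 2 d / c`
#' mixes down to a beat tone `fb = beta * td = beta * 2 d / c`.
#'
#' @param distance_m radial distance(s) in metres; must be positive.
#' @param config a [radar_config()].
#' @return beat frequency in Hz (vectorised over `distance_m`).
#' @seealso [range_from_beat()] for the inverse.
#' @export
beat_frequency <- function(distance_m, config) {
  stopifnot(inherits(config, "radar_config"))
  if (!is.numeric(distance_m) || any(!is.finite(distance_m)) ||
      any(distance_m <= 0))
    stopf("beat_frequency: distances must be positive and finite")
  config$chirp_slope * 2 * distance_m / .c0
}

#' Synthesise the complex baseband data cube for one trajectory
#'
#' Writes, for every chirp m at slow time t_m, the fast-time samples of a
#' complex exponential at the beat frequency of the instantaneous range
#' d(t_m), with the slow-time phase advancing as `4 pi fc d(t_m) / c`.
#' That phase progression is what encodes Doppler: its derivative is
#' `(2 fc / c) dd/dt`, negative while the target approaches.  Echo
#' amplitude follows a `1/d^2` law normalised to 1 at the starting range.
#' Optionally adds complex white Gaussian noise at the requested SNR and
#' a static clutter return at a fixed range (2.5 m).
#'
#' @param trajectory a [fall_trajectory()]; must cover the full record.
#' @param config a [radar_config()].
#' @param noise a [noise_spec()], or `NULL` for a clean cube.
#' @param seed integer seed; identical `(trajectory, config, noise, seed)`
#'   give bit-identical cubes.
#' @param target_amplitude echo amplitude at the starting range (set to 0
#'   for a noise-only cube).
#' @return an object of class `radar_cube`: complex matrix `samples`
#'   (fast time x slow time) plus config, provenance and seed.
#' @export
synthesize_cube <- function(trajectory, config, noise = NULL, seed = 1L,
                            target_amplitude = 1) {
  stopifnot(inherits(trajectory, "fall_trajectory"),
            inherits(config, "radar_config"))
  if (!is.null(noise) && !inherits(noise, "noise_spec"))
    stopf("`noise` must be a noise_spec or NULL")
  nch <- n_chirps(config)
  ns <- config$samples_per_chirp
  ti <- chirp_interval(config)
  span <- record_duration(config)
  if (trajectory$duration < span - 1e-9)
    stopf("trajectory covers %.3f s but the record spans %.3f s",
          trajectory$duration, span)

  t_m <- (seq_len(nch) - 1) * ti
  d_m <- trajectory$d_of_t(t_m)
  if (any(!is.finite(d_m)) || any(d_m <= 0))
    stopf("trajectory range must stay positive and finite over the record")
  # continuity guard: a physical walk/fall cannot jump between chirps.
  # The speed bound covers walking and the fall's own peak radial speed
  # (half-cosine profile peaks at pi * excursion / (2 * duration)).
  v_fall <- if (is.finite(trajectory$excursion) &&
                trajectory$fall_duration > 0)
    pi * abs(trajectory$excursion) / (2 * trajectory$fall_duration) else 0
  step_bound <- 10 * max(trajectory$walk_speed, v_fall, 1) * ti
  if (max(abs(diff(d_m))) > step_bound)
    stopf("trajectory is discontinuous at the chirp scale (max step %.2g m > bound %.2g m)",
          max(abs(diff(d_m))), step_bound)

  tau <- (seq_len(ns) - 1) / config$sample_rate
  fb <- beat_frequency(d_m, config)
  amp <- target_amplitude * (d_m[1] / d_m)^2
  # fast-time tone per chirp + slow-time carrier phase
  phase_slow <- 4 * pi * config$start_frequency * d_m / .c0
  cube <- exp(1i * (outer(2 * pi * tau, fb) +
                    matrix(phase_slow, ns, nch, byrow = TRUE)))
  cube <- cube * matrix(amp, ns, nch, byrow = TRUE)

  if (!is.null(noise)) {
    with_seed(seed, {
      if (noise$clutter_amplitude > 0) {
        fb_cl <- beat_frequency(2.5, config)
        cube <- cube + noise$clutter_amplitude *
          exp(1i * 2 * pi * fb_cl * tau)  # recycled down columns
      }
      sig_pow <- if (target_amplitude > 0) mean(amp^2) else 1
      sigma <- sqrt(sig_pow * 10^(-noise$snr_db / 10) / 2)
      cube <- cube + complex(real = rnorm(ns * nch, sd = sigma),
                             imaginary = rnorm(ns * nch, sd = sigma))
    })
  }
  stopifnot(all(is.finite(Re(cube))), all(is.finite(Im(cube))))
  structure(list(samples = cube, config = config,
                 trajectory_id = paste(trajectory$label,
                                       trajectory$approach, sep = "/"),
                 label = trajectory$label, approach = trajectory$approach,
                 subject_height = trajectory$subject_height,
                 fall_onset = trajectory$fall_onset,
                 fall_duration = trajectory$fall_duration,
                 noise = noise, seed = as.integer(seed)),
            class = "radar_cube")
}

#' @export
print.radar_cube <- function(x, ...) {
  cat(sprintf("<radar_cube> %s, %d x %d (fast x slow), seed %d\n",
              x$trajectory_id, nrow(x$samples), ncol(x$samples), x$seed))
  invisible(x)
}

#' Generate a balanced, labelled set of radar data cubes
#'
#' Draws `n_per_class` trajectories per fall class (motion classes
#' alternate toward/away approaches, which are merged under one label),
#' synthesises the corresponding data cubes, and returns them together
#' with a manifest recording label, approach, subject height and
#' per-sample seed.  All randomness derives from `seed`; two calls with
#' the same arguments produce identical manifests and cubes.
#'
#' @param n_per_class cubes per class (5 classes).
#' @param config a [radar_config()]; default the desk-scale profile.
#' @param noise a [noise_spec()] or `NULL`.
#' @param height_range subject heights drawn uniformly from this range (m).
#' @param seed master seed.
#' @param walk_speed nominal walking speed (m/s).
#' @return an object of class `radar_dataset`: list with `cubes` (list of
#'   `radar_cube`), `labels` (character) and `manifest` (data frame with
#'   columns sample_id, label, approach, height_m, seed).
#' @export
generate_dataset <- function(n_per_class = 4, config = desk_radar_config(),
                             noise = noise_spec(), height_range = c(1.5, 1.9),
                             seed = 1L, walk_speed = 1.0) {
  manifest <- dataset_manifest(n_per_class, height_range, seed)
  cubes <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    cubes[[i]] <- .cube_from_manifest_row(manifest[i, ], config, noise,
                                          walk_speed)
  }
  structure(list(cubes = cubes, labels = manifest$label,
                 manifest = manifest, config = config, noise = noise),
            class = "radar_dataset")
}

# deterministic plan for a balanced dataset: one row per sample
dataset_manifest <- function(n_per_class, height_range, seed) {
  if (!is_count(n_per_class)) stopf("n_per_class must be a count >= 1")
  labels <- rep(fall_labels(), each = n_per_class)
  approach <- unlist(lapply(fall_labels(), function(lb) {
    if (lb == "nonmotion_fall") rep("static", n_per_class)
    else rep_len(c("toward_radar", "away_from_radar"), n_per_class)
  }))
  n <- length(labels)
  with_seed(seed, {
    heights <- runif(n, height_range[1], height_range[2])
    seeds <- sample.int(2^31 - 2, n)
  })
  data.frame(sample_id = sprintf("s%04d", seq_len(n)), label = labels,
             approach = approach, height_m = round(heights, 4),
             seed = seeds, stringsAsFactors = FALSE)
}

.cube_from_manifest_row <- function(row, config, noise, walk_speed) {
  tr <- trajectory_template(row$label, row$approach,
                            subject_height = row$height_m,
                            walk_speed = walk_speed, seed = row$seed,
                            duration = record_duration(config) + 1e-6)
  synthesize_cube(tr, config, noise, seed = row$seed)
}

#' @export
print.radar_dataset <- function(x, ...) {
  cat(sprintf("<radar_dataset> %d cubes (%d per class)\n",
              length(x$cubes), length(x$cubes) / 5L))
  print(table(x$manifest$label))
  invisible(x)
}
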