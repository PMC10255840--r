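#' Range from beat frequency
#'
#' Inverse of [beat_frequency()]: `d = c * fb / (2 beta)`.
#'
#' @param fb_hz beat frequency in Hz; must be non-negative.
#' @param config a [radar_config()].
#' @return distance in metres (vectorised).
#' @export
range_from_beat <- function(fb_hz, config) {
  stopifnot(inherits(config, "radar_config"))
  if (!is.numeric(fb_hz) || any(!is.finite(fb_hz)) || any(fb_hz < 0))
    stopf("range_from_beat: frequencies must be non-negative and finite")
  .c0 * fb_hz / (2 * config$chirp_slope)
}

#' Short-time Fourier transform parameters for the Doppler-time map
#'
#' @param window_length sliding-window length in chirps.
#' @param hop hop between window positions, in chirps.
#' @param window taper name; `"hann"` or `"rect"`.
#' @param fft_length FFT length (>= `window_length`; zero-padded).
#' @return an object of class `stft_params`.
#' @export
stft_params <- function(window_length = 32L, hop = 8L, window = "hann",
                        fft_length = 64L) {
  if (!is_count(window_length) || !is_count(hop) || !is_count(fft_length))
    stopf("stft_params: window_length, hop and fft_length must be counts")
  if (hop > window_length)
    stopf("stft_params: hop (%d) must not exceed window_length (%d)",
          hop, window_length)
  if (fft_length < window_length)
    stopf("stft_params: fft_length (%d) must be >= window_length (%d)",
          fft_length, window_length)
  window <- match.arg(window, c("hann", "rect"))
  structure(list(window_length = as.integer(window_length),
                 hop = as.integer(hop), window = window,
                 fft_length = as.integer(fft_length)),
            class = "stft_params")
}

# internal feature-map constructor; values in dB, axes physical
feature_map <- function(values, kind, feature_axis, time_axis, provenance) {
  stopifnot(kind %in% c("RT", "DT"),
            nrow(values) == length(feature_axis),
            ncol(values) == length(time_axis))
  structure(list(values = values, kind = kind, feature_axis = feature_axis,
                 time_axis = time_axis, provenance = provenance),
            class = "feature_map")
}

# convert a linear power matrix to decibels above the floor: values lie
# in [0, floor_db] with the map maximum at floor_db and the floor
# (floor_db below the maximum) at 0.  Keeping map values non-negative is
# what makes the additive adaptive threshold of the PFE stage behave as
# a between-mean-and-max cut.  With floor_db = Inf the raw 10*log10
# power is returned instead (used where exact power bookkeeping
# matters).  An all-zero map collapses to a flat floor.
power_to_db <- function(p, floor_db = 60) {
  pmax <- max(p)
  if (pmax <= 0) return(matrix(0, nrow(p), ncol(p)))
  if (!is.finite(floor_db)) return(10 * log10(p))
  v <- 10 * log10(p / pmax) + floor_db
  v[v < 0] <- 0
  v
}

#' Range-time map (fast-time DFT)
#'
#' Applies a DFT along fast time to every chirp and stacks the
#' magnitude-squared spectra over slow time, giving range-bin power
#' against observation time.  Values are stored in decibels above a
#' floor `floor_db` below the map maximum (so they are non-negative,
#' with the maximum at `floor_db`); with `floor_db = Inf` the raw
#' `10*log10` power is kept, and since the DFT is unitary (`1/sqrt(N)`)
#' the total linear power of that map equals the cube power exactly
#' (Parseval).  Range calibration follows the range equation: bin k sits
#' at `k * range_bin_width(config)`.
#'
#' @param cube a [synthesize_cube()] result.
#' @param clutter_suppress subtract the per-range slow-time complex mean
#'   before forming power (removes static returns).
#' @param decimate keep every `decimate`-th chirp column (display/training
#'   economy; 1 keeps all).
#' @param floor_db dB floor below the map maximum (`Inf` disables).
#' @return a `feature_map` with `kind = "RT"`, feature axis in metres.
#' @export
range_time_map <- function(cube, clutter_suppress = FALSE, decimate = 1L,
                           floor_db = 60) {
  stopifnot(inherits(cube, "radar_cube"))
  x <- cube$samples
  if (length(x) == 0L) stopf("empty cube")
  if (!is_count(decimate)) stopf("decimate must be a count >= 1")
  idx <- seq(1L, ncol(x), by = as.integer(decimate))
  f <- stats::mvfft(x[, idx, drop = FALSE]) / sqrt(nrow(x))
  if (clutter_suppress) f <- f - rowMeans(f)
  vals <- power_to_db(Mod(f)^2, floor_db)
  feature_map(vals, "RT",
              feature_axis = (seq_len(nrow(x)) - 1) * range_bin_width(cube$config),
              time_axis = (idx - 1) * chirp_interval(cube$config),
              provenance = list(trajectory_id = cube$trajectory_id,
                                seed = cube$seed,
                                clutter_suppress = clutter_suppress,
                                decimate = as.integer(decimate),
                                floor_db = floor_db))
}

#' Doppler-time map (slow-time STFT)
#'
#' Sums the complex slow-time signal over the active range gate and runs
#' a short-time Fourier transform over it: for each window position, the
#' windowed segment is Fourier-transformed and the zero-Doppler bin is
#' centred, giving Doppler power against time.  The Doppler axis spans
#' +/- half the chirp repetition frequency; by the phase convention of
#' [synthesize_cube()], Doppler carries the sign of the range rate
#' (negative while approaching).
#'
#' The active gate is the set of range bins whose slow-time variance
#' exceeds the median variance (moving returns); if the cube is
#' slow-time-deterministic (noiseless static scene) the gate falls back
#' to bins whose mean power exceeds the median power.
#'
#' @param cube a [synthesize_cube()] result.
#' @param params an [stft_params()].
#' @param floor_db dB floor below the map maximum (`Inf` disables).
#' @return a `feature_map` with `kind = "DT"`, feature axis in Hz.
#' @export
doppler_time_map <- function(cube, params = stft_params(), floor_db = 60) {
  stopifnot(inherits(cube, "radar_cube"), inherits(params, "stft_params"))
  x <- cube$samples
  nch <- ncol(x)
  win <- params$window_length
  if (win > nch)
    stopf("STFT window (%d chirps) longer than the record (%d chirps)",
          win, nch)

  # range bins (fast-time DFT), then the active range gate: bins whose
  # slow-time variance exceeds the median (moving returns)
  f <- stats::mvfft(x) / sqrt(nrow(x))
  mu <- rowMeans(f)
  v <- rowMeans(Mod(f - mu)^2)
  p <- rowMeans(Mod(f)^2)
  gate <- if (max(v) >= 1e-12 * max(p)) v > median(v) else p > median(p)
  if (!any(gate)) gate <- rep(TRUE, nrow(f))
  z <- colSums(f[gate, , drop = FALSE])

  w <- if (params$window == "hann") {
    0.5 * (1 - cos(2 * pi * (seq_len(win) - 1) / (win - 1)))
  } else rep(1, win)
  starts <- seq(1L, nch - win + 1L, by = params$hop)
  seg <- matrix(0i, params$fft_length, length(starts))
  for (k in seq_along(starts)) {
    seg[seq_len(win), k] <- z[starts[k]:(starts[k] + win - 1L)] * w
  }
  sp <- stats::mvfft(seg) / sqrt(win)
  nf <- params$fft_length
  shift <- c((nf / 2 + 1):nf, 1:(nf / 2))  # centre the zero-Doppler bin
  prf <- 1 / chirp_interval(cube$config)
  feature_map(power_to_db(Mod(sp[shift, , drop = FALSE])^2, floor_db), "DT",
              feature_axis = (seq_len(nf) - 1 - nf / 2) * prf / nf,
              time_axis = (starts - 1 + win / 2) * chirp_interval(cube$config),
              provenance = list(trajectory_id = cube$trajectory_id,
                                seed = cube$seed, stft = unclass(params),
                                gate_bins = sum(gate), floor_db = floor_db))
}

#' Inject speckle outliers into a feature map
#'
#' Sets randomly chosen cells to `mean(values) + gain_db`, emulating the
#' isolated interference specks that the Hampel stage of the PFE cleaner
#' is designed to remove.  The injection mask is recorded in the map
#' provenance (`provenance$outlier_mask`).
#'
#' @param map a `feature_map`.
#' @param rate per-cell injection probability, in `[0, 0.05]`.
#' @param gain_db speckle level in dB above the map mean.
#' @param seed integer seed.
#' @return the modified `feature_map`.
#' @export
inject_outliers <- function(map, rate, gain_db = 15, seed = 1L) {
  stopifnot(inherits(map, "feature_map"))
  if (rate < 0 || rate > 0.05) stopf("outlier rate must lie in [0, 0.05]")
  v <- map$values
  mask <- with_seed(seed, matrix(runif(length(v)) < rate, nrow(v), ncol(v)))
  v[mask] <- mean(map$values) + gain_db
  map$values <- v
  map$provenance$outlier_mask <- mask
  map$provenance$outlier_gain_db <- gain_db
  map
}

#' @export
print.feature_map <- function(x, ...) {
  unit <- if (x$kind == "RT") "m" else "Hz"
  cat(sprintf("<feature_map %s> %d bins x %d time steps, %.3g..%.3g %s, %.2f..%.2f s\n",
              x$kind, nrow(x$values), ncol(x$values), min(x$feature_axis),
              max(x$feature_axis), unit, min(x$time_axis), max(x$time_axis)))
  cat(sprintf("  power %.1f .. %.1f dB%s\n", min(x$values), max(x$values),
              if (!is.null(x$provenance$pfe)) " (PFE-cleaned)" else ""))
  invisible(x)
}

#' @param x a `feature_map`.
#' @param col colour palette.
#' @param ... passed to [graphics::image()].
#' @rdname range_time_map
#' @export
plot.feature_map <- function(x, col = hcl.colors(64, "viridis"), ...) {
  image(x$time_axis, x$feature_axis, t(x$values), col = col,
        xlab = "time (s)",
        ylab = if (x$kind == "RT") "range (m)" else "Doppler (Hz)",
        main = paste0(x$kind, " map"), useRaster = TRUE, ...)
  invisible(x)
}

#' Render a feature map to an 8-bit grayscale PNG
#'
#' Values are min-max scaled to `[0, 1]`; the feature axis runs bottom to
#' top, time left to right.
#'
#' @param map a `feature_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
render_png <- function(map, path) {
  stopifnot(inherits(map, "feature_map"))
  v <- map$values
  rng <- range(v)
  img <- if (rng[1] == rng[2]) matrix(0.5, nrow(v), ncol(v))
         else (v - rng[1]) / (rng[2] - rng[1])
  png::writePNG(img[rev(seq_len(nrow(img))), , drop = FALSE], path)
  invisible(path)
}

#' Crop a feature map along its feature axis
#'
#' Restricts the map to feature-axis values inside `[from, to]`.  Used to
#' focus RT images on the range band the scene actually occupies before
#' resampling them for the classifier: without it, a few-metre scene
#' occupies a sliver of the full unambiguous range span.
#'
#' @param map a `feature_map`.
#' @param from,to feature-axis bounds (same unit as the axis).
#' @return the cropped `feature_map`.
#' @export
crop_map <- function(map, from, to) {
  stopifnot(inherits(map, "feature_map"), from < to)
  keep <- map$feature_axis >= from & map$feature_axis <= to
  if (!any(keep)) stopf("crop window [%g, %g] empty", from, to)
  map$values <- map$values[keep, , drop = FALSE]
  if (!is.null(map$provenance$outlier_mask))
    map$provenance$outlier_mask <-
      map$provenance$outlier_mask[keep, , drop = FALSE]
  map$feature_axis <- map$feature_axis[keep]
  map$provenance$crop <- c(from, to)
  map
}

#' Ridge (per-column argmax) of a feature map
#'
#' For RT maps this traces the dominant range of the target over time;
#' the class templates differ in whether this trace is monotone or
#' reverses at the fall.
#'
#' @param map a `feature_map`.
#' @return numeric vector of feature-axis values, one per time step.
#' @export
map_ridge <- function(map) {
  stopifnot(inherits(map, "feature_map"))
  map$feature_axis[apply(map$values, 2, which.max)]
}
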