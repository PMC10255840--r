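#' FMCW radar chirp and frame parameters
#'
#' Describes the linear-chirp waveform and the frame structure of the
#' radar.  The defaults are the IWR6843-style 60 GHz parameter set used
#' throughout the package: 3.015 GHz sweep at 50.259 MHz/us, 256 complex
#' samples per chirp at 5 MHz, 128 chirps per frame, 100 us idle time
#' between chirps.
#'
#' The chirp slope `chirp_slope` should equal `bandwidth / chirp_duration`;
#' a deviation beyond 1% triggers a warning (the waveform is then
#' internally inconsistent).  The ADC may sample only part of the ramp
#' (`samples_per_chirp / sample_rate <= chirp_duration`); range-bin
#' calibration uses the *sampled* bandwidth
#' `chirp_slope * samples_per_chirp / sample_rate`.
#'
#' @param start_frequency chirp start frequency fc (Hz).
#' @param bandwidth swept bandwidth B (Hz).
#' @param chirp_slope chirp slope beta (Hz/s).
#' @param chirp_duration ramp duration Tc (s).
#' @param sample_rate complex baseband sampling rate (Hz).
#' @param samples_per_chirp fast-time samples recorded per chirp.
#' @param chirps_per_frame slow-time chirps per frame.
#' @param n_frames number of frames in one recording.
#' @param idle_time idle time between consecutive chirps (s).
#' @param rx_channels,tx_channels antenna counts (kept as metadata; a
#'   single receive channel is synthesised).
#' @return an object of class `radar_config`.
#' @seealso [desk_radar_config()] for the reduced-scale profile used in
#'   examples and simulation studies.
#' @examples
#' cfg <- radar_config(n_frames = 4)
#' range_bin_width(cfg)
#' @export
radar_config <- function(start_frequency = 60e9,
                         bandwidth = 3.015e9,
                         chirp_slope = 50.259e12,
                         chirp_duration = 60e-6,
                         sample_rate = 5e6,
                         samples_per_chirp = 256L,
                         chirps_per_frame = 128L,
                         n_frames = 488L,
                         idle_time = 100e-6,
                         rx_channels = 4L,
                         tx_channels = 1L) {
  for (nm in c("start_frequency", "bandwidth", "chirp_slope",
               "chirp_duration", "sample_rate", "idle_time")) {
    v <- get(nm)
    if (!is_pos(v) && !(nm == "idle_time" && is.numeric(v) && v >= 0))
      stopf("radar_config: `%s` must be a positive finite scalar", nm)
  }
  for (nm in c("samples_per_chirp", "chirps_per_frame", "n_frames",
               "rx_channels", "tx_channels")) {
    if (!is_count(get(nm)))
      stopf("radar_config: `%s` must be a count >= 1", nm)
  }
  implied <- bandwidth / chirp_duration
  if (abs(chirp_slope - implied) / implied > 0.01)
    warnf(paste("radar_config: chirp_slope (%.4g Hz/s) deviates from",
                "bandwidth/chirp_duration (%.4g Hz/s) by more than 1%%"),
          chirp_slope, implied)
  if (samples_per_chirp / sample_rate > chirp_duration + 1e-12)
    stopf("radar_config: ADC window %.3g s exceeds chirp duration %.3g s",
          samples_per_chirp / sample_rate, chirp_duration)
  structure(list(
    start_frequency = start_frequency, bandwidth = bandwidth,
    chirp_slope = chirp_slope, chirp_duration = chirp_duration,
    sample_rate = sample_rate,
    samples_per_chirp = as.integer(samples_per_chirp),
    chirps_per_frame = as.integer(chirps_per_frame),
    n_frames = as.integer(n_frames), idle_time = idle_time,
    rx_channels = as.integer(rx_channels),
    tx_channels = as.integer(tx_channels)), class = "radar_config")
}

#' Reduced-scale radar profile for simulation studies
#'
#' Same 60 GHz waveform as [radar_config()] but with 64 fast-time samples
#' per chirp and a 400 us chirp interval (idle time stretched to 340 us),
#' giving a 2.5 kHz slow-time sampling rate that comfortably covers
#' walking and falling Doppler (up to roughly +/- 1.1 kHz at 60 GHz) at a
#' fraction of the data volume.  The default 59 frames span 3.02 s, long
#' enough for a walk phase, a fall, and a post-fall rest.
#'
#' @param n_frames number of frames (59 frames = 3.02 s).
#' @param samples_per_chirp fast-time samples per chirp.
#' @param ... further overrides passed to [radar_config()].
#' @return an object of class `radar_config`.
#' @export
desk_radar_config <- function(n_frames = 59L, samples_per_chirp = 64L, ...) {
  radar_config(samples_per_chirp = samples_per_chirp,
               idle_time = 340e-6, n_frames = n_frames, ...)
}

#' @export
print.radar_config <- function(x, ...) {
  cat("<radar_config>\n")
  cat(sprintf("  chirp: fc %.3f GHz, B %.3f GHz, slope %.3f MHz/us, Tc %.1f us\n",
              x$start_frequency / 1e9, x$bandwidth / 1e9,
              x$chirp_slope / 1e12, x$chirp_duration * 1e6))
  cat(sprintf("  sampling: %d samples @ %.2f MHz; %d chirps/frame x %d frames\n",
              x$samples_per_chirp, x$sample_rate / 1e6,
              x$chirps_per_frame, x$n_frames))
  cat(sprintf("  chirp interval %.0f us (PRF %.3f kHz), record %.2f s\n",
              chirp_interval(x) * 1e6, 1e-3 / chirp_interval(x),
              record_duration(x)))
  cat(sprintf("  range bin %.3f m, %d bins (max %.1f m)\n",
              range_bin_width(x), x$samples_per_chirp,
              range_bin_width(x) * x$samples_per_chirp))
  invisible(x)
}

#' @rdname radar_config
#' @param config a `radar_config`.
#' @export
chirp_interval <- function(config) config$chirp_duration + config$idle_time

#' @rdname radar_config
#' @export
n_chirps <- function(config) config$chirps_per_frame * config$n_frames

#' @rdname radar_config
#' @export
record_duration <- function(config) n_chirps(config) * chirp_interval(config)

#' Width of one range bin
#'
#' The fast-time DFT bin spacing in beat frequency is
#' `sample_rate / samples_per_chirp`; through the range equation
#' `d = c * fb / (2 beta)` this corresponds to `c / (2 B_s)` metres where
#' `B_s = chirp_slope * samples_per_chirp / sample_rate` is the bandwidth
#' actually swept during the ADC window (equal to the nominal bandwidth
#' when the ADC spans the full ramp).
#'
#' @param config a `radar_config`.
#' @return bin width in metres.
#' @export
range_bin_width <- function(config) {
  b_sampled <- config$chirp_slope * config$samples_per_chirp /
    config$sample_rate
  .c0 / (2 * b_sampled)
}

#' Noise and artifact model for the simulator
#'
#' @param snr_db per-sample signal-to-noise ratio of the point echo, in dB
#'   (complex white Gaussian noise; must be finite -- pass `noise = NULL`
#'   to the synthesiser for a noiseless cube).
#' @param clutter_amplitude amplitude of a static zero-Doppler clutter
#'   return, relative to the unit echo amplitude (0 disables it).
#' @param outlier_rate probability per map cell of a speckle outlier,
#'   injected after map formation; must lie in `[0, 0.05]`.
#' @param outlier_gain_db speckle level in dB above the map mean.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(snr_db = 15, clutter_amplitude = 0.3,
                       outlier_rate = 0.005, outlier_gain_db = 15) {
  if (!is.numeric(snr_db) || length(snr_db) != 1L || !is.finite(snr_db))
    stopf("noise_spec: `snr_db` must be a finite scalar")
  if (!is.numeric(clutter_amplitude) || clutter_amplitude < 0)
    stopf("noise_spec: `clutter_amplitude` must be >= 0")
  if (!is.numeric(outlier_rate) || outlier_rate < 0 || outlier_rate > 0.05)
    stopf("noise_spec: `outlier_rate` must lie in [0, 0.05]")
  if (!is.numeric(outlier_gain_db) || !is.finite(outlier_gain_db))
    stopf("noise_spec: `outlier_gain_db` must be finite")
  structure(list(snr_db = snr_db, clutter_amplitude = clutter_amplitude,
                 outlier_rate = outlier_rate,
                 outlier_gain_db = outlier_gain_db), class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf(
    "<noise_spec> snr %.1f dB, clutter %.2f, outliers %.3f @ +%.0f dB\n",
    x$snr_db, x$clutter_amplitude, x$outlier_rate, x$outlier_gain_db))
  invisible(x)
}
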