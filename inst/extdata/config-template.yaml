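# radarfall pipeline configuration template
#
# Radar block: the full 60 GHz IWR6843-style parameter set
#   starting frequency   60 GHz
#   stop frequency       63.015 GHz
#   bandwidth            3.015 GHz
#   frequency slope      50.259 MHz/us
#   sample rate          5 MHz
#   idle time            100 us
#   ramp end time        60 us
#   receive antennas     4 (one channel synthesised)
#   transmit antennas    1
#   samples per chirp    256
#   chirp loops          128
# profile "full" uses those values as-is; profile "desk" (default) keeps
# the waveform but records 64 fast-time samples and stretches the chirp
# interval to 400 us for desk-scale studies.

master_seed: 1
paths:
  workdir: radarfall-run

radar:
  profile: full
  start_frequency: 6.0e+10       # Hz
  bandwidth: 3.015e+9            # Hz
  chirp_slope: 5.0259e+13        # Hz/s (= 50.259 MHz/us)
  chirp_duration: 6.0e-5       # s (ramp end time)
  sample_rate: 5.0e+6            # Hz
  samples_per_chirp: 256
  chirps_per_frame: 128         # chirp loops
  n_frames: 488
  idle_time: 1.0e-4           # s
  rx_channels: 4
  tx_channels: 1

noise:
  snr_db: 15                    # per-sample echo SNR (dB)
  clutter_amplitude: 0.3        # static return, relative amplitude
  outlier_rate: 0.005           # speckle probability per map cell
  outlier_gain_db: 15           # speckle level above the map mean

pfe:
  a: 0.25                       # adaptive threshold weight, [0, 1]
  hampel_k: 5                   # half-window (time cells)
  hampel_nth: 3                 # replacement multiplier

stft:
  window_length: 32             # chirps
  hop: 8
  window: hann
  fft_length: 64

train:
  learning_rate: 0.0005
  epochs: 50
  step_size: 10                 # epochs between halvings
  gamma: 0.5
  batch_size: 32
  split_fraction: 0.8

dataset:
  n_per_class: 20
  height_range: [1.5, 1.9]      # m
  walk_speed: 1.0               # m/s

image_size: 54
rt_decimate: 8
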