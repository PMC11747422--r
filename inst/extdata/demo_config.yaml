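# Demo study configuration: 6 mice per genotype x sex cell, imaged at
# 50/75/125 days on both carotids, full image rendering and extraction.
seed: 7
stages:
  simulate: true
  extract: true
  analyze: true
  stats: true
cohort:
  n_per_group: 6
  ages: [50, 75, 125]
  dropout: true
synth:
  n_cycles: 20
  fs: 5000
mmode:
  pixel_pitch_mm: 0.01
  line_rate_hz: 1000
  speckle: 0.5
doppler:
  v_bin_mm_s: 5.0
  line_rate_hz: 1000
  speckle: 0.5
  noise_floor: 0.05
cycles:
  n_samples: 256
  rr_tol: 0.2
stats:
  alpha: 0.05
  age_as: factor
write_images: false
write_waveforms: false
log_level: info
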