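# Example pipeline configuration with every stage at its default.
cutoff_hz: 1000
analysis_rate_hz: 32000
tracker:
  tempo_prior_center_bpm: 80
  tempo_prior_spread_octaves: 1.0
  tightness: 8
  tempo_range_bpm: [40, 220]
  interp_factor: 4
segmentation:
  sigma_s: 0.1
  suppression_depth: 0.8
  min_s1_separation_s: 0.22
  max_separation_factor: 1.3
  infrasonic_band_hz: [2, 20]
  width_threshold: 0.2
refine: true
reestimate_tempo: false
tolerance_s: 0.05
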