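# Example nominal regions for the diagnostic plots.  These axes are
# plausible reference values for resting adults, supplied purely for
# display: they are user configuration, not validated medical ranges.
ellipse:
  center_t11_s: 0.85     # heartbeat interval at ~70 bpm
  center_t12_s: 0.31     # systolic duration
  semi_t11_s: 0.35
  semi_t12_s: 0.06
  angle_deg: 12          # systole lengthens mildly with the interval
widths_rect:
  t1_min_s: 0.06
  t1_max_s: 0.16
  t2_min_s: 0.05
  t2_max_s: 0.14
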