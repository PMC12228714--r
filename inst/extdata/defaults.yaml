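# Packaged pipeline defaults.
# Calibration: red-channel SNARF readout, linear over pH 5-9.
calibration:
  slope: 28.8          # FI units per pH unit
  intercept: -120.05   # FI units
  r_squared: 0.957
  channel: R
  linear_range: [5.0, 9.0]

segmentation:
  k: 5                 # labels 0 (background) .. 4
  threshold: 10        # brightness cut-off, mean(R,G,B) on 0-255
  scaling: minmax
  background: exclude  # sub-threshold pixels never enter k-means
  n_init: 10
  seed: 0
  ph_channels: [R, G, B]   # pH clustering features (plus x, y)
  no_channels: [G]         # NO clustering features (plus x, y)

dynamics:
  center_cluster: 4
  reference: mean      # combine peripheral |dpH| variances by plain mean

# Normalized linear relations between NO features and outcomes:
# outcome = slope * feature + intercept, all variables on [0, 1].
regression:
  alpha: 0
  full_fi:
    day:    {slope: 0.85, intercept: 0.57}
    re_epi: {slope: 0.40, intercept: 0.25}
  cluster_fi:
    day:    {slope: 1.08, intercept: 0.03}
    re_epi: {slope: 0.56, intercept: -0.04}
  cluster_area:
    day:    {slope: -1.08, intercept: 0.92}
    re_epi: {slope: -1.13, intercept: 0.51}

zstack:
  n_frames: 11
  positions: [0, 1000]   # evenly spaced stage range
  frame_strategy: max-laplacian
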