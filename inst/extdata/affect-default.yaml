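feature_scales:
  f0_mean: 200.0
  f0_sd: 25.0
  f0_slope: 100.0
  f0_range: 80.0
  voiced_fraction: 1.0
  rms_mean: 0.15
  rms_cv: 0.5
  duration_s: 3.0
vitality_weights:
  w_pos: 0.4
  w_neg: 0.4
  w_exc: 0.1
emotions:
  calmness:
    bias: 0.6
    weights:
      f0_sd: -1.2
      rms_cv: -0.8
      voiced_fraction: 3.0
      rms_mean: -0.2
      f0_slope: -0.2
  anger:
    bias: -2.4
    weights:
      rms_mean: 1.0
      rms_cv: 0.8
      f0_sd: 0.6
      f0_mean: -1.0
      f0_slope: -0.4
  joy:
    bias: -4.65
    weights:
      rms_mean: 0.8
      f0_mean: 2.0
      f0_sd: 0.5
      f0_slope: 0.6
      voiced_fraction: 1.5
  sorrow:
    bias: 3.82
    weights:
      rms_mean: -1.0
      f0_sd: -0.6
      f0_mean: -1.667
      f0_slope: -0.5
      voiced_fraction: -1.5
  excitement:
    bias: -4.33
    weights:
      rms_mean: 0.9
      f0_sd: 1.0
      f0_range: 0.5
      f0_mean: 1.333
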