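# Standardization settings matched to the default phantom grid
# (240 x 240 x 230 mm): 2 x 2 x 3 mm output, ROI covering all organs.
target_spacing_mm: [2, 2, 3]
roi_mm:
  min: [18, 24, 48]
  max: [210, 216, 201]
per_station_bias_correction: false
bias_correction: true
bias_degree: 4
normalization: none
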