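# Standardization settings matched to the reduced phantom grid
# (160 x 160 x 158 mm): 2 x 2 x 3 mm output, 64 x 64 x 35 voxel ROI.
target_spacing_mm: [2, 2, 3]
roi_mm:
  min: [12, 16, 33]
  max: [140, 144, 138]
per_station_bias_correction: false
bias_correction: true
bias_degree: 4
normalization: none
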