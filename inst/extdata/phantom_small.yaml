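# Reduced phantom for fast end-to-end runs: 160 x 160 x 158 mm grid, two
# stations; organ layout scaled from the default.
grid_shape: [64, 64, 44]
voxel_spacing_mm: [2.5, 2.5, 3.6]
n_stations: 2
overlap_mm: 36
bias_amplitude: 0.2
noise_sigma: 0.02
center_jitter_mm: 3
axes_jitter_frac: 0.08
intensity_jitter: 0.05
organ_specs:
  - {label: 1, name: liver,       cx: 0.33, cy: 0.42, cz: 0.62, ax: 40, ay: 28, az: 30, water_fraction: 0.70}
  - {label: 2, name: spleen,      cx: 0.76, cy: 0.44, cz: 0.64, ax: 18, ay: 15, az: 17, water_fraction: 0.80}
  - {label: 3, name: kidney_r,    cx: 0.30, cy: 0.66, cz: 0.36, ax: 13, ay: 12, az: 18, water_fraction: 0.75}
  - {label: 4, name: kidney_l,    cx: 0.70, cy: 0.66, cz: 0.36, ax: 13, ay: 12, az: 18, water_fraction: 0.75}
  - {label: 5, name: adrenal_r,   cx: 0.30, cy: 0.70, cz: 0.55, ax: 6.5, ay: 5, az: 6, water_fraction: 0.55}
  - {label: 6, name: adrenal_l,   cx: 0.70, cy: 0.70, cz: 0.55, ax: 6.5, ay: 5, az: 6, water_fraction: 0.55}
  - {label: 7, name: pancreas,    cx: 0.52, cy: 0.62, cz: 0.47, ax: 26, ay: 9,  az: 8, water_fraction: 0.62}
  - {label: 8, name: gallbladder, cx: 0.42, cy: 0.20, cz: 0.47, ax: 9,  ay: 7,  az: 10, water_fraction: 0.92}
seed: 1
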