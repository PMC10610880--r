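# Annotated epieff configuration: the two reference GRE-EPI protocol
# families at 0.5 T, gray-matter relaxation, and a phantom specification.
# Times in ms, bandwidths in Hz, angles in degrees.

relaxation:
  t1: 717.2          # gray matter T1 at ~0.5 T
  t2star: 86         # gray matter T2* used for efficiency optimization
  tissue_label: GM

# A single fully specified protocol (for the `timing` subcommand).
protocol:
  voxel_dims: 3.4
  fov_inplane: 240
  etl: 70
  n_slices: 38
  acq_bandwidth: 160000
  te: 55
  per_slice_overhead: 20.76   # calibrated: mean(TR/n_slices - TE)
  prep_time: 3

# The 3.4 mm family TE/TR/FA grid (for the `optimize` subcommand).
# Flip angles are the rounded Ernst angles for T1 = 717.2 ms.
protocol_grid:
  te: [25, 35, 45, 55, 65, 75, 85, 95, 105]
  tr: [1738, 2119, 2499, 2879, 3259, 3639, 4019, 4399, 4779]
  fa: [85, 87, 88, 89, 89, 90, 90, 90, 90]
  etl: 70
  n_slices: 38
  voxel_mm: 3.4
  fov_mm: 240
  acq_bandwidth_hz: 160000

# The 4.0 mm family, for comparison runs.
protocol_grid_4mm:
  te: [25, 35, 45, 55, 65, 75, 85, 95, 105]
  tr: [1386, 1706, 2026, 2346, 2666, 2986, 3306, 3626, 3946]
  fa: [82, 85, 87, 88, 89, 89, 89, 90, 90]
  etl: 60
  n_slices: 32
  voxel_mm: 4.0
  fov_mm: 240
  acq_bandwidth_hz: 160000

# Digital phantom: grid size, coil array, thermal noise target and
# physiological fluctuation (see ?phantom_spec).
phantom:
  grid_dim: [40, 40, 10]
  voxel_dims: 3.4
  n_coils: 8
  coil_rho: 0.1
  target_snr: 100      # gray-matter thermal (pseudo-replica) SNR
  target_ratio: 0.5    # gray-matter sigma_P / sigma_T to inject
  lambda_bold: 0
  seed: 42
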