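# Demo configuration: small two-region viscoelastic phantom through the
# full MRE chain, plus two simulated cell groups through the AFM chain.
schema_version: 1
stages:
  - simulate-mre
  - recon
  - invert
  - report
  - simulate-afm
  - fit-afm
  - compare
out: brainmech_demo_out
phantom:
  grid_shape: [48, 48, 8]
  voxel_size_m: [0.0002, 0.0002, 0.0003]
  region_geometry: two_region
  regions:
    "1": {storage_pa: 8070, loss_pa: 3200}
    "2": {storage_pa: 6600, loss_pa: 2520}
  frequency_hz: 1000
  density_kg_m3: 1000
  wave_amplitude_m: 5.0e-6
  seed: 1
meg:
  encoding_sensitivity: 1.0e+5
  n_phase_offsets: 4
  noise_sd: 0
  seed: 2
inversion:
  laplacian: modified_wavenumber
  smoothing_sd: 0
  density_kg_m3: 1000
afm:
  probe:
    radius_m: 6.0e-6
    spring_constant_n_m: 0.1
    deflection_sensitivity_m_v: 3.3e-8
    poisson_ratio: 0.5
  contact_z_m: 5.0e-7
  ramp_size_m: 1.5e-6
  n_points: 200
  noise_sd_m: 0
  groups:
    astrocyte: {mean_E_pa: 681.13, sd_E_pa: 89.49, n_cells: 10, seed: 101}
    neuron:    {mean_E_pa: 470.88, sd_E_pa: 111.75, n_cells: 10, seed: 202}
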