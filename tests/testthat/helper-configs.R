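# Shared demo pipeline configuration (small two-region phantom + two
# three-cell groups); used by the determinism and acceptance suites.

demo_config <- function(out_dir) {
  list(
    schema_version = 1,
    stages = c("simulate-mre", "recon", "invert", "report",
               "simulate-afm", "fit-afm", "compare"),
    out = out_dir,
    phantom = list(grid_shape = c(32L, 32L, 6L),
                   voxel_size_m = c(0.2e-3, 0.2e-3, 0.3e-3),
                   region_geometry = "two_region",
                   regions = list(`1` = list(storage_pa = 8070,
                                             loss_pa = 3200),
                                  `2` = list(storage_pa = 6600,
                                             loss_pa = 2520)),
                   seed = 21L),
    meg = list(noise_sd = 0, seed = 22L),
    inversion = list(laplacian = "modified_wavenumber"),
    afm = list(groups = list(astrocyte = list(mean_E_pa = 681.13,
                                              sd_E_pa = 89.49,
                                              n_cells = 3L, seed = 23L),
                             neuron = list(mean_E_pa = 470.88,
                                           sd_E_pa = 111.75,
                                           n_cells = 3L, seed = 24L)),
               n_points = 80L))
}

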