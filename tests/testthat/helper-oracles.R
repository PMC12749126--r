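# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct loops, hand formulas, brute force.

# Direct-sum DFT fundamental, (2/N) sum_t phi_t exp(-2i pi t / N),
# computed with an explicit loop (oracle for extract_harmonic).
oracle_harmonic <- function(vols) {
  N <- length(vols)
  acc <- array(0i, dim = dim(vols[[1]]))
  for (t in seq_len(N) - 1) {
    acc <- acc + vols[[t + 1]] * exp(complex(imaginary = -2 * pi * t / N))
  }
  (2 / N) * acc
}

# Welch two-sample t statistic and two-sided p from the textbook formulas.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Central-difference 3D Laplacian of a complex array, explicit loops over a
# few probe voxels (oracle for the inversion's stencil).
oracle_laplacian_at <- function(u, h, i, j, k) {
  (u[i + 1, j, k] + u[i - 1, j, k] - 2 * u[i, j, k]) / h[1]^2 +
    (u[i, j + 1, k] + u[i, j - 1, k] - 2 * u[i, j, k]) / h[2]^2 +
    (u[i, j, k + 1] + u[i, j, k - 1] - 2 * u[i, j, k]) / h[3]^2
}

# Smooth random wrapped-phase test volume: low-pass filtered white noise,
# scaled to the requested amplitude and then capped so true per-voxel
# gradients stay below pi (otherwise exact unwrapping is ill-posed).
smooth_random_phase <- function(dims, amplitude, seed, grad_cap = 2.4) {
  set.seed(seed)
  raw <- array(rnorm(prod(dims)), dim = dims)
  sm <- brainmech:::gaussian_smooth_3d(raw, 2)
  v <- amplitude * sm / max(abs(sm))
  g <- max(abs(diff(v)), abs(aperm(apply(v, c(1, 3), diff), c(2, 1, 3))),
           if (dims[3] > 1) abs(apply(v, c(1, 2), diff)) else 0)
  if (g > grad_cap) v <- v * grad_cap / g
  v
}

# Default-protocol phantom helpers
cortex_gstar <- complex(real = 8070, imaginary = 3200)
hippocampus_gstar <- complex(real = 6600, imaginary = 2520)

small_phantom <- function(gstar = cortex_gstar, grid = c(48L, 48L, 6L),
                          prop = c(1, 0, 0), pol = c(0, 0, 1)) {
  phantom_spec(grid_shape = grid,
               region_moduli = list(`1` = gstar),
               propagation_direction = prop, polarization = pol)
}

run_mre_pipeline <- function(spec, laplacian = "modified_wavenumber",
                             noise_sd = 0, seed = 1L, smoothing_sd = 0,
                             masks = region_masks(spec)) {
  field <- simulate_wave_field(spec)
  acq <- encode_acquisition(field, meg_spec(), noise_sd = noise_sd,
                            seed = seed, masks = masks)
  rec <- reconstruct_displacement(acq)
  maps <- ahi_invert(rec, inversion_config(frequency = spec$frequency,
                                           density = spec$density,
                                           laplacian = laplacian,
                                           smoothing_sd = smoothing_sd))
  list(field = field, acq = acq, rec = rec, maps = maps,
       report = roi_statistics(maps, acq$masks))
}

# Minimal hand-built elastogram_maps object for ROI statistics tests.
make_maps <- function(storage, loss, valid = NULL) {
  d <- dim(storage)
  if (is.null(valid)) valid <- array(TRUE, dim = d)
  structure(list(storage = storage, loss = loss,
                 stiffness = sqrt(storage^2 + loss^2), valid = valid,
                 qc = list()),
            class = "elastogram_maps")
}
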