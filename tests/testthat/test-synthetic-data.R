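# Synthetic-data module: wave-field simulator, MEG encoder, AFM curve
# generator. Frozen expected values were computed independently by direct
# arithmetic before implementation (see comments at each assertion).

test_that("shear wavenumber matches direct complex arithmetic", {
  # k = omega * sqrt(rho/G*), evaluated independently:
  # 2*pi*1000*sqrt(1000/(8070+3200i)) = 2094.6165 - 400.1346i
  k <- shear_wavenumber(8070 + 3200i, 1000, 1000)
  expect_equal(Re(k), 2094.6165, tolerance = 1e-6)
  expect_equal(Im(k), -400.1346, tolerance = 1e-6)
  # shear wavelength ~3.0 mm
  expect_equal(2 * pi / Re(k), 3.0e-3, tolerance = 1e-3)

  # rho*omega^2/k^2 inverted by hand: G = 9869.604 gives k = 2000 exactly
  k2 <- shear_wavenumber(9869.604401, 1000, 1000)
  expect_equal(Re(k2), 2000, tolerance = 1e-9)
  expect_equal(Im(k2), 0)
})

test_that("simulated field satisfies the discrete Helmholtz relation", {
  cases <- list(
    list(g = cortex_gstar, prop = c(1, 0, 0), pol = c(0, 0, 1)),
    list(g = hippocampus_gstar, prop = c(1, 1, 0) / sqrt(2), pol = c(0, 0, 1)),
    list(g = 9869.604401 + 0i, prop = c(1, 0, 0), pol = c(0, 1, 0)))
  for (cs in cases) {
    spec <- small_phantom(cs$g, grid = c(32L, 32L, 8L), prop = cs$prop,
                          pol = cs$pol)
    field <- simulate_wave_field(spec)
    rho <- spec$density; omega <- 2 * pi * spec$frequency
    k <- shear_wavenumber(cs$g, rho, spec$frequency)
    h <- spec$voxel_size
    tol <- (Mod(k) * max(h))^2 / 6
    comp <- if (cs$pol[3] == 1) field$z else field$y
    for (idx in list(c(8, 8, 4), c(20, 15, 5), c(25, 25, 3))) {
      lap <- oracle_laplacian_at(comp, h, idx[1], idx[2], idx[3])
      g_rec <- -rho * omega^2 * comp[idx[1], idx[2], idx[3]] / lap
      expect_lt(Mod(g_rec - cs$g) / Mod(cs$g), tol)
    }
  }
})

test_that("attenuation is monotone for lossy media, absent for elastic", {
  spec <- small_phantom(cortex_gstar)
  amp <- Mod(simulate_wave_field(spec)$z)
  along <- amp[, 5, 3]
  expect_true(all(diff(along) < 0))

  spec_el <- small_phantom(9869.604401 + 0i)
  amp_el <- Mod(simulate_wave_field(spec_el)$z)
  expect_equal(max(amp_el), min(amp_el), tolerance = 1e-12)
})

test_that("phantom validation rejects bad physics", {
  expect_error(phantom_spec(polarization = c(1, 0, 0)), "orthogonal")
  expect_error(phantom_spec(region_moduli = list(`1` = -5 + 1i)),
               "storage modulus")
  expect_error(phantom_spec(region_moduli = list(`1` = 100 - 1i)),
               "loss modulus")
})

test_that("phase encoding implements the lumped linear MEG map", {
  d <- c(4L, 4L, 3L)
  # 5 um purely real x-displacement, xi = 1e5 -> 0.5 rad at offset 0
  f <- displacement_field(array(5e-6 + 0i, d), array(0i, d), array(0i, d),
                          1000, c(2e-4, 2e-4, 3e-4))
  acq <- encode_acquisition(f, meg_spec())
  expect_equal(max(abs(acq$phase[["+x"]][[1]] - 0.5)), 0, tolerance = 1e-12)
  # -x polarity is the negation (zero background)
  expect_equal(acq$phase[["-x"]][[1]], -acq$phase[["+x"]][[1]])
  # offsets advance the vibration phase: t = 1 gives Re(u*exp(i pi/2)) = 0
  expect_equal(max(abs(acq$phase[["+x"]][[2]])), 0, tolerance = 1e-12)

  # zero displacement -> background everywhere
  f0 <- displacement_field(array(0i, d), array(0i, d), array(0i, d),
                           1000, c(2e-4, 2e-4, 3e-4))
  acq0 <- encode_acquisition(f0, meg_spec(background_phase = 0.3))
  for (dir in names(acq0$phase)) {
    for (t in 1:4) expect_equal(max(abs(acq0$phase[[dir]][[t]] - 0.3)), 0)
  }
})

test_that("encoded phase is always wrapped and noise is seed-reproducible", {
  spec <- small_phantom(grid = c(16L, 16L, 4L))
  field <- simulate_wave_field(spec)
  meg_big <- meg_spec(encoding_sensitivity = 1e6)  # forces wraps
  a1 <- encode_acquisition(field, meg_big, noise_sd = 0.1, seed = 42)
  a2 <- encode_acquisition(field, meg_big, noise_sd = 0.1, seed = 42)
  a3 <- encode_acquisition(field, meg_big, noise_sd = 0.1, seed = 43)
  for (dir in names(a1$phase)) {
    for (t in 1:4) {
      p <- a1$phase[[dir]][[t]]
      expect_true(all(p > -pi & p <= pi))
      expect_identical(p, a2$phase[[dir]][[t]])
    }
  }
  expect_false(identical(a1$phase[["+x"]][[1]], a3$phase[["+x"]][[1]]))
})

test_that("meg_spec enforces the protocol invariants", {
  expect_error(meg_spec(n_phase_offsets = 2), "n_phase_offsets")
  expect_error(meg_spec(directions = c("+x", "-x", "+y")), "unpaired")
  expect_error(meg_spec(encoding_sensitivity = 0))
})

test_that("Hertz force matches hand evaluation and scales linearly in E", {
  # (4/3) * 470.88/(1-0.25) * sqrt(6e-6) * (1e-6)^1.5 = 2.050517e-9 N
  expect_equal(hertz_force(1e-6, 470.88, probe_spec()), 2.050517e-9,
               tolerance = 1e-6)
  expect_equal(hertz_force(1e-6, 2 * 470.88, probe_spec()),
               2 * hertz_force(1e-6, 470.88, probe_spec()))
})

test_that("generated force curves obey the contact force balance", {
  probe <- probe_spec()
  cv <- generate_force_curve(470.88, probe)
  pre <- cv$z <= cv$true_contact
  expect_true(all(cv$deflection[pre] == 0))
  post <- !pre
  delta <- (cv$z[post] - cv$true_contact) - cv$deflection[post]
  F_cant <- probe$spring_constant * cv$deflection[post]
  F_hertz <- hertz_force(delta, 470.88, probe)
  expect_lt(max(abs(F_cant - F_hertz) / pmax(F_hertz, 1e-30)), 1e-8)
  expect_error(generate_force_curve(-10), "positive")
})

test_that("cell population generator is reproducible and respects truncation", {
  # degenerate distribution
  pop0 <- generate_cell_population(500, 0, 5, seed = 3)
  expect_equal(vapply(pop0, `[[`, numeric(1), "true_E"), rep(500, 5))
  # single cell: sample mean is its E
  pop1 <- generate_cell_population(470.88, 50, 1, seed = 3)
  expect_length(pop1, 1)
  expect_gt(pop1[[1]]$true_E, 0)
  # CLT bound at the astrocyte scale (SD = sqrt(40) * 14.15 = 89.49)
  pop <- generate_cell_population(681.13, 89.49, 40, seed = 7)
  Es <- vapply(pop, `[[`, numeric(1), "true_E")
  expect_lt(abs(mean(Es) - 681.13), 3 * 89.49 / sqrt(40))
  expect_true(all(Es > 0))
  # reproducibility
  pop_b <- generate_cell_population(681.13, 89.49, 40, seed = 7)
  expect_identical(Es, vapply(pop_b, `[[`, numeric(1), "true_E"))
  expect_error(generate_cell_population(-1, 10, 5), "positive")
})
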