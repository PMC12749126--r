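# Algebraic Helmholtz inversion and ROI statistics.

analytic_plane_field <- function(k, d = c(40L, 40L, 6L),
                                 h = c(2e-4, 2e-4, 3e-4)) {
  x <- (seq_len(d[1]) - 1) * h[1]
  u <- array(rep(exp(-1i * k * x), prod(d[2:3])), dim = d)
  displacement_field(array(0i, d), array(0i, d), u, 1000, h)
}

test_that("smoothing preserves constants and is the identity at sd 0", {
  spec <- small_phantom(grid = c(12L, 12L, 4L))
  f <- simulate_wave_field(spec)
  expect_identical(smooth_field(f, 0), f)
  d <- c(16L, 16L, 6L)
  fc <- displacement_field(array(2 + 3i, d), array(0i, d), array(0i, d),
                           1000, c(2e-4, 2e-4, 3e-4))
  fs <- smooth_field(fc, 1.5)
  expect_equal(fs$x, fc$x, tolerance = 1e-12)
})

test_that("white-noise variance drops by the analytic kernel factor", {
  # oracle: normalized Gaussian kernel weights computed here by hand
  sdv <- 2
  off <- seq(-ceiling(4 * sdv), ceiling(4 * sdv))
  w <- exp(-off^2 / (2 * sdv^2)); w <- w / sum(w)
  factor_1d <- sum(w^2)
  d <- c(48L, 48L, 30L)
  set.seed(12)
  noise <- array(rnorm(prod(d)), dim = d)
  f <- displacement_field(noise + 0i, array(0i, d), array(0i, d),
                          1000, c(1e-4, 1e-4, 1e-4))
  fs <- smooth_field(f, sdv)
  core <- Re(fs$x)[17:32, 17:32, 12:19]   # interior, away from edges
  ratio <- var(as.vector(core))
  expect_equal(ratio, factor_1d^3, tolerance = 0.05)
})

test_that("plane-wave AHI equals rho*omega^2/k^2 closed form", {
  k <- 2000
  g_true <- 1000 * (2 * pi * 1000)^2 / k^2   # 9869.604 Pa
  f <- analytic_plane_field(k)
  cfg_mw <- inversion_config(laplacian = "modified_wavenumber")
  maps <- ahi_invert(f, cfg_mw)
  v <- maps$valid
  expect_lt(max(abs(maps$storage[v] - g_true)) / g_true, 1e-9)
  expect_lt(max(abs(maps$loss[v])) / g_true, 1e-9)

  # central stencil: biased by exactly (kh/2)^2 / sin^2(kh/2)
  h <- 2e-4
  bias <- (k * h / 2)^2 / sin(k * h / 2)^2   # = 1.013441
  maps_c <- ahi_invert(f, inversion_config(laplacian = "central"))
  vc <- maps_c$valid
  expect_equal(mean(maps_c$storage[vc]) / g_true, bias, tolerance = 1e-8)
})

test_that("AHI is invariant to field amplitude and satisfies |G*| identity", {
  spec <- small_phantom()
  f <- simulate_wave_field(spec)
  cfg <- inversion_config(laplacian = "central")
  m1 <- ahi_invert(f, cfg)
  for (c_scale in c(-2.5, 1e6, 0.3 - 0.4i)) {
    f2 <- f
    for (ax in c("x", "y", "z")) f2[[ax]] <- f2[[ax]] * c_scale
    m2 <- ahi_invert(f2, cfg)
    expect_equal(m2$storage[m2$valid], m1$storage[m1$valid],
                 tolerance = 1e-10)
  }
  v <- m1$valid
  expect_equal(m1$stiffness[v], sqrt(m1$storage[v]^2 + m1$loss[v]^2),
               tolerance = 1e-12)
})

test_that("AHI rejects flat fields and empty interiors", {
  d <- c(10L, 10L, 4L)
  flat <- displacement_field(array(1e-6 + 0i, d), array(0i, d), array(0i, d),
                             1000, c(2e-4, 2e-4, 3e-4))
  expect_error(ahi_invert(flat, inversion_config()), "flat")
  f <- simulate_wave_field(small_phantom(grid = c(12L, 12L, 4L)))
  expect_error(ahi_invert(f, inversion_config(edge_margin = 6L)),
               "interior")
})

test_that("full-pipeline parameter recovery hits stated tolerances", {
  for (g in list(cortex_gstar, hippocampus_gstar)) {
    res_mw <- run_mre_pipeline(small_phantom(g))
    r <- res_mw$report
    expect_lt(abs(r$storage_mean - Re(g)) / Re(g), 0.005)
    expect_lt(abs(r$loss_mean - Im(g)) / Im(g), 0.005)
    # passivity: no negative loss voxels on a noiseless passive phantom
    expect_identical(res_mw$maps$qc$frac_negative_loss, 0)

    res_c <- run_mre_pipeline(small_phantom(g), laplacian = "central")
    expect_lt(abs(res_c$report$storage_mean - Re(g)) / Re(g), 0.03)
    expect_lt(abs(res_c$report$loss_mean - Im(g)) / Im(g), 0.03)
  }
})

test_that("two-region phantom recovers each ROI without cross-talk", {
  spec <- two_region_phantom(cortex_gstar, hippocampus_gstar,
                             grid_shape = c(64L, 64L, 8L))
  res <- run_mre_pipeline(spec)
  r <- res$report
  expect_setequal(r$roi, c("region1", "region2"))
  g <- list(region1 = cortex_gstar, region2 = hippocampus_gstar)
  for (i in seq_len(nrow(r))) {
    gt <- g[[r$roi[i]]]
    expect_lt(abs(r$storage_mean[i] - Re(gt)) / Re(gt), 0.005)
    expect_lt(abs(r$loss_mean[i] - Im(gt)) / Im(gt), 0.005)
  }
})

test_that("ROI recovery bias stays under 5% at 0.05 rad phase noise", {
  # moderately attenuating phantom so the wave keeps usable SNR across the
  # ROI (see methods vignette); central Laplacian + 1.5-voxel smoothing.
  spec <- phantom_spec(region_moduli = list(`1` = 8000 + 800i))
  res <- run_mre_pipeline(spec, laplacian = "central", noise_sd = 0.05,
                          seed = 11, smoothing_sd = 1.5)
  r <- res$report
  expect_lt(abs(r$storage_mean - 8000) / 8000, 0.05)
  expect_lt(abs(r$loss_mean - 800) / 800, 0.05)
  # the passivity violation rate is reported as a QC metric under noise
  expect_true(res$maps$qc$frac_negative_loss >= 0 &&
                res$maps$qc$frac_negative_loss < 0.25)
})

test_that("ROI statistics follow the sample-SD convention", {
  d <- c(2L, 1L, 1L)
  maps <- make_maps(array(c(6000, 8000), d), array(0, d))
  r <- roi_statistics(maps, list(roi = array(TRUE, d)))
  expect_equal(r$storage_mean, 7000)
  expect_equal(r$storage_sd, sqrt(2) * 1000)  # sample SD, n-1 denominator

  # homogeneous map: SD exactly 0
  dh <- c(4L, 4L, 2L)
  mh <- make_maps(array(5000, dh), array(1000, dh))
  rh <- roi_statistics(mh, list(all = array(TRUE, dh)))
  expect_equal(rh$storage_sd, 0)
  expect_equal(rh$stiffness_mean, sqrt(5000^2 + 1000^2))

  # ROI fully outside the valid region is dropped with a warning
  valid <- array(TRUE, dh); valid[1:2, , ] <- FALSE
  mv <- make_maps(array(5000, dh), array(1000, dh), valid)
  out <- array(FALSE, dh); out[1:2, , ] <- TRUE
  expect_warning(r2 <- roi_statistics(mv, list(good = array(TRUE, dh),
                                               dead = out)),
                 "dead")
  expect_equal(r2$roi, "good")
  expect_error(suppressWarnings(roi_statistics(mv, list(dead = out))),
               "no ROI")
})
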