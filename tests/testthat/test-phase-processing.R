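# Phase processing: polarity differencing, unwrapping, harmonic
# extraction, decoding, and the end-to-end reconstruction contracts.

make_acq <- function(plus, minus, d = c(4L, 4L, 2L)) {
  # hand-built one-axis acquisition with a single offset repeated 4 times
  mk <- function(v) lapply(1:4, function(t) array(v, dim = d))
  structure(list(phase = list(`+x` = mk(plus), `-x` = mk(minus)),
                 magnitude = array(1, dim = d), masks = list(),
                 meg = meg_spec(directions = c("+x", "-x")),
                 frequency = 1000, voxel_size = c(2e-4, 2e-4, 3e-4)),
            class = "wave_acquisition")
}

test_that("polarity differencing cancels background and preserves motion", {
  for (b in c(0, 0.9, -2.5)) {
    pd <- polarity_difference(make_acq(wrap_phase(0.5 + b),
                                       wrap_phase(-0.5 + b)))
    expect_equal(max(abs(pd$x[[1]] - 0.5)), 0, tolerance = 1e-12)
  }
  pd0 <- polarity_difference(make_acq(1.1, 1.1))
  expect_equal(max(abs(pd0$x[[1]])), 0)
  # wrap boundary: (3 - (-3))/2 = 3, wrap(3) = 3
  pd3 <- polarity_difference(make_acq(3.0, -3.0))
  expect_equal(max(abs(pd3$x[[1]] - 3.0)), 0, tolerance = 1e-12)

  acq <- make_acq(0.5, -0.5)
  acq$phase[["-x"]] <- NULL
  expect_error(polarity_difference(acq), "axis 'x'")
})

test_that("unwrapping recovers smooth fields up to one 2*pi constant", {
  # linear ramp 0 -> 6*pi
  v <- array(rep(seq(0, 6 * pi, length.out = 48), 12), dim = c(48L, 12L, 1L))
  u <- unwrap_phase(wrap_phase(v))
  resid <- u - v
  expect_equal(max(resid) - min(resid), 0, tolerance = 1e-9)
  expect_equal((max(resid) / (2 * pi)) %% 1, 0, tolerance = 1e-9)

  # already-unwrapped field with small gradients returns unchanged
  w <- smooth_random_phase(c(24, 24, 3), 2.5, seed = 4)
  expect_equal(unwrap_phase(w), w, tolerance = 1e-12)

  expect_error(unwrap_phase(array(0, dim = c(4, 4, 1)),
                            array(FALSE, dim = c(4, 4, 1))), "empty mask")
})

test_that("unwrap output is congruent to input modulo 2*pi (property)", {
  for (seed in 1:4) {
    truth <- smooth_random_phase(c(32, 32, 2), 9, seed = seed)
    w <- wrap_phase(truth)
    mask <- array(TRUE, dim = dim(w))
    mask[1:5, 1:5, ] <- FALSE  # non-trivial support
    u <- unwrap_phase(w, mask)
    expect_lt(max(abs(wrap_phase(u[mask] - w[mask]))), 1e-9)
    expect_true(all(is.na(u[!mask])))
    # recovered truth up to a constant 2*pi multiple
    resid <- u[mask] - truth[mask]
    expect_lt(max(resid) - min(resid), 1e-9)
  }
})

test_that("wrap-forcing acquisition unwraps back to encode-time truth", {
  spec <- small_phantom(grid = c(48L, 48L, 4L))
  field <- simulate_wave_field(spec)
  meg <- meg_spec(encoding_sensitivity = 1e6)  # 5 um -> 5 rad: wraps
  acq <- encode_acquisition(field, meg)
  truth <- attr(acq, "truth_phase")
  w <- acq$phase[["+z"]][[1]]
  expect_gt(max(abs(truth[["+z"]][[1]] - w)), 1)  # wrapping really occurred
  u <- unwrap_phase(w)
  resid <- u - truth[["+z"]][[1]]
  resid <- resid - 2 * pi * round(median(resid) / (2 * pi))
  expect_lt(sqrt(mean(resid^2)), 1e-6)
})

test_that("harmonic extraction matches the direct DFT oracle", {
  d <- c(5L, 4L, 2L)
  # pure quadrature sinusoid [0, A, 0, -A] has amplitude A
  A <- 0.7
  vols <- lapply(c(0, A, 0, -A), function(v) array(v, dim = d))
  C <- extract_harmonic(vols)
  expect_equal(max(abs(Mod(C) - A)), 0, tolerance = 1e-12)
  expect_equal(C, oracle_harmonic(vols), ignore_attr = TRUE)

  # constant offsets -> DC rejected
  Cc <- extract_harmonic(lapply(1:4, function(i) array(1.3, dim = d)))
  expect_equal(max(Mod(Cc)), 0, tolerance = 1e-12)
  expect_lt(max(attr(Cc, "residual_rms")), 1e-12)

  # pure second harmonic at N = 4 vanishes but is flagged by the residual
  v2 <- lapply(c(1, -1, 1, -1), function(v) array(v, dim = d))
  C2 <- extract_harmonic(v2)
  expect_equal(max(Mod(C2)), 0, tolerance = 1e-12)
  expect_gt(min(attr(C2, "residual_rms")), 0.5)

  # random volumes against the loop oracle
  set.seed(9)
  vr <- lapply(1:4, function(i) array(rnorm(prod(d)), dim = d))
  expect_equal(extract_harmonic(vr), oracle_harmonic(vr),
               ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(extract_harmonic(vr[1:2]), "at least 3")
})

test_that("decoding is division by the encoding sensitivity", {
  d <- c(3L, 3L, 2L)
  C <- list(x = array(0.5 + 0i, d), y = array(0i, d), z = array(0i, d))
  u <- decode_displacement(C, meg_spec(), 1000, c(2e-4, 2e-4, 3e-4))
  expect_equal(Re(u$x[1, 1, 1]), 5e-6)
  u2 <- decode_displacement(C, meg_spec(encoding_sensitivity = 2e5),
                            1000, c(2e-4, 2e-4, 3e-4))
  expect_equal(u2$x, u$x / 2)
})

test_that("end-to-end reconstruction is exact and linear (noiseless)", {
  spec <- small_phantom(prop = c(1, 1, 0) / sqrt(2))
  field <- simulate_wave_field(spec)
  acq <- encode_acquisition(field, meg_spec())
  rec <- reconstruct_displacement(acq)
  rel <- sqrt(sum(Mod(rec$z - field$z)^2) / sum(Mod(field$z)^2))
  expect_lt(rel, 1e-8)
  # unencoded components come back (numerically) zero
  expect_lt(max(Mod(rec$x)), 1e-20)

  # linearity in wave amplitude below wrapping limits
  spec_half <- small_phantom(prop = c(1, 1, 0) / sqrt(2))
  spec_half$wave_amplitude <- spec$wave_amplitude / 2
  rec_half <- reconstruct_displacement(
    encode_acquisition(simulate_wave_field(spec_half), meg_spec()))
  expect_equal(rec_half$z, rec$z / 2, tolerance = 1e-10)
})
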