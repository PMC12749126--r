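#' AFM probe specification
#'
#' Spherical colloidal probe on a soft cantilever, as used for cell
#' nanoindentation. Defaults match a microsphere probe with
#' R = 6 um, k = 0.1 N/m, deflection sensitivity 33 nm/V, and the
#' incompressible-cell Poisson ratio 0.5.
#'
#' @param radius sphere radius R, meters.
#' @param spring_constant cantilever spring constant k, N/m.
#' @param deflection_sensitivity photodetector conversion, m/V.
#' @param poisson_ratio nu, dimensionless, in (0, 0.5].
#' @return object of class `probe_spec`.
#' @export
probe_spec <- function(radius = 6e-6, spring_constant = 0.1,
                       deflection_sensitivity = 33e-9, poisson_ratio = 0.5) {
  stopifnot(radius > 0, spring_constant > 0, deflection_sensitivity > 0,
            poisson_ratio > 0, poisson_ratio <= 0.5)
  structure(list(radius = radius, spring_constant = spring_constant,
                 deflection_sensitivity = deflection_sensitivity,
                 poisson_ratio = poisson_ratio),
            class = "probe_spec")
}

#' Force curve container
#'
#' @param z piezo extension samples, meters, strictly monotone.
#' @param deflection cantilever deflection, meters (or volts, see `units`).
#' @param probe a [probe_spec()].
#' @param units `"m"` or `"V"`; volts require the probe's deflection
#'   sensitivity for conversion via [curve_to_physical()].
#' @param true_E,true_contact optional synthetic ground truth (Pa, meters).
#' @return object of class `force_curve`.
#' @export
force_curve <- function(z, deflection, probe, units = "m",
                        true_E = NULL, true_contact = NULL) {
  z <- as.numeric(z); deflection <- as.numeric(deflection)
  stopifnot(length(z) == length(deflection), length(z) >= 2L,
            all(is.finite(z)), all(is.finite(deflection)),
            inherits(probe, "probe_spec"), units %in% c("m", "V"))
  dz <- diff(z)
  if (!(all(dz > 0) || all(dz < 0))) stop("z must be strictly monotone")
  structure(list(z = z, deflection = deflection, probe = probe,
                 units = units, true_E = true_E, true_contact = true_contact),
            class = "force_curve")
}

# Hertz prefactor C such that F = C * delta^{3/2}
hertz_prefactor <- function(E, probe) {
  (4 / 3) * E / (1 - probe$poisson_ratio^2) * sqrt(probe$radius)
}

#' Hertz contact force for a spherical indenter
#'
#' F = (4/3) * E/(1-nu^2) * sqrt(R) * delta^{3/2}. This is the standard
#' spherical-contact Hertz relation linking indentation depth delta to
#' force for a rigid sphere on an elastic half-space.
#'
#' @param delta indentation depth, meters (>= 0; vectorized).
#' @param E Young's modulus, Pa.
#' @param probe a [probe_spec()].
#' @return force, Newtons.
#' @export
#' @examples
#' hertz_force(1e-6, 470.88, probe_spec())  # ~2.05 nN
hertz_force <- function(delta, E, probe) {
  stopifnot(all(delta >= 0), E > 0)
  hertz_prefactor(E, probe) * delta^1.5
}

# Solve the post-contact force balance for cantilever deflection d:
#   k d = C ((z - z0) - d)^{3/2},  0 <= d < z - z0.
# Substituting x = sqrt(z - z0 - d) gives the cubic C x^3 + k x^2 - k(z-z0) = 0
# with a unique positive root; solved by safeguarded Newton to 1e-12 relative.
solve_contact_deflection <- function(travel, E, probe) {
  C <- hertz_prefactor(E, probe)
  k <- probe$spring_constant
  vapply(travel, function(s) {
    if (s <= 0) return(0)
    f <- function(x) C * x^3 + k * x^2 - k * s
    lo <- 0; hi <- sqrt(s)
    x <- sqrt(s)                       # d = 0 start
    for (i in 1:100) {
      fx <- f(x)
      if (fx > 0) hi <- x else lo <- x
      dfx <- 3 * C * x^2 + 2 * k * x
      xn <- x - fx / dfx
      if (!is.finite(xn) || xn <= lo || xn >= hi) xn <- (lo + hi) / 2
      if (abs(xn - x) <= 1e-13 * max(xn, 1e-300)) { x <- xn; break }
      x <- xn
    }
    s - x^2
  }, numeric(1))
}

#' Generate a synthetic spherical-indenter force curve
#'
#' Simulates a contact-mode indentation ramp against an elastic cell of
#' known Young's modulus. Before contact the deflection is baseline
#' noise; past contact the deflection solves the force balance between
#' cantilever (F = k d) and Hertz contact with the compliance-corrected
#' indentation delta = (z - z0) - d. Ground truth (E, contact point) is
#' recorded on the curve for round-trip testing.
#'
#' @param E_true ground-truth Young's modulus, Pa (> 0).
#' @param probe a [probe_spec()].
#' @param contact_z piezo position of first contact, meters.
#' @param ramp_size total piezo travel, meters (default 1.5 um, must
#'   exceed the contact position).
#' @param n_points samples along the ramp (>= 20).
#' @param noise_sd additive deflection noise SD, meters.
#' @param seed integer seed for the noise.
#' @return a [force_curve()] in meters with `true_E`/`true_contact` set.
#' @export
generate_force_curve <- function(E_true, probe = probe_spec(),
                                 contact_z = 0.5e-6, ramp_size = 1.5e-6,
                                 n_points = 200L, noise_sd = 0, seed = 1L) {
  if (!(E_true > 0)) stop("E_true must be positive")
  stopifnot(n_points >= 20L, ramp_size > contact_z, contact_z >= 0,
            noise_sd >= 0)
  z <- seq(0, ramp_size, length.out = n_points)
  d <- solve_contact_deflection(z - contact_z, E_true, probe)
  if (noise_sd > 0) {
    d <- d + with_local_seed(seed, rnorm(n_points, 0, noise_sd))
  }
  force_curve(z, d, probe, units = "m",
              true_E = E_true, true_contact = contact_z)
}

#' Generate a population of synthetic cell force curves
#'
#' Per-cell moduli are drawn from a normal distribution truncated at
#' E > 0 (resampling), emulating a measured group of cells; each cell
#' yields one force curve with that modulus.
#'
#' @param mean_E population mean Young's modulus, Pa (> 0).
#' @param sd_E population SD, Pa (>= 0).
#' @param n_cells number of cells (>= 1).
#' @param probe a [probe_spec()].
#' @param seed integer seed; cell i uses a derived sub-seed so curves
#'   are individually reproducible.
#' @param contact_z,ramp_size,n_points,noise_sd forwarded to
#'   [generate_force_curve()].
#' @return list of [force_curve()] objects of length `n_cells`.
#' @export
generate_cell_population <- function(mean_E, sd_E, n_cells,
                                     probe = probe_spec(), seed = 1L,
                                     contact_z = 0.5e-6, ramp_size = 1.5e-6,
                                     n_points = 200L, noise_sd = 0) {
  if (!(mean_E > 0)) stop("mean_E must be positive")
  stopifnot(sd_E >= 0, n_cells >= 1L)
  Es <- with_local_seed(seed, {
    out <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      repeat {
        e <- rnorm(1, mean_E, sd_E)
        if (e > 0) break
      }
      out[i] <- e
    }
    out
  })
  lapply(seq_len(n_cells), function(i) {
    generate_force_curve(Es[i], probe = probe, contact_z = contact_z,
                         ramp_size = ramp_size, n_points = n_points,
                         noise_sd = noise_sd,
                         seed = (as.integer(seed) + i) %% .Machine$integer.max)
  })
}
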