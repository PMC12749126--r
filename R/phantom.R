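#' Viscoelastic phantom specification
#'
#' Describes the simulated ground truth for an MRE acquisition: a labelled
#' voxel grid where each region has a complex shear modulus
#' G* = G' + iG'' (Pa), a tissue density, a vibration frequency, and a
#' monochromatic plane shear wave defined by amplitude, propagation
#' direction and (transverse) polarization. Label 0 is background: no
#' displacement is simulated there.
#'
#' Incompressibility is built in: the wave is purely transverse
#' (polarization orthogonal to propagation), so the simulated field is
#' divergence-free and the first Lame constant never enters.
#'
#' @param grid_shape integer vector of 3 positive voxel counts.
#' @param voxel_size numeric vector of 3 voxel edge lengths, meters.
#' @param region_labels integer array of `grid_shape` labels (0 = background),
#'   or NULL for a uniform label-1 phantom.
#' @param region_moduli named list mapping label (as character) to complex
#'   shear modulus in Pa; every G' must be > 0 and G'' >= 0.
#' @param density tissue density, kg/m^3 (default 1000, standard for brain).
#' @param frequency vibration frequency, Hz.
#' @param wave_amplitude displacement amplitude at the phase origin, meters.
#' @param propagation_direction unit 3-vector (normalized internally).
#' @param polarization unit 3-vector orthogonal to the propagation direction.
#' @param seed integer seed recorded with the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 10L),
                         voxel_size = c(0.2e-3, 0.2e-3, 0.3e-3),
                         region_labels = NULL,
                         region_moduli = list(`1` = complex(real = 8070,
                                                            imaginary = 3200)),
                         density = 1000,
                         frequency = 1000,
                         wave_amplitude = 5e-6,
                         propagation_direction = c(1, 0, 0),
                         polarization = c(0, 0, 1),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            density > 0, frequency > 0, wave_amplitude > 0)
  if (is.null(region_labels)) {
    region_labels <- array(1L, dim = grid_shape)
  }
  region_labels <- array(as.integer(region_labels), dim = grid_shape)
  lbls <- setdiff(sort(unique(as.vector(region_labels))), 0L)
  if (length(lbls) == 0L) stop("phantom has no foreground region")
  for (l in lbls) {
    g <- region_moduli[[as.character(l)]]
    if (is.null(g)) stop("no modulus given for region label ", l)
    g <- as.complex(g)
    if (!(Re(g) > 0)) stop("storage modulus must be > 0 (region ", l, ")")
    if (Im(g) < 0) stop("loss modulus must be >= 0 (region ", l, ")")
    region_moduli[[as.character(l)]] <- g
  }
  n <- propagation_direction / sqrt(sum(propagation_direction^2))
  p <- polarization / sqrt(sum(polarization^2))
  if (abs(sum(n * p)) >= 1e-12) {
    stop("polarization must be orthogonal to the propagation direction ",
         "(|dot| = ", format(abs(sum(n * p))), ")")
  }
  structure(list(grid_shape = grid_shape,
                 voxel_size = as.numeric(voxel_size),
                 region_labels = region_labels,
                 region_moduli = region_moduli,
                 density = density,
                 frequency = frequency,
                 wave_amplitude = wave_amplitude,
                 propagation_direction = n,
                 polarization = p,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Complex shear wavenumber of a viscoelastic medium
#'
#' k = omega * sqrt(rho / G*), taking the root with Re(k) > 0 and
#' Im(k) <= 0, so that with the e^{+ik x} spatial convention the wave
#' decays along the propagation direction.
#'
#' @param gstar complex shear modulus, Pa (G' > 0, G'' >= 0).
#' @param density density, kg/m^3.
#' @param frequency frequency, Hz.
#' @return complex wavenumber, rad/m.
#' @export
#' @examples
#' shear_wavenumber(8070 + 3200i, 1000, 1000)  # ~2094.6 - 400.1i rad/m
shear_wavenumber <- function(gstar, density, frequency) {
  omega <- TWO_PI * frequency
  k <- omega * sqrt(as.complex(density) / as.complex(gstar))
  if (Re(k) < 0) k <- -k
  stopifnot(Re(k) > 0, Im(k) <= 1e-12 * Re(k))
  k
}

#' Simulate the steady-state harmonic displacement field of a phantom
#'
#' Evaluates, per voxel, the plane shear wave
#' u(r) = A * p * exp(-i k n . r) with the complex wavenumber of the
#' voxel's region, k = omega * sqrt(rho / G*) taken as the principal
#' root (Re(k) > 0, Im(k) <= 0), so the amplitude decays along the
#' propagation direction for any lossy medium. The field is transverse
#' (divergence-free) and satisfies the shear-wave Helmholtz relation
#' G* Laplacian(u) = -rho omega^2 u to discretization accuracy, which is
#' exactly what algebraic Helmholtz inversion assumes, so the simulator
#' doubles as an inversion oracle. Background voxels (label 0) carry zero
#' displacement. For multi-region phantoms each voxel uses its own
#' region's wavenumber with a common phase origin at the grid corner;
#' the field is smooth within regions and piecewise at region boundaries.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `displacement_field`: complex arrays `x`, `y`,
#'   `z` (meters), plus `frequency`, `voxel_size`, and the per-voxel
#'   ground-truth complex modulus as attribute `gstar_truth`.
#' @export
simulate_wave_field <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  h <- spec$voxel_size
  n <- spec$propagation_direction
  # voxel-center coordinate along the propagation direction
  cx <- (seq_len(d[1]) - 1L) * h[1]
  cy <- (seq_len(d[2]) - 1L) * h[2]
  cz <- (seq_len(d[3]) - 1L) * h[3]
  s <- outer(outer(cx * n[1], cy * n[2], `+`), cz * n[3], `+`)
  lab <- spec$region_labels
  kvol <- array(complex(real = NA_real_), dim = d)
  gtruth <- array(complex(real = NA_real_), dim = d)
  for (l in setdiff(sort(unique(as.vector(lab))), 0L)) {
    g <- spec$region_moduli[[as.character(l)]]
    k <- shear_wavenumber(g, spec$density, spec$frequency)
    sel <- lab == l
    kvol[sel] <- k
    gtruth[sel] <- g
  }
  phase <- array(0i, dim = d)
  sel <- lab != 0L
  phase[sel] <- -1i * kvol[sel] * s[sel]
  amp <- array(0i, dim = d)
  amp[sel] <- spec$wave_amplitude * exp(phase[sel])
  p <- spec$polarization
  field <- structure(list(x = amp * p[1], y = amp * p[2], z = amp * p[3],
                          frequency = spec$frequency,
                          voxel_size = spec$voxel_size),
                     class = "displacement_field")
  attr(field, "gstar_truth") <- gtruth
  attr(field, "support") <- sel
  field
}

#' Construct a displacement field from raw component arrays
#'
#' @param x,y,z complex 3D arrays, meters; same dimensions.
#' @param frequency vibration frequency, Hz.
#' @param voxel_size numeric 3-vector, meters.
#' @return object of class `displacement_field`.
#' @export
displacement_field <- function(x, y, z, frequency, voxel_size) {
  stopifnot(identical(dim(x), dim(y)), identical(dim(x), dim(z)),
            length(dim(x)) == 3L, frequency > 0,
            length(voxel_size) == 3L, all(voxel_size > 0))
  if (!all(is.finite(Re(x)) & is.finite(Im(x))) ||
      !all(is.finite(Re(y)) & is.finite(Im(y))) ||
      !all(is.finite(Re(z)) & is.finite(Im(z)))) {
    stop("displacement field must be finite everywhere")
  }
  structure(list(x = as.array(x) + 0i, y = as.array(y) + 0i,
                 z = as.array(z) + 0i,
                 frequency = frequency, voxel_size = as.numeric(voxel_size)),
            class = "displacement_field")
}

#' Two-region phantom split along one in-plane axis
#'
#' Convenience constructor for validation studies: the grid is split into
#' two slabs (labels 1 and 2) along `split_axis`, each with its own
#' complex modulus. The default propagates the wave along the other
#' in-plane axis so each region carries an undisturbed plane wave and
#' region cross-talk is confined to the stencil width at the boundary.
#'
#' @param g1,g2 complex shear moduli (Pa) of the two regions.
#' @param grid_shape,voxel_size,frequency,density,wave_amplitude,seed
#'   as in [phantom_spec()].
#' @param split_axis axis (1 or 2) perpendicular to the region boundary.
#' @return a [phantom_spec()] with two labelled regions.
#' @export
two_region_phantom <- function(g1, g2,
                               grid_shape = c(96L, 96L, 10L),
                               voxel_size = c(0.2e-3, 0.2e-3, 0.3e-3),
                               frequency = 1000, density = 1000,
                               wave_amplitude = 5e-6, split_axis = 1L,
                               seed = 1L) {
  stopifnot(split_axis %in% c(1L, 2L))
  lab <- array(1L, dim = grid_shape)
  idx <- lapply(grid_shape, seq_len)
  half <- grid_shape[split_axis] %/% 2L
  idx[[split_axis]] <- seq.int(half + 1L, grid_shape[split_axis])
  lab[idx[[1]], idx[[2]], idx[[3]]] <- 2L
  prop <- c(0, 0, 0); prop[3L - split_axis] <- 1   # propagate along the boundary
  phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size,
               region_labels = lab,
               region_moduli = list(`1` = as.complex(g1), `2` = as.complex(g2)),
               density = density, frequency = frequency,
               wave_amplitude = wave_amplitude,
               propagation_direction = prop, polarization = c(0, 0, 1),
               seed = seed)
}
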