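#' Polarity differencing of +/- encoded phase images
#'
#' Each axis is encoded with both gradient polarities; the half
#' difference wrap((phi_plus - phi_minus)/2) doubles the motion-encoded
#' signal-to-background ratio and cancels static background phase
#' exactly. Valid whenever the background does not push the two
#' polarities across different wrap boundaries (guaranteed for the
#' default zero background; see the methods vignette for the limitation
#' under large wrapped backgrounds).
#'
#' @param acq a [encode_acquisition()] result.
#' @return list `diffs[[axis]][[offset]]` of wrapped phase volumes,
#'   radians, for axes `"x"`, `"y"`, `"z"` present in the acquisition.
#' @export
polarity_difference <- function(acq) {
  stopifnot(inherits(acq, "wave_acquisition"))
  dirs <- names(acq$phase)
  axes <- unique(substr(dirs, 2, 2))
  N <- acq$meg$n_phase_offsets
  out <- list()
  for (ax in axes) {
    plus <- paste0("+", ax); minus <- paste0("-", ax)
    if (!(plus %in% dirs) || !(minus %in% dirs)) {
      stop("missing polarity partner for axis '", ax, "'")
    }
    out[[ax]] <- lapply(seq_len(N), function(t) {
      wrap_phase((acq$phase[[plus]][[t]] - acq$phase[[minus]][[t]]) / 2)
    })
  }
  out
}

#' Spatial phase unwrapping (quality-guided, slice by slice)
#'
#' Unwraps a wrapped phase volume one axial slice at a time with a
#' quality-guided region-growing algorithm (pixels integrated in order
#' of local phase smoothness). The output is congruent to the input
#' modulo 2*pi at every masked voxel; for smooth fields whose true
#' per-voxel gradient stays below pi the truth is recovered up to one
#' global 2*pi*n constant per connected component. That constant is
#' normalized by subtracting the mask-median multiple of 2*pi, making
#' results bit-reproducible; it is irrelevant to the Laplacian-based
#' inversion downstream.
#'
#' @param volume wrapped phase volume (3D array, radians).
#' @param mask logical volume of voxels to unwrap; NULL = all.
#' @return unwrapped phase volume; voxels outside the mask are NA.
#' @export
unwrap_phase <- function(volume, mask = NULL) {
  stopifnot(length(dim(volume)) == 3L)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(volume))
  stopifnot(identical(dim(mask), dim(volume)))
  if (!any(mask)) stop("empty mask: nothing to unwrap")
  if (any(!is.finite(volume[mask]))) stop("phase must be finite inside mask")
  out <- array(NA_real_, dim = dim(volume))
  for (s in seq_len(dim(volume)[3])) {
    msk <- matrix(mask[, , s], nrow = dim(volume)[1])
    if (!any(msk)) next
    out[, , s] <- .unwrap2d_cpp(matrix(volume[, , s], nrow = dim(volume)[1]),
                                msk)
  }
  n_med <- round(median((out[mask] - volume[mask]) / TWO_PI))
  out <- out - TWO_PI * n_med
  out
}

#' Temporal harmonic extraction from phase-offset samples
#'
#' Given N uniformly spaced samples of one vibration period, returns the
#' complex fundamental harmonic
#' \deqn{C = (2/N) \sum_t \phi_t e^{-2\pi i t/N},}
#' which rejects the static (DC) component and preserves the amplitude
#' of a pure sinusoid. A residual diagnostic (RMS of the samples after
#' removing DC + fundamental) is attached to flag higher-harmonic or
#' aliased content.
#'
#' @param offset_volumes list of >= 3 phase volumes (radians), ordered by
#'   offset index t = 0..N-1.
#' @return complex volume with attribute `residual_rms` (same grid).
#' @export
extract_harmonic <- function(offset_volumes) {
  N <- length(offset_volumes)
  if (N < 3L) stop("need at least 3 uniformly spaced phase offsets")
  d <- dim(offset_volumes[[1]])
  C <- array(0i, dim = d)
  dc <- array(0, dim = d)
  for (t in seq_len(N) - 1L) {
    C <- C + offset_volumes[[t + 1L]] *
      exp(complex(imaginary = -TWO_PI * t / N))
    dc <- dc + offset_volumes[[t + 1L]]
  }
  C <- (2 / N) * C
  dc <- dc / N
  resid2 <- array(0, dim = d)
  for (t in seq_len(N) - 1L) {
    fit <- dc + Re(C * exp(complex(imaginary = TWO_PI * t / N)))
    resid2 <- resid2 + (offset_volumes[[t + 1L]] - fit)^2
  }
  attr(C, "residual_rms") <- sqrt(resid2 / N)
  C
}

#' Decode complex phase to displacement
#'
#' Inverts the lumped motion-encoding map: u = cphase / xi, meters.
#' Round-trips with [encode_acquisition()] on noiseless, unwrapped-range
#' data.
#'
#' @param cphase list of complex phase volumes per axis (`x`, `y`, `z`),
#'   radians (missing axes are filled with zeros).
#' @param meg a [meg_spec()].
#' @param frequency vibration frequency, Hz.
#' @param voxel_size voxel size 3-vector, meters.
#' @return a [displacement_field()].
#' @export
decode_displacement <- function(cphase, meg, frequency, voxel_size) {
  stopifnot(inherits(meg, "meg_spec"))
  xi <- meg$encoding_sensitivity
  d <- dim(cphase[[1]])
  get <- function(ax) {
    v <- cphase[[ax]]
    if (is.null(v)) array(0i, dim = d) else v / xi
  }
  displacement_field(get("x"), get("y"), get("z"),
                     frequency = frequency, voxel_size = voxel_size)
}

#' Full phase-to-displacement reconstruction
#'
#' Chains polarity differencing, slice-wise unwrapping of every
#' (axis, offset) volume, temporal harmonic extraction, and decoding to
#' meters. This is the reconstruction stage run between acquisition and
#' inversion.
#'
#' @param acq a `wave_acquisition`.
#' @param mask logical volume for unwrapping support; NULL = full grid.
#' @return a [displacement_field()] with attribute `harmonic_residual_rms`.
#' @export
reconstruct_displacement <- function(acq, mask = NULL) {
  stopifnot(inherits(acq, "wave_acquisition"))
  diffs <- polarity_difference(acq)
  cphase <- list()
  resid <- NULL
  for (ax in names(diffs)) {
    unwrapped <- lapply(diffs[[ax]], unwrap_phase, mask = mask)
    if (!is.null(mask)) {
      unwrapped <- lapply(unwrapped, function(v) { v[!mask] <- 0; v })
    }
    C <- extract_harmonic(unwrapped)
    r <- attr(C, "residual_rms")
    resid <- if (is.null(resid)) r else pmax(resid, r)
    cphase[[ax]] <- C
  }
  field <- decode_displacement(cphase, acq$meg, acq$frequency, acq$voxel_size)
  attr(field, "harmonic_residual_rms") <- resid
  field
}
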