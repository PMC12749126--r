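#' Motion-encoding-gradient specification
#'
#' The scanner's motion-encoding gradient converts tissue displacement
#' into image phase. All gradient details (gyromagnetic ratio, gradient
#' amplitude and waveform, timing) are lumped into a single encoding
#' sensitivity `xi` in radians of image phase per meter of displacement
#' amplitude; with the default 1e5 rad/m a 5 um wave stays within +/-pi
#' before background phase is added.
#'
#' @param encoding_sensitivity xi, rad per meter of displacement (> 0).
#' @param n_phase_offsets number of uniformly spaced samples of one
#'   vibration period (>= 3 so the fundamental harmonic is resolvable;
#'   protocol value 4).
#' @param directions character vector of signed encoding axes; must come
#'   in +/- pairs. Default `c("+x","-x","+y","-y","+z","-z")`.
#' @param background_phase static background phase, radians: a scalar or
#'   a volume matching the acquisition grid.
#' @return object of class `meg_spec`.
#' @export
meg_spec <- function(encoding_sensitivity = 1e5,
                     n_phase_offsets = 4L,
                     directions = c("+x", "-x", "+y", "-y", "+z", "-z"),
                     background_phase = 0) {
  stopifnot(encoding_sensitivity > 0, n_phase_offsets >= 3L)
  axes <- substr(directions, 2, 2)
  signs <- substr(directions, 1, 1)
  if (!all(signs %in% c("+", "-")) || !all(axes %in% c("x", "y", "z"))) {
    stop("directions must look like '+x', '-y', ...")
  }
  for (ax in unique(axes)) {
    if (!(paste0("+", ax) %in% directions && paste0("-", ax) %in% directions)) {
      stop("encoding directions must come in +/- pairs; axis '", ax,
           "' is unpaired")
    }
  }
  structure(list(encoding_sensitivity = encoding_sensitivity,
                 n_phase_offsets = as.integer(n_phase_offsets),
                 directions = directions,
                 background_phase = background_phase),
            class = "meg_spec")
}

#' Encode a displacement field into wrapped MRE phase images
#'
#' Applies the lumped linear motion-encoding map: for signed direction d
#' (polarity s_d = +/-1, axis component u_d) and phase offset
#' t = 0..N-1,
#' \deqn{\phi_{d,t} = wrap(s_d \xi \, Re[u_d e^{+2\pi i t/N}] + \phi_{bg}
#'   + \epsilon),}
#' i.e. each offset advances the vibration phase by 2*pi/N, and noise is
#' additive Gaussian on phase (the small-noise limit of complex MR
#' signal noise). The noiseless unwrapped encode-time phase is retained
#' as ground truth for testing the unwrapping stage.
#'
#' @param field a [displacement_field()].
#' @param meg a [meg_spec()].
#' @param noise_sd phase noise standard deviation, radians (>= 0).
#' @param seed integer seed for the noise (required when noise_sd > 0).
#' @param masks named list of logical ROI volumes on the field grid.
#' @param magnitude optional magnitude volume; if NULL one is synthesized
#'   as a smooth positive background plus wave-support contrast.
#' @return object of class `wave_acquisition` with elements `phase`
#'   (list: `phase[[direction]][[offset]]`, wrapped radians), `magnitude`,
#'   `masks`, `meg`, `frequency`, `voxel_size`, and attribute
#'   `truth_phase` (noiseless unwrapped phase, same indexing).
#' @export
encode_acquisition <- function(field, meg, noise_sd = 0, seed = 1L,
                               masks = list(), magnitude = NULL) {
  stopifnot(inherits(field, "displacement_field"), inherits(meg, "meg_spec"),
            noise_sd >= 0)
  d <- dim(field$x)
  for (m in masks) stopifnot(identical(dim(m), d))
  xi <- meg$encoding_sensitivity
  N <- meg$n_phase_offsets
  bg <- meg$background_phase
  if (length(bg) > 1L) stopifnot(identical(dim(bg), d))
  if (is.null(magnitude)) {
    supp <- attr(field, "support")
    if (is.null(supp)) supp <- (Mod(field$x) + Mod(field$y) + Mod(field$z)) > 0
    magnitude <- 100 + 80 * gaussian_smooth_3d(array(as.numeric(supp), d), 1)
  }
  stopifnot(identical(dim(magnitude), d), all(magnitude >= 0))

  phase <- list()
  truth <- list()
  gen_noise <- function() array(rnorm(prod(d), 0, noise_sd), dim = d)
  do_encode <- function() {
    for (dir in meg$directions) {
      s <- if (substr(dir, 1, 1) == "+") 1 else -1
      u <- field[[substr(dir, 2, 2)]]
      phase[[dir]] <- vector("list", N)
      truth[[dir]] <- vector("list", N)
      for (t in seq_len(N) - 1L) {
        clean <- s * xi * Re(u * exp(complex(imaginary = TWO_PI * t / N))) + bg
        if (length(bg) == 1L) clean <- array(clean, dim = d)
        noisy <- if (noise_sd > 0) clean + gen_noise() else clean
        phase[[dir]][[t + 1L]] <- wrap_phase(noisy)
        truth[[dir]][[t + 1L]] <- clean
      }
    }
    list(phase = phase, truth = truth)
  }
  enc <- if (noise_sd > 0) with_local_seed(seed, do_encode()) else do_encode()

  acq <- structure(list(phase = enc$phase, magnitude = magnitude,
                        masks = masks, meg = meg,
                        frequency = field$frequency,
                        voxel_size = field$voxel_size),
                   class = "wave_acquisition")
  attr(acq, "truth_phase") <- enc$truth
  acq
}
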