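#' @useDynLib brainmech, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm sd t.test pt median optimize complete.cases
#' @importFrom utils write.csv read.csv packageVersion
NULL

TWO_PI <- 2 * pi

#' Wrap phase to the half-open interval (-pi, pi]
#'
#' MR phase is measured modulo 2*pi. This maps any real value to the
#' principal interval, with the boundary convention that -pi maps to +pi.
#'
#' @param x numeric array or vector, radians.
#' @return object of the same shape, every value in (-pi, pi].
#' @export
#' @examples
#' wrap_phase(c(0.5, 3.0, 4.0, -pi))
wrap_phase <- function(x) {
  -((pi - x) %% TWO_PI - pi)
}

# Run expr with a local RNG seed, restoring global state afterwards.
# Keeps all randomness explicit-seed only (no global state leakage).
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Shift a 3D array by `by` voxels along `axis`, filling vacated planes
# with `fill`. Used for stencil operations.
shift_array <- function(a, axis, by, fill = NA) {
  d <- dim(a)
  stopifnot(length(d) == 3L)
  idx <- lapply(d, seq_len)
  src <- idx
  n <- d[axis]
  if (abs(by) >= n) {
    out <- array(fill, dim = d)
    return(out)
  }
  if (by > 0) {
    src[[axis]] <- seq_len(n - by)
    dstr <- seq.int(by + 1L, n)
  } else if (by < 0) {
    src[[axis]] <- seq.int(1L - by, n)
    dstr <- seq_len(n + by)
  } else {
    return(a)
  }
  out <- array(fill, dim = d)
  dst <- idx
  dst[[axis]] <- dstr
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Separable Gaussian smoothing of a 3D numeric array with renormalized
# (mask-aware at edges) convolution, so constants are preserved exactly.
gaussian_smooth_3d <- function(a, sd_vox) {
  if (sd_vox == 0) return(a)
  stopifnot(sd_vox > 0)
  r <- max(1L, as.integer(ceiling(4 * sd_vox)))
  off <- seq.int(-r, r)
  w <- exp(-off^2 / (2 * sd_vox^2))
  w <- w / sum(w)
  for (axis in 1:3) {
    num <- array(0, dim = dim(a))
    den <- array(0, dim = dim(a))
    ones <- array(1, dim = dim(a))
    for (j in seq_along(off)) {
      num <- num + w[j] * shift_array(a, axis, off[j], fill = 0)
      den <- den + w[j] * shift_array(ones, axis, off[j], fill = 0)
    }
    a <- num / den
  }
  a
}

# The analytic white-noise variance-reduction factor of the kernel above,
# interior voxels (sum of squared weights, per axis, multiplied over axes).
gaussian_kernel_var_factor <- function(sd_vox) {
  r <- max(1L, as.integer(ceiling(4 * sd_vox)))
  off <- seq.int(-r, r)
  w <- exp(-off^2 / (2 * sd_vox^2))
  w <- w / sum(w)
  sum(w^2)^3
}

# Erode a logical 3D mask by `margin` iterations of 6-neighbourhood erosion,
# additionally clearing `margin` voxels at every array face.
erode_mask <- function(mask, margin = 1L) {
  stopifnot(length(dim(mask)) == 3L)
  m <- mask
  for (i in seq_len(margin)) {
    keep <- m
    for (axis in 1:3) {
      keep <- keep &
        shift_array(m, axis, 1L, fill = FALSE) &
        shift_array(m, axis, -1L, fill = FALSE)
    }
    m <- keep
  }
  d <- dim(mask)
  if (margin > 0) {
    for (axis in 1:3) {
      idx <- lapply(d, seq_len)
      edge <- c(seq_len(min(margin, d[axis])),
                seq.int(max(1L, d[axis] - margin + 1L), d[axis]))
      idx[[axis]] <- unique(edge)
      m[idx[[1]], idx[[2]], idx[[3]]] <- FALSE
    }
  }
  m
}

# Pa -> kPa formatting helper used at the reporting boundary.
format_kpa <- function(pa, digits = 2) {
  sprintf(paste0("%.", digits, "f kPa"), pa / 1000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
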