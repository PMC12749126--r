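# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# No NIfTI package is available in the target R environment, so the
# 348-byte NIfTI-1 header is read and written directly. Scope is
# deliberately narrow: little-endian, single-file magic "n+1",
# float32/float64 data, 3D or 4D, no scaling (scl_slope = 1), no
# extensions. Voxel sizes are stored in mm (NIfTI convention) and
# converted to/from meters at this boundary; everything else in the
# package is SI.

NIFTI_DT_FLOAT32 <- 16L
NIFTI_DT_FLOAT64 <- 64L

open_nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a volume as NIfTI-1
#'
#' @param volume 3D (or 4D) numeric array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size voxel edge lengths in meters (length 3).
#' @param datatype `"float64"` (default; lossless for R doubles) or
#'   `"float32"` (standard for modulus maps).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(volume, path, voxel_size,
                               datatype = c("float64", "float32")) {
  datatype <- match.arg(datatype)
  d <- dim(volume)
  stopifnot(length(d) %in% c(3L, 4L), length(voxel_size) == 3L,
            all(voxel_size > 0))
  ndim <- length(d)
  dims <- integer(8); dims[1] <- ndim; dims[seq_len(ndim) + 1L] <- d
  dims[dims == 0L] <- 1L
  pixdim <- numeric(8)
  pixdim[2:4] <- voxel_size * 1000   # meters -> mm
  pixdim[5] <- 1
  dt <- if (datatype == "float32") NIFTI_DT_FLOAT32 else NIFTI_DT_FLOAT64
  bitpix <- if (datatype == "float32") 32L else 64L

  con <- open_nifti_con(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wchr <- function(s, len) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(len - length(raw_s))), con)
  }
  wint(348L, 4)                       # sizeof_hdr
  writeBin(raw(36), con)              # data_type[10], db_name[18], extents,
                                      # session_error, regular, dim_info
  wint(dims, 2)                       # dim[8]
  wflt(c(0, 0, 0))                    # intent_p1..p3
  wint(0L, 2)                         # intent_code
  wint(dt, 2)                         # datatype
  wint(bitpix, 2)                     # bitpix
  wint(0L, 2)                         # slice_start
  wflt(pixdim)                        # pixdim[8]
  wflt(352)                           # vox_offset
  wflt(1)                             # scl_slope
  wflt(0)                             # scl_inter
  wint(0L, 2); wint(0L, 1); wint(0L, 1)  # slice_end, slice_code, xyzt_units
  wflt(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wint(c(0L, 0L), 4)                  # glmax, glmin
  wchr("brainmech", 80)               # descrip
  wchr("", 24)                        # aux_file
  wint(c(0L, 0L), 2)                  # qform_code, sform_code
  wflt(numeric(18))                   # quatern/qoffset + srow_x/y/z
  wchr("", 16)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)               # extender
  if (datatype == "float32") {
    writeBin(as.numeric(volume), con, size = 4, endian = "little")
  } else {
    writeBin(as.numeric(volume), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file little-endian NIfTI-1 image (optionally
#' gzipped). Only 3D and 4D float32/float64 images without scaling are
#' supported - exactly what this package writes. Axis order is x
#' fastest; indices are 0-based voxel centers.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (array) and `voxel_size` (meters, length 3).
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- open_nifti_con(path, "rb")
  on.exit(close(con))
  rint <- function(n, size) readBin(con, "integer", n = n, size = size,
                                    endian = "little")
  rflt <- function(n) readBin(con, "numeric", n = n, size = 4,
                              endian = "little")
  sizeof <- rint(1, 4)
  if (!identical(sizeof, 348L)) {
    stop("not a little-endian NIfTI-1 file (sizeof_hdr = ", sizeof, ")")
  }
  readBin(con, "raw", n = 36)
  dims <- rint(8, 2)
  ndim <- dims[1]
  if (!(ndim %in% c(3L, 4L))) {
    stop("expected a 3D or 4D volume, got dim[0] = ", ndim,
         " (shape ", paste(dims[seq_len(max(ndim, 1)) + 1L], collapse = "x"),
         ")")
  }
  rflt(3); rint(1, 2)
  dt <- rint(1, 2)
  rint(1, 2); rint(1, 2)              # bitpix, slice_start
  pixdim <- rflt(8)
  vox_offset <- rflt(1)
  scl_slope <- rflt(1); scl_inter <- rflt(1)
  if (!(dt %in% c(NIFTI_DT_FLOAT32, NIFTI_DT_FLOAT64))) {
    stop("unsupported NIfTI datatype code ", dt)
  }
  # bytes consumed so far: 4+36+16+12+2+2+2+2+32+4+4+4 = 120
  here <- 120
  readBin(con, "raw", n = round(vox_offset) - here)
  d <- dims[seq_len(ndim) + 1L]
  n <- prod(d)
  size <- if (dt == NIFTI_DT_FLOAT32) 4L else 8L
  data <- readBin(con, "numeric", n = n, size = size, endian = "little")
  if (length(data) != n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  list(data = array(data, dim = d),
       voxel_size = pixdim[2:4] / 1000)  # mm -> meters
}
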