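# On-disk layout of the two dataset kinds.
#
# MRE acquisition directory:
#   phase_d{axis}{sign}_t{offset}.nii.gz   wrapped phase per direction/offset
#   magnitude.nii.gz                       magnitude image
#   mask_{name}.nii.gz                     ROI masks (0/1)
#   ground_truth.json                      MEG spec, frequency, truth moduli
#
# AFM curves: one CSV per cell with header `z_m,deflection_m` (or
# `z_m,deflection_V`), plus a JSON sidecar per curve holding the probe
# spec, units, and synthetic ground truth.

dir_tag <- function(dir) {
  paste0("d", substr(dir, 2, 2), substr(dir, 1, 1))
}

#' Write a wave acquisition to a directory
#'
#' @param acq a `wave_acquisition`.
#' @param dir output directory (created if needed).
#' @param truth optional named list of extra ground-truth metadata
#'   stored in the JSON sidecar (e.g. per-region complex moduli).
#' @return `dir`, invisibly.
#' @export
write_acquisition <- function(acq, dir, truth = list()) {
  stopifnot(inherits(acq, "wave_acquisition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- acq$voxel_size
  for (d in names(acq$phase)) {
    for (t in seq_along(acq$phase[[d]])) {
      f <- file.path(dir, sprintf("phase_%s_t%d.nii.gz", dir_tag(d), t - 1L))
      write_nifti_volume(acq$phase[[d]][[t]], f, vs)
    }
  }
  write_nifti_volume(acq$magnitude, file.path(dir, "magnitude.nii.gz"), vs)
  for (nm in names(acq$masks)) {
    write_nifti_volume(array(as.numeric(acq$masks[[nm]]),
                             dim = dim(acq$masks[[nm]])),
                       file.path(dir, sprintf("mask_%s.nii.gz", nm)), vs)
  }
  side <- list(
    schema = "brainmech-acquisition-1",
    frequency_hz = acq$frequency,
    voxel_size_m = vs,
    meg = list(encoding_sensitivity = acq$meg$encoding_sensitivity,
               n_phase_offsets = acq$meg$n_phase_offsets,
               directions = acq$meg$directions,
               background_phase = if (length(acq$meg$background_phase) == 1L)
                 acq$meg$background_phase else "volume"),
    truth = truth)
  jsonlite::write_json(side, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a wave acquisition from a directory
#'
#' @param dir directory written by [write_acquisition()].
#' @return a `wave_acquisition`.
#' @export
read_acquisition <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                              simplifyVector = TRUE)
  meg <- meg_spec(encoding_sensitivity = side$meg$encoding_sensitivity,
                  n_phase_offsets = side$meg$n_phase_offsets,
                  directions = side$meg$directions,
                  background_phase =
                    if (identical(side$meg$background_phase, "volume")) 0
                    else side$meg$background_phase)
  phase <- list()
  vs <- NULL
  for (d in meg$directions) {
    phase[[d]] <- vector("list", meg$n_phase_offsets)
    for (t in seq_len(meg$n_phase_offsets)) {
      f <- file.path(dir, sprintf("phase_%s_t%d.nii.gz", dir_tag(d), t - 1L))
      v <- read_nifti_volume(f)
      phase[[d]][[t]] <- v$data
      vs <- v$voxel_size
    }
  }
  mag <- read_nifti_volume(file.path(dir, "magnitude.nii.gz"))$data
  masks <- list()
  for (f in list.files(dir, pattern = "^mask_.*\\.nii(\\.gz)?$")) {
    nm <- sub("^mask_", "", sub("\\.nii(\\.gz)?$", "", f))
    masks[[nm]] <- read_nifti_volume(file.path(dir, f))$data > 0.5
  }
  acq <- structure(list(phase = phase, magnitude = mag, masks = masks,
                        meg = meg, frequency = side$frequency_hz,
                        voxel_size = as.numeric(side$voxel_size_m)),
                   class = "wave_acquisition")
  attr(acq, "truth") <- side$truth
  acq
}

#' Write a force curve as CSV (+ JSON sidecar)
#'
#' @param curve a [force_curve()].
#' @param path output CSV path; the sidecar replaces `.csv` with `.json`.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  col <- if (curve$units == "V") "deflection_V" else "deflection_m"
  df <- data.frame(z_m = curve$z, d = curve$deflection)
  names(df)[2] <- col
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(schema = "brainmech-forcecurve-1",
               units = curve$units,
               probe = unclass(curve$probe),
               true_E_pa = curve$true_E,
               true_contact_m = curve$true_contact)
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a force curve from CSV
#'
#' @param path CSV with header `z_m,deflection_m` or `z_m,deflection_V`;
#'   a JSON sidecar (same basename) supplies the probe. Without a
#'   sidecar, `probe` must be given.
#' @param probe optional [probe_spec()] overriding the sidecar.
#' @return a [force_curve()].
#' @export
read_force_curve <- function(path, probe = NULL) {
  df <- read.csv(path)
  if (!identical(names(df)[1], "z_m") ||
      !(names(df)[2] %in% c("deflection_m", "deflection_V"))) {
    stop("expected columns z_m and deflection_m/deflection_V in ", path)
  }
  units <- if (names(df)[2] == "deflection_V") "V" else "m"
  sidecar <- sub("\\.csv$", ".json", path)
  tE <- NULL; tC <- NULL
  if (is.null(probe)) {
    if (!file.exists(sidecar)) {
      stop("no probe given and no sidecar found for ", path)
    }
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    probe <- do.call(probe_spec, side$probe)
    tE <- side$true_E_pa; tC <- side$true_contact_m
  } else if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    tE <- side$true_E_pa; tC <- side$true_contact_m
  }
  force_curve(df$z_m, df[[2]], probe, units = units,
              true_E = tE, true_contact = tC)
}

#' Write elastogram maps as NIfTI (float32) plus ROI report
#'
#' @param maps an [ahi_invert()] result.
#' @param report a [roi_statistics()] result (or NULL to skip).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_elastograms <- function(maps, report, dir) {
  stopifnot(inherits(maps, "elastogram_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- attr(maps, "voxel_size") %||% c(1e-3, 1e-3, 1e-3)
  for (nm in c("storage", "loss", "stiffness")) {
    v <- maps[[nm]]
    v[!maps$valid] <- 0
    write_nifti_volume(v, file.path(dir, paste0(nm, ".nii.gz")), vs,
                       datatype = "float32")
  }
  write_nifti_volume(array(as.numeric(maps$valid), dim = dim(maps$valid)),
                     file.path(dir, "valid.nii.gz"), vs, datatype = "float32")
  if (!is.null(report)) {
    write.csv(as.data.frame(report), file.path(dir, "roi_report.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(as.data.frame(report),
                         file.path(dir, "roi_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
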