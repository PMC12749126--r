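# Run configuration: one YAML/JSON file drives the whole two-scale
# pipeline. Top-level schema (schema_version 1):
#
#   schema_version: 1
#   stages: [simulate-mre, recon, invert, report, simulate-afm, fit-afm,
#            compare]
#   out: output directory
#   phantom:   {grid_shape, voxel_size_m, regions: {label: {storage_pa,
#              loss_pa}}, region_geometry: homogeneous|two_region,
#              density_kg_m3, frequency_hz, wave_amplitude_m,
#              propagation, polarization, seed}
#   meg:       {encoding_sensitivity, n_phase_offsets, directions,
#              background_phase, noise_sd, seed}
#   inversion: {density_kg_m3, frequency_hz, smoothing_sd, laplacian,
#              edge_margin}
#   afm:       {probe: {radius_m, spring_constant_n_m,
#              deflection_sensitivity_m_v, poisson_ratio}, groups:
#              {name: {mean_E_pa, sd_E_pa, n_cells, seed}}, contact_z_m,
#              ramp_size_m, n_points, noise_sd_m}
#
# Unknown keys anywhere in this schema are rejected; every stochastic
# stage must carry an explicit seed.

known_keys <- list(
  top = c("schema_version", "stages", "out", "phantom", "meg", "inversion",
          "afm"),
  phantom = c("grid_shape", "voxel_size_m", "regions", "region_geometry",
              "density_kg_m3", "frequency_hz", "wave_amplitude_m",
              "propagation", "polarization", "seed", "split_axis"),
  meg = c("encoding_sensitivity", "n_phase_offsets", "directions",
          "background_phase", "noise_sd", "seed"),
  inversion = c("density_kg_m3", "frequency_hz", "smoothing_sd", "laplacian",
                "edge_margin"),
  afm = c("probe", "groups", "contact_z_m", "ramp_size_m", "n_points",
          "noise_sd_m"),
  probe = c("radius_m", "spring_constant_n_m", "deflection_sensitivity_m_v",
            "poisson_ratio"),
  group = c("mean_E_pa", "sd_E_pa", "n_cells", "seed"),
  region = c("storage_pa", "loss_pa"))

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "))
  }
}

#' Read and validate a run configuration
#'
#' Accepts YAML (`.yaml`/`.yml`) or JSON. Validation is strict: unknown
#' keys are rejected with their name, and any stage that draws random
#' numbers (noisy MRE encoding, AFM group generation) must carry an
#' explicit integer seed.
#'
#' @param path config file path.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a raw config list (already parsed).
#' @export
validate_run_config <- function(cfg) {
  check_keys(cfg, known_keys$top, "config")
  if (is.null(cfg$schema_version) || cfg$schema_version != 1) {
    stop("config must declare schema_version: 1")
  }
  stages <- cfg$stages %||% character()
  ok <- c("simulate-mre", "recon", "invert", "report", "simulate-afm",
          "fit-afm", "compare")
  bad <- setdiff(stages, ok)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$out)) stop("config key 'out' (output directory) is required")
  if (!is.null(cfg$phantom)) {
    check_keys(cfg$phantom, known_keys$phantom, "phantom")
    for (r in cfg$phantom$regions) check_keys(r, known_keys$region,
                                             "phantom.regions")
    if (is.null(cfg$phantom$seed)) stop("phantom stage requires a seed")
  }
  if (!is.null(cfg$meg)) {
    check_keys(cfg$meg, known_keys$meg, "meg")
    if ((cfg$meg$noise_sd %||% 0) > 0 && is.null(cfg$meg$seed)) {
      stop("meg stage with noise_sd > 0 requires a seed")
    }
  }
  if (!is.null(cfg$inversion)) {
    check_keys(cfg$inversion, known_keys$inversion, "inversion")
  }
  if (!is.null(cfg$afm)) {
    check_keys(cfg$afm, known_keys$afm, "afm")
    if (!is.null(cfg$afm$probe)) check_keys(cfg$afm$probe, known_keys$probe,
                                            "afm.probe")
    for (nm in names(cfg$afm$groups)) {
      g <- cfg$afm$groups[[nm]]
      check_keys(g, known_keys$group, paste0("afm.groups.", nm))
      if (is.null(g$seed)) stop("afm group '", nm, "' requires a seed")
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

phantom_from_config <- function(pc) {
  moduli <- lapply(pc$regions, function(r) {
    complex(real = r$storage_pa, imaginary = r$loss_pa)
  })
  geometry <- pc$region_geometry %||% "homogeneous"
  gs <- as.integer(pc$grid_shape %||% c(96L, 96L, 10L))
  vs <- as.numeric(pc$voxel_size_m %||% c(0.2e-3, 0.2e-3, 0.3e-3))
  if (geometry == "two_region") {
    stopifnot(length(moduli) == 2L)
    two_region_phantom(moduli[[1]], moduli[[2]], grid_shape = gs,
                       voxel_size = vs,
                       frequency = pc$frequency_hz %||% 1000,
                       density = pc$density_kg_m3 %||% 1000,
                       wave_amplitude = pc$wave_amplitude_m %||% 5e-6,
                       split_axis = as.integer(pc$split_axis %||% 1L),
                       seed = pc$seed)
  } else {
    phantom_spec(grid_shape = gs, voxel_size = vs,
                 region_moduli = stats::setNames(moduli, names(pc$regions)),
                 density = pc$density_kg_m3 %||% 1000,
                 frequency = pc$frequency_hz %||% 1000,
                 wave_amplitude = pc$wave_amplitude_m %||% 5e-6,
                 propagation_direction = as.numeric(pc$propagation %||%
                                                      c(1, 0, 0)),
                 polarization = as.numeric(pc$polarization %||% c(0, 0, 1)),
                 seed = pc$seed)
  }
}

meg_from_config <- function(mc) {
  meg_spec(encoding_sensitivity = mc$encoding_sensitivity %||% 1e5,
           n_phase_offsets = mc$n_phase_offsets %||% 4L,
           directions = mc$directions %||%
             c("+x", "-x", "+y", "-y", "+z", "-z"),
           background_phase = mc$background_phase %||% 0)
}

inversion_from_config <- function(ic, frequency) {
  inversion_config(density = ic$density_kg_m3 %||% 1000,
                   frequency = ic$frequency_hz %||% frequency,
                   smoothing_sd = ic$smoothing_sd %||% 0,
                   laplacian = ic$laplacian %||% "central",
                   edge_margin = ic$edge_margin %||% 1L)
}

probe_from_config <- function(pc) {
  if (is.null(pc)) return(probe_spec())
  probe_spec(radius = pc$radius_m %||% 6e-6,
             spring_constant = pc$spring_constant_n_m %||% 0.1,
             deflection_sensitivity = pc$deflection_sensitivity_m_v %||% 33e-9,
             poisson_ratio = pc$poisson_ratio %||% 0.5)
}

#' Run the configured pipeline stages
#'
#' Executes the requested stages in their canonical order
#' (simulate-mre, recon, invert, report, simulate-afm, fit-afm,
#' compare), writing every product under the config's output directory
#' and finishing with a manifest (`manifest.json`) of output-file MD5
#' hashes, stage parameters and package version, so a run is exactly
#' reproducible and verifiable. A stage failure aborts with the failing
#' stage named.
#'
#' @param config a validated `run_config` (or a path to one).
#' @param quiet suppress stage log lines (logged to stderr).
#' @return list with the in-memory products of the stages that ran
#'   (`roi_report`, `comparison`, ...), invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[brainmech] ", ...)
  stage <- function(name, expr) {
    say("stage ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  stages <- config$stages
  products <- list()
  acq <- NULL; field <- NULL

  if ("simulate-mre" %in% stages) {
    stage("simulate-mre", {
      spec <- phantom_from_config(config$phantom)
      meg <- meg_from_config(config$meg %||% list())
      sim <- simulate_wave_field(spec)
      masks <- region_masks(spec)
      acq <- encode_acquisition(sim, meg,
                                 noise_sd = config$meg$noise_sd %||% 0,
                                 seed = config$meg$seed %||% spec$seed,
                                 masks = masks)
      truth <- lapply(spec$region_moduli, function(g) {
        list(storage_pa = Re(g), loss_pa = Im(g))
      })
      write_acquisition(acq, file.path(out_dir, "acquisition"),
                        truth = list(regions = truth,
                                     seed = spec$seed))
    })
  }
  if ("recon" %in% stages) {
    stage("recon", {
      if (is.null(acq)) acq <- read_acquisition(file.path(out_dir,
                                                          "acquisition"))
      field <- reconstruct_displacement(acq)
      for (ax in c("x", "y", "z")) {
        write_nifti_volume(Re(field[[ax]]),
                           file.path(out_dir,
                                     sprintf("displacement_%s_real.nii.gz",
                                             ax)),
                           field$voxel_size)
        write_nifti_volume(Im(field[[ax]]),
                           file.path(out_dir,
                                     sprintf("displacement_%s_imag.nii.gz",
                                             ax)),
                           field$voxel_size)
      }
    })
  }
  if ("invert" %in% stages || "report" %in% stages) {
    stage("invert", {
      if (is.null(acq)) acq <- read_acquisition(file.path(out_dir,
                                                          "acquisition"))
      if (is.null(field)) field <- reconstruct_displacement(acq)
      cfg <- inversion_from_config(config$inversion %||% list(),
                                   acq$frequency)
      maps <- ahi_invert(field, cfg)
      attr(maps, "voxel_size") <- field$voxel_size
      report <- if (length(acq$masks) > 0) {
        roi_statistics(maps, acq$masks)
      } else NULL
      write_elastograms(maps, report, file.path(out_dir, "elastograms"))
      products$roi_report <- report
      products$maps_qc <- maps$qc
    })
  }
  if (any(c("simulate-afm", "fit-afm", "compare") %in% stages)) {
    stage("afm", {
      probe <- probe_from_config(config$afm$probe)
      afm_dir <- file.path(out_dir, "afm")
      dir.create(afm_dir, showWarnings = FALSE, recursive = TRUE)
      summaries <- list()
      for (nm in names(config$afm$groups)) {
        g <- config$afm$groups[[nm]]
        curves <- generate_cell_population(
          mean_E = g$mean_E_pa, sd_E = g$sd_E_pa %||% 0,
          n_cells = g$n_cells, probe = probe, seed = g$seed,
          contact_z = config$afm$contact_z_m %||% 0.5e-6,
          ramp_size = config$afm$ramp_size_m %||% 1.5e-6,
          n_points = config$afm$n_points %||% 200L,
          noise_sd = config$afm$noise_sd_m %||% 0)
        if ("simulate-afm" %in% stages) {
          gd <- file.path(afm_dir, nm)
          dir.create(gd, showWarnings = FALSE)
          for (i in seq_along(curves)) {
            write_force_curve(curves[[i]],
                              file.path(gd, sprintf("cell_%03d.csv", i)))
          }
        }
        if (any(c("fit-afm", "compare") %in% stages)) {
          fits <- lapply(curves, analyze_curve)
          summaries[[nm]] <- analyze_group(fits, name = nm)
          df <- data.frame(
            cell = seq_along(fits),
            youngs_modulus_pa = vapply(fits, `[[`, numeric(1),
                                       "youngs_modulus"),
            contact_point_m = vapply(fits, `[[`, numeric(1), "contact_point"),
            converged = vapply(fits, `[[`, logical(1), "converged"))
          write.csv(df, file.path(afm_dir, paste0(nm, "_fits.csv")),
                    row.names = FALSE, quote = FALSE)
        }
      }
      if ("compare" %in% stages && length(summaries) >= 2L) {
        cmp <- compare_groups(summaries[[1]], summaries[[2]])
        jsonlite::write_json(
          list(group_a = summaries[[1]]$name, group_b = summaries[[2]]$name,
               n = c(cmp$group_a$n, cmp$group_b$n),
               mean_E_pa = c(cmp$group_a$mean_E, cmp$group_b$mean_E),
               sd_E_pa = c(cmp$group_a$sd_E, cmp$group_b$sd_E),
               sem_E_pa = c(cmp$group_a$sem_E, cmp$group_b$sem_E),
               t_statistic = cmp$t_statistic, df = cmp$df,
               p_value = cmp$p_value,
               percent_difference = cmp$percent_difference),
          file.path(afm_dir, "comparison.json"),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
        products$comparison <- cmp
      }
      products$group_summaries <- summaries
    })
  }

  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.json")
  hashes <- tools::md5sum(file.path(out_dir, files))
  names(hashes) <- files
  manifest <- list(schema_version = 1,
                   package_version = as.character(packageVersion("brainmech")),
                   stages = stages,
                   files = as.list(hashes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", length(files), " files, manifest written")
  invisible(products)
}

#' Binary ROI masks of a phantom's labelled regions
#'
#' One mask per foreground label, named `region<label>`, eroded by
#' `erode` voxels so ROI statistics stay clear of region boundaries and
#' stencil margins.
#'
#' @param spec a [phantom_spec()].
#' @param erode erosion iterations (default 2).
#' @return named list of logical volumes.
#' @export
region_masks <- function(spec, erode = 2L) {
  lab <- spec$region_labels
  out <- list()
  for (l in setdiff(sort(unique(as.vector(lab))), 0L)) {
    out[[paste0("region", l)]] <- erode_mask(lab == l, erode)
  }
  out
}
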