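# File formats: NIfTI image series with JSON schedule sidecars, 32-bit
# float TIFF PLM maps, JSON phantom specs and tidy CSV profiles.

#' Write an image series as NIfTI plus a JSON schedule sidecar
#'
#' The stack is stored with the preparation-time axis as the 4th NIfTI
#' dimension (`rows x cols x 1 x ntimes`); the mask and background ROI go
#' into a companion label volume (`1` = foreground, `2` = background ROI)
#' and the schedule, orientation and pixel size into `<prefix>.json`.
#'
#' @param series an `image_series`.
#' @param prefix path prefix (files `<prefix>.nii.gz`,
#'   `<prefix>_inv.nii.gz` if present, `<prefix>_regions.nii.gz`,
#'   `<prefix>.json`).
#' @return `prefix`, invisibly.
#' @export
write_series <- function(series, prefix) {
  to4d <- function(stack) {
    d <- dim(stack)
    aperm(array(stack, c(d[1], d[2], d[3], 1)), c(2, 3, 4, 1))
  }
  RNifti::writeNifti(RNifti::asNifti(to4d(series$data)),
                     paste0(prefix, ".nii.gz"))
  if (!is.null(series$data_inverted))
    RNifti::writeNifti(RNifti::asNifti(to4d(series$data_inverted)),
                       paste0(prefix, "_inv.nii.gz"))
  regions <- matrix(0L, nrow(series$mask), ncol(series$mask))
  regions[series$mask] <- 1L
  regions[series$background_roi] <- 2L
  RNifti::writeNifti(RNifti::asNifti(regions),
                     paste0(prefix, "_regions.nii.gz"))
  sched <- series$schedule
  jsonlite::write_json(list(
    parameter_kind = sched$parameter_kind,
    prep_times_ms = sched$prep_times_ms,
    spinlock_amplitude_hz = sched$spinlock_amplitude_hz,
    n_pulses = sched$n_pulses,
    pulse_duration_ms = sched$pulse_duration_ms,
    has_inversion_pair = sched$has_inversion_pair,
    sample_orientation_deg = series$sample_orientation_deg,
    pixel_size_mm = series$pixel_size_mm
  ), paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' Read an image series written by [write_series()]
#'
#' @param prefix path prefix used at write time.
#' @return an `image_series`.
#' @export
read_series <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  from4d <- function(path) {
    arr <- as.array(RNifti::readNifti(path))
    aperm(arr, c(4, 1, 2, 3))[, , , 1, drop = TRUE]
  }
  data <- from4d(paste0(prefix, ".nii.gz"))
  inv_path <- paste0(prefix, "_inv.nii.gz")
  data_inv <- if (file.exists(inv_path)) from4d(inv_path) else NULL
  regions <- as.array(RNifti::readNifti(paste0(prefix, "_regions.nii.gz")))
  regions <- matrix(regions, dim(data)[2], dim(data)[3])
  schedule <- structure(list(
    parameter_kind = meta$parameter_kind,
    prep_times_ms = meta$prep_times_ms,
    spinlock_amplitude_hz = meta$spinlock_amplitude_hz,
    n_pulses = meta$n_pulses,
    pulse_duration_ms = meta$pulse_duration_ms,
    has_inversion_pair = isTRUE(meta$has_inversion_pair)
  ), class = "acquisition_schedule")
  structure(list(
    data = data, data_inverted = data_inv, schedule = schedule,
    sample_orientation_deg = meta$sample_orientation_deg,
    mask = regions == 1, background_roi = regions == 2,
    pixel_size_mm = meta$pixel_size_mm
  ), class = "image_series")
}

#' Write PLM maps as 32-bit float TIFFs
#'
#' @param maps a `plm_maps` object.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return the directory, invisibly.
#' @export
write_plm_maps <- function(maps, dir, prefix = "plm") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # TIFF samples are stored in [0, 1]; the physical scale goes in the sidecar
  ret_scale <- max(maps$retardation, 1e-12)
  tiff::writeTIFF(maps$orientation / 180,
                  file.path(dir, paste0(prefix, "_orientation.tif")),
                  bits.per.sample = 32L)
  tiff::writeTIFF(maps$retardation / ret_scale,
                  file.path(dir, paste0(prefix, "_retardation.tif")),
                  bits.per.sample = 32L)
  tiff::writeTIFF(maps$mask * 1,
                  file.path(dir, paste0(prefix, "_mask.tif")),
                  bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_size_um = maps$pixel_size_um,
                            orientation_scale = 180,
                            retardation_scale = ret_scale),
                       file.path(dir, paste0(prefix, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read PLM maps written by [write_plm_maps()]
#'
#' @param dir directory holding the TIFFs.
#' @param prefix filename prefix.
#' @return a `plm_maps` object.
#' @export
read_plm_maps <- function(dir, prefix = "plm") {
  rd <- function(name) {
    m <- tiff::readTIFF(file.path(dir, paste0(prefix, "_", name, ".tif")))
    matrix(m, nrow(m), ncol(m))
  }
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  structure(list(orientation = rd("orientation") * meta$orientation_scale,
                 retardation = rd("retardation") * meta$retardation_scale,
                 mask = rd("mask") > 0.5,
                 pixel_size_um = meta$pixel_size_um),
            class = "plm_maps")
}

#' Tidy data.frame of depth profiles
#'
#' @param profiles list of [depth_profile()]s.
#' @return data.frame with columns `sample`, `parameter`,
#'   `orientation_deg`, `depth_fraction`, `value`.
#' @export
profiles_to_df <- function(profiles) {
  if (inherits(profiles, "depth_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample = attr(p, "sample_id"),
               parameter = attr(p, "kind"),
               orientation_deg = attr(p, "orientation_deg"),
               depth_fraction = p$depth_fraction,
               value = p$value)
  }))
}
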