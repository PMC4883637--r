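#' Dynamic PET series
#'
#' A 4D grid of activity concentration (Bq/mL) plus its frame schedule.
#' Activity is assumed decay-corrected to injection time by the
#' reconstruction; this package performs no decay correction.
#'
#' @param voxels 4D numeric array `(x, y, z, frame)` of activity
#'   concentration in Bq/mL.
#' @param spacing Voxel spacing in mm for the three spatial axes.
#' @param schedule A [frame_schedule()] whose frame count matches the
#'   fourth dimension of `voxels`.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(voxels, spacing, schedule) {
  if (is.null(dim(voxels)) || length(dim(voxels)) != 4L)
    stop("voxels must be a 4D array (x, y, z, frame)")
  if (!inherits(schedule, "frame_schedule"))
    stop("schedule must be a frame_schedule")
  if (dim(voxels)[4L] != n_frames(schedule))
    stop("time axis length (", dim(voxels)[4L], ") does not match schedule frame count (",
         n_frames(schedule), ")")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be positive on all three spatial axes")
  structure(list(voxels = voxels, spacing = spacing, schedule = schedule),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("dynamic_series: %dx%dx%d voxels @ %.2gx%.2gx%.2g mm, %d frames (%.0f s)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              d[4], sum(x$schedule$frame_duration)))
  invisible(x)
}

#' Read a dynamic PET series (4D NIfTI + frame-schedule CSV)
#'
#' @param image_path Path to a 4D NIfTI-1 volume (Bq/mL, decay-corrected).
#' @param schedule_path Path to a CSV with header
#'   `frame_start_s,frame_duration_s` and one row per frame.
#' @return A [dynamic_series()].
#' @export
read_dynamic_series <- function(image_path, schedule_path) {
  nif <- read_nifti(image_path)
  if (length(dim(nif$data)) != 4L)
    stop("image is not 4D: ", image_path)
  schedule <- read_frame_schedule(schedule_path)
  if (dim(nif$data)[4L] != n_frames(schedule))
    stop("schedule has ", n_frames(schedule), " rows but image has ",
         dim(nif$data)[4L], " time points")
  dynamic_series(nif$data, nif$spacing, schedule)
}

#' Write a dynamic series as NIfTI plus schedule CSV
#' @param series A [dynamic_series()].
#' @param image_path Output NIfTI path.
#' @param schedule_path Output schedule CSV path.
#' @param datatype Storage datatype passed to [write_nifti()].
#' @return `image_path`, invisibly.
#' @export
write_dynamic_series <- function(series, image_path, schedule_path,
                                 datatype = "float64") {
  write_nifti(series$voxels, image_path, series$spacing, datatype)
  write_frame_schedule(series$schedule, schedule_path)
  invisible(image_path)
}

#' Write a label/mask volume with the geometry of a reference series
#'
#' Stored as uint8 when all labels fit in 0..255, else uint16.
#'
#' @param labels 3D integer array (0 = background) or logical mask.
#' @param reference A [dynamic_series()] providing the spatial grid.
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(labels, reference, path) {
  if (is.logical(labels)) labels <- array(as.integer(labels), dim = dim(labels))
  if (is.null(dim(labels)) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (!all(dim(labels) == dim(reference$voxels)[1:3]))
    stop("label volume shape does not match the reference spatial grid")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  dtype <- if (max(labels) <= 255) "uint8" else "uint16"
  write_nifti(labels, path, reference$spacing, dtype)
  invisible(path)
}

#' Read a 3D label/mask volume
#' @param path NIfTI path.
#' @return 3D integer array.
#' @export
read_mask <- function(path) {
  nif <- read_nifti(path)
  if (length(dim(nif$data)) != 3L) stop("mask is not 3D: ", path)
  array(as.integer(round(nif$data)), dim = dim(nif$data))
}

#' Acquisition context: injected dose and heart rate
#'
#' The two scalars the operator must supply: the injected dose
#' (decay-corrected to injection time) and the heart rate at the start of
#' the scan. Dose is given in MBq at the interface (clinical convention)
#' and stored in Bq.
#'
#' @param injected_dose_MBq Injected dose in MBq (> 0).
#' @param heart_rate Heart rate in beats per minute (> 0).
#' @param injection_time Injection time in seconds relative to scan start;
#'   default 0 (scan starting simultaneously with injection).
#' @return An object of class `acquisition_context` with `injected_dose_Bq`,
#'   `heart_rate_bpm`, `injection_time_s`.
#' @export
acquisition_context <- function(injected_dose_MBq, heart_rate, injection_time = 0) {
  if (!is.numeric(injected_dose_MBq) || length(injected_dose_MBq) != 1L ||
      injected_dose_MBq <= 0)
    stop("injected_dose_MBq must be a single positive number")
  if (!is.numeric(heart_rate) || length(heart_rate) != 1L || heart_rate <= 0)
    stop("heart_rate must be a single positive number (beats/min)")
  structure(list(injected_dose_Bq = injected_dose_MBq * 1e6,
                 heart_rate_bpm = as.numeric(heart_rate),
                 injection_time_s = as.numeric(injection_time)),
            class = "acquisition_context")
}
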