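#' Time-activity curve (TAC)
#'
#' Per-frame mean activity concentration of a region, indexed by frame
#' mid-time. Negative values (possible in reconstructed PET) are preserved.
#'
#' @param mid_time Frame mid-times in seconds.
#' @param value Activity concentration per frame, Bq/mL.
#' @param schedule Optional [frame_schedule()]; when supplied, its
#'   mid-times must agree with `mid_time` to within floating tolerance.
#' @return An object of class `tac`.
#' @export
tac <- function(mid_time, value, schedule = NULL) {
  mid_time <- as.numeric(mid_time)
  value <- as.numeric(value)
  if (length(mid_time) != length(value))
    stop("mid_time and value must have the same length")
  if (length(mid_time) < 1L) stop("TAC must have at least one frame")
  if (anyNA(mid_time) || anyNA(value)) stop("TAC contains missing values")
  if (any(diff(mid_time) <= 0)) stop("mid_time must be strictly increasing")
  if (!is.null(schedule)) {
    if (!inherits(schedule, "frame_schedule"))
      stop("schedule must be a frame_schedule")
    if (n_frames(schedule) != length(value))
      stop("TAC length does not match schedule frame count")
    if (max(abs(frame_mid(schedule) - mid_time)) > 1e-6 * max(1, max(abs(mid_time))))
      stop("mid_time is inconsistent with the schedule")
  }
  structure(list(mid_time = mid_time, value = value, schedule = schedule),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  pk <- which.max(x$value)
  cat(sprintf("tac: %d frames, peak %.4g Bq/mL at %.1f s\n",
              length(x$value), x$value[pk], x$mid_time[pk]))
  invisible(x)
}

#' Write a TAC to CSV
#'
#' Header is `frame_mid_s,activity_Bq_per_mL`, plus
#' `frame_start_s,frame_duration_s` when the TAC carries a schedule.
#'
#' @param tac A [tac()].
#' @param path Output CSV path.
#' @param extra Optional data.frame of extra columns (e.g. an
#'   `extrapolated` flag for composite curves).
#' @return `path`, invisibly.
#' @export
write_tac <- function(tac, path, extra = NULL) {
  df <- data.frame(frame_mid_s = tac$mid_time,
                   activity_Bq_per_mL = tac$value)
  if (!is.null(tac$schedule)) {
    df$frame_start_s <- tac$schedule$frame_start
    df$frame_duration_s <- tac$schedule$frame_duration
  }
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a TAC from CSV
#'
#' Expects the header written by [write_tac()]; a schedule is attached when
#' the optional `frame_start_s,frame_duration_s` columns are present.
#' Values pass through unmodified (no clamping of negatives).
#'
#' @param path CSV file path.
#' @return A [tac()].
#' @export
read_tac <- function(path) {
  if (!file.exists(path)) stop("TAC file not found: ", path)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("malformed TAC CSV: ", conditionMessage(e)))
  req <- c("frame_mid_s", "activity_Bq_per_mL")
  if (!all(req %in% names(df)))
    stop("TAC CSV must have columns frame_mid_s,activity_Bq_per_mL")
  if (nrow(df) == 0L) stop("TAC CSV has no rows")
  if (!all(vapply(df[req], is.numeric, logical(1))))
    stop("TAC CSV has non-numeric cells")
  sch <- NULL
  if (all(c("frame_start_s", "frame_duration_s") %in% names(df)))
    sch <- frame_schedule(df$frame_start_s, df$frame_duration_s)
  tac(df$frame_mid_s, df$activity_Bq_per_mL, sch)
}
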