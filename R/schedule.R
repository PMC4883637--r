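#' Frame schedule of a dynamic PET reconstruction
#'
#' A frame schedule is the sequence of acquisition time-bin start times and
#' durations (both in seconds) that a dynamic series was rebinned into.
#' Frames must be non-overlapping and in temporal order.
#'
#' @param frame_start Numeric vector of frame start times in seconds.
#' @param frame_duration Numeric vector of frame durations in seconds.
#' @return An object of class `frame_schedule` with fields `frame_start`
#'   and `frame_duration`.
#' @examples
#' sch <- frame_schedule(c(0, 10, 15), c(10, 5, 5))
#' frame_mid(sch)
#' @export
frame_schedule <- function(frame_start, frame_duration) {
  frame_start <- as.numeric(frame_start)
  frame_duration <- as.numeric(frame_duration)
  if (length(frame_start) != length(frame_duration))
    stop("frame_start and frame_duration must have the same length")
  if (length(frame_start) < 1L)
    stop("schedule must contain at least one frame")
  if (anyNA(frame_start) || anyNA(frame_duration))
    stop("schedule contains missing values")
  if (any(frame_duration <= 0))
    stop("all frame durations must be > 0")
  n <- length(frame_start)
  if (n > 1L) {
    if (any(diff(frame_start) <= 0))
      stop("frame_start must be strictly increasing")
    tol <- 1e-9
    if (any(frame_start[-n] + frame_duration[-n] > frame_start[-1L] + tol))
      stop("frames overlap: frame_start[i] + frame_duration[i] must not exceed frame_start[i+1]")
  }
  structure(list(frame_start = frame_start, frame_duration = frame_duration),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("frame_schedule: %d frames, %.0f s total (%.1f-%.1f s)\n",
              n_frames(x), sum(x$frame_duration),
              x$frame_start[1L], frame_end(x)[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a schedule
#' @param schedule A `frame_schedule`.
#' @return Integer frame count.
#' @export
n_frames <- function(schedule) length(schedule$frame_start)

#' Frame mid-times
#'
#' Mid-time of each frame, `frame_start + frame_duration/2`; strictly
#' increasing for a valid schedule. TAC values are indexed by mid-time.
#'
#' @param schedule A `frame_schedule`.
#' @return Numeric vector of mid-times in seconds.
#' @export
frame_mid <- function(schedule) schedule$frame_start + schedule$frame_duration / 2

#' Frame end times
#' @param schedule A `frame_schedule`.
#' @return Numeric vector of end times in seconds.
#' @export
frame_end <- function(schedule) schedule$frame_start + schedule$frame_duration

#' Standard 27-min acetate framing (29 frames)
#'
#' 1 x 10 s, 12 x 5 s, 5 x 10 s, 2 x 30 s, 3 x 60 s, 3 x 120 s, 3 x 300 s;
#' 1620 s total. The short early frames sample the bolus first pass.
#'
#' @return A `frame_schedule` with 29 frames.
#' @export
acetate_framing <- function() {
  dur <- c(rep(10, 1), rep(5, 12), rep(10, 5), rep(30, 2),
           rep(60, 3), rep(120, 3), rep(300, 3))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' Standard 6-min water framing (22 frames)
#'
#' 1 x 10 s, 8 x 5 s, 4 x 20 s, 2 x 15 s, 3 x 20 s, 2 x 30 s, 2 x 60 s;
#' 400 s total.
#'
#' @return A `frame_schedule` with 22 frames.
#' @export
water_framing <- function() {
  dur <- c(rep(10, 1), rep(5, 8), rep(20, 4), rep(15, 2),
           rep(20, 3), rep(30, 2), rep(60, 2))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' Read a frame schedule from a CSV sidecar
#'
#' Expects a header `frame_start_s,frame_duration_s` and one row per frame.
#'
#' @param path CSV file path.
#' @return A `frame_schedule`.
#' @export
read_frame_schedule <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  df <- utils::read.csv(path)
  req <- c("frame_start_s", "frame_duration_s")
  if (!all(req %in% names(df)))
    stop("schedule CSV must have columns frame_start_s,frame_duration_s")
  if (nrow(df) == 0L) stop("schedule CSV has no frames")
  if (!all(vapply(df[req], is.numeric, logical(1))))
    stop("schedule CSV has non-numeric cells")
  frame_schedule(df$frame_start_s, df$frame_duration_s)
}

#' Write a frame schedule to CSV
#' @param schedule A `frame_schedule`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_schedule <- function(schedule, path) {
  df <- data.frame(frame_start_s = schedule$frame_start,
                   frame_duration_s = schedule$frame_duration)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
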