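# First-pass peak isolation.
#
# Recirculating tracer contaminates the tail of the bolus peak and would
# inflate its area. The descending limb of the blood TAC is therefore cut
# at the last of the steep downslope frames and replaced by a two-point
# exponential: the pair of successive frames (t1, t2) is the last pair in
# the contiguous run of downslopes exceeding a fraction (default 0.75) of
# the maximum downslope; the exponential passes exactly through both
# anchor values. No assumption is made about the upslope — original frame
# values are retained through t2.

#' First-pass isolation configuration
#'
#' @param downslope_threshold_fraction Fraction of the maximum downslope a
#'   frame pair must reach to qualify as an anchor candidate; in (0, 1],
#'   default 0.75.
#' @param exp_frame_value_convention How the exponential tail is turned
#'   into frame values: `"analytic_mean"` (default; the exponential's mean
#'   over the frame window, matching per-frame average activity) or
#'   `"midpoint"` (value at the frame mid-time, hand-checkable).
#' @param extend_beyond_scan If `TRUE`, the closed-form exponential tail
#'   beyond the last frame is added to the AUC. Default `FALSE`: the AUC
#'   sums the scheduled frames only.
#' @return An object of class `first_pass_config`.
#' @export
first_pass_config <- function(downslope_threshold_fraction = 0.75,
                              exp_frame_value_convention = c("analytic_mean", "midpoint"),
                              extend_beyond_scan = FALSE) {
  if (!is.numeric(downslope_threshold_fraction) ||
      downslope_threshold_fraction <= 0 || downslope_threshold_fraction > 1)
    stop("downslope_threshold_fraction must be in (0, 1]")
  structure(list(downslope_threshold_fraction = downslope_threshold_fraction,
                 exp_frame_value_convention = match.arg(exp_frame_value_convention),
                 extend_beyond_scan = isTRUE(extend_beyond_scan)),
            class = "first_pass_config")
}

#' Per-pair downslopes of the descending limb
#'
#' For each pair of successive frames at or after the TAC's global-maximum
#' frame, the downslope is `(value_i - value_{i+1}) / (mid_{i+1} - mid_i)`
#' in Bq/mL/s (frames may have unequal durations, so slopes are per
#' second). Pairs on the ascending limb are excluded.
#'
#' @param tac A [tac()] with at least 3 frames and its global maximum
#'   before the last frame.
#' @return data.frame with `t1_index`, `t2_index`, `downslope`.
#' @export
frame_downslopes <- function(tac) {
  n <- length(tac$value)
  if (n < 3L) stop("TAC must have at least 3 frames")
  pk <- which.max(tac$value)
  if (pk == n) stop("TAC peaks at the last frame: no descending limb")
  i <- pk:(n - 1L)
  data.frame(t1_index = i, t2_index = i + 1L,
             downslope = (tac$value[i] - tac$value[i + 1L]) /
                         (tac$mid_time[i + 1L] - tac$mid_time[i]))
}

#' Isolate the first-pass peak of a blood TAC
#'
#' Identifies the anchor pair (t1, t2), fits the two-point exponential
#' `v(t) = value(t1) * exp(-lambda * (t - mid(t1)))` with
#' `lambda = log(value(t1)/value(t2)) / (mid(t2) - mid(t1))`, and builds the
#' composite curve: original frame values through t2, exponential tail
#' after. Among the contiguous run of supra-threshold downslope pairs
#' containing the maximum, the *last* pair is used, anchoring the
#' extrapolation as late as possible on the genuine first-pass downslope.
#'
#' @param tac A [tac()] carrying a schedule (needed for frame windows).
#' @param config A [first_pass_config()].
#' @return Object of class `first_pass_curve`: `t1_index`, `t2_index`,
#'   `decay_rate` (1/s), `anchor_value` (Bq/mL at mid(t2)),
#'   `composite_values`, `extrapolated` (logical per frame), `auc`
#'   (Bq·s/mL), `schedule`, `config`.
#' @export
isolate_first_pass <- function(tac, config = first_pass_config()) {
  if (is.null(tac$schedule))
    stop("TAC must carry a frame schedule for first-pass isolation")
  ds <- frame_downslopes(tac)
  smax <- max(ds$downslope)
  if (smax <= 0)
    stop("descending limb has no positive downslope; cannot isolate first pass")
  thr <- config$downslope_threshold_fraction * smax
  qual <- ds$downslope >= thr
  imax <- which.max(ds$downslope)
  last <- imax
  while (last < nrow(ds) && qual[last + 1L]) last <- last + 1L
  t1 <- ds$t1_index[last]
  t2 <- ds$t2_index[last]
  v1 <- tac$value[t1]; v2 <- tac$value[t2]
  if (v1 <= 0 || v2 <= 0) stop("anchor frame values must be strictly positive")
  if (v1 <= v2) stop("anchor values must decrease: value(t1) > value(t2)")
  m1 <- tac$mid_time[t1]; m2 <- tac$mid_time[t2]
  lambda <- log(v1 / v2) / (m2 - m1)

  n <- length(tac$value)
  comp <- tac$value
  extrap <- rep(FALSE, n)
  if (t2 < n) {
    j <- (t2 + 1L):n
    extrap[j] <- TRUE
    if (config$exp_frame_value_convention == "midpoint") {
      comp[j] <- v2 * exp(-lambda * (tac$mid_time[j] - m2))
    } else {
      fs <- tac$schedule$frame_start[j]
      fe <- frame_end(tac$schedule)[j]
      du <- tac$schedule$frame_duration[j]
      comp[j] <- v2 / (lambda * du) *
        (exp(-lambda * (fs - m2)) - exp(-lambda * (fe - m2)))
    }
  }
  fp <- structure(list(t1_index = t1, t2_index = t2,
                       decay_rate = lambda, anchor_value = v2,
                       composite_values = comp, extrapolated = extrap,
                       schedule = tac$schedule, config = config),
                  class = "first_pass_curve")
  fp$auc <- integrate_first_pass(fp, tac$schedule)
  fp
}

#' @export
print.first_pass_curve <- function(x, ...) {
  cat(sprintf("first_pass_curve: anchors t1/t2 at frames %d/%d (%.1f/%.1f s), lambda %.4g 1/s, AUC %.6g Bq*s/mL\n",
              x$t1_index, x$t2_index,
              frame_mid(x$schedule)[x$t1_index], frame_mid(x$schedule)[x$t2_index],
              x$decay_rate, x$auc))
  invisible(x)
}

#' Integrate a first-pass composite curve over the frame schedule
#'
#' AUC = sum over frames of duration x frame value: original frame values
#' through t2, the exponential under the configured convention after
#' (`analytic_mean` integrates the exponential over each frame window and
#' divides by duration). With `extend_beyond_scan`, the closed-form tail
#' `value(scan end)/lambda` is added.
#'
#' @param fp A `first_pass_curve`.
#' @param schedule The [frame_schedule()] to integrate over.
#' @return AUC in Bq·s/mL.
#' @export
integrate_first_pass <- function(fp, schedule = fp$schedule) {
  if (length(fp$composite_values) != n_frames(schedule))
    stop("composite curve and schedule disagree on frame count")
  if (fp$decay_rate <= 0) stop("decay_rate must be > 0")
  auc <- sum(schedule$frame_duration * fp$composite_values)
  if (isTRUE(fp$config$extend_beyond_scan)) {
    t_end <- frame_end(schedule)[n_frames(schedule)]
    m2 <- frame_mid(schedule)[fp$t2_index]
    v_end <- fp$anchor_value * exp(-fp$decay_rate * (t_end - m2))
    auc <- auc + v_end / fp$decay_rate
  }
  auc
}

#' Export a composite first-pass curve as a TAC CSV
#'
#' Writes the composite values with an `extrapolated` column flagging the
#' exponential-tail frames.
#'
#' @param fp A `first_pass_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_first_pass <- function(fp, path) {
  ct <- tac(frame_mid(fp$schedule), fp$composite_values, fp$schedule)
  write_tac(ct, path, extra = data.frame(extrapolated = fp$extrapolated))
}
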