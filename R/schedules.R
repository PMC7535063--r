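#' Dynamic PET frame schedule
#'
#' A frame schedule is a set of contiguous, non-overlapping acquisition
#' frames, in seconds post-injection, with the first frame starting at 0.
#'
#' @param start_s numeric vector of frame start times (seconds).
#' @param end_s numeric vector of frame end times (seconds).
#' @return A `frame_schedule` data frame with columns `start_s`, `end_s`.
#' @examples
#' frame_schedule(c(0, 15, 30), c(15, 30, 60))
#' @export
frame_schedule <- function(start_s, end_s) {
  if (length(start_s) != length(end_s) || length(start_s) == 0L)
    stop_input("frame starts and ends must be non-empty vectors of equal length")
  o <- order(start_s)
  start_s <- as.numeric(start_s[o])
  end_s <- as.numeric(end_s[o])
  if (any(!is.finite(start_s)) || any(!is.finite(end_s)))
    stop_input("frame times must be finite")
  if (any(end_s <= start_s))
    stop_input("every frame must end after it starts")
  if (abs(start_s[1L]) > 1e-9)
    stop_input("first frame must start at 0 s")
  if (length(start_s) > 1L) {
    gap <- start_s[-1L] - end_s[-length(end_s)]
    bad <- which(abs(gap) > 1e-6)
    if (length(bad))
      stop_input(sprintf("frames must be contiguous; gap/overlap after frame %d", bad[1L]))
  }
  structure(data.frame(start_s = start_s, end_s = end_s),
            class = c("frame_schedule", "data.frame"))
}

#' Default frame binning schedule
#'
#' The printed rebinning recipe (4x15, 4x30, 2x60, 5x120, 3x300, 9x600 s)
#' sums to 120 min, but the dynamic acquisition lasts 60 min; the default
#' keeps the printed frame durations truncated at the scan end, which for a
#' 60-min scan yields 21 frames covering exactly 3600 s.
#'
#' @param scan_minutes scan duration in minutes (default 60).
#' @return A [frame_schedule()].
#' @examples
#' nrow(default_frame_schedule())       # 21 frames
#' nrow(default_frame_schedule(120))    # the full 27-frame recipe
#' @export
default_frame_schedule <- function(scan_minutes = 60) {
  durs <- c(rep(15, 4), rep(30, 4), rep(60, 2), rep(120, 5), rep(300, 3), rep(600, 9))
  ends <- cumsum(durs)
  keep <- ends <= scan_minutes * 60 + 1e-9
  if (!any(keep)) stop_input("scan too short for any frame")
  ends <- ends[keep]
  frame_schedule(c(0, ends[-length(ends)]), ends)
}

#' Frame midpoints in minutes
#' @param schedule a [frame_schedule()].
#' @return numeric vector of frame midpoints (min).
#' @export
frame_midpoints_min <- function(schedule) {
  (schedule$start_s + schedule$end_s) / 2 / 60
}

#' Frame durations in seconds
#' @param schedule a [frame_schedule()].
#' @return numeric vector of durations (s).
#' @export
frame_durations_s <- function(schedule) {
  schedule$end_s - schedule$start_s
}

#' Default arterial blood sampling schedule
#'
#' A pre-injection sample at t = 0, then every 15 s during the first
#' 2 min, then 2.5, 3, 5, 10, 20, 40 and 60 min post-injection.
#'
#' @return numeric vector of sampling times (min).
#' @export
default_blood_times <- function() {
  c(0, seq(0.25, 2, by = 0.25), 2.5, 3, 5, 10, 20, 40, 60)
}

# classed input error so callers/tests can distinguish user errors
stop_input <- function(msg) {
  stop(structure(class = c("fdgrepeat_input_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_config <- function(msg) {
  stop(structure(class = c("fdgrepeat_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
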