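#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule is the time axis shared by every time-activity curve in a
#' study: per-frame start times and durations in minutes, with frame midpoints
#' derived as `start + duration/2`. Frames must be non-overlapping and in
#' increasing order.
#'
#' @param start Numeric vector of frame start times (minutes).
#' @param duration Numeric vector of frame durations (minutes), same length.
#' @return An object of class `frame_schedule` with fields `start`,
#'   `duration`, `midpoint`, `end` and `F` (number of frames).
#' @examples
#' sch <- frame_schedule(start = c(0, 1, 2), duration = c(1, 1, 1))
#' sch$midpoint
#' @export
frame_schedule <- function(start, duration) {
  start <- as.numeric(start)
  duration <- as.numeric(duration)
  if (length(start) != length(duration) || length(start) == 0L)
    stop("start and duration must be non-empty vectors of equal length")
  if (any(!is.finite(start)) || any(!is.finite(duration)))
    stop("frame times must be finite")
  if (any(duration <= 0)) stop("frame durations must be positive")
  if (is.unsorted(start, strictly = TRUE))
    stop("frame starts must be strictly increasing")
  ends <- start + duration
  if (any(start[-1] < ends[-length(ends)] - 1e-9))
    stop("frames must be non-overlapping")
  structure(
    list(start = start, duration = duration,
         midpoint = start + duration / 2, end = ends,
         F = length(start)),
    class = "frame_schedule")
}

#' Build a frame schedule from groups of identical frames
#'
#' The default reproduces the 26-frame, 60-minute dynamic protocol commonly
#' used for PiB: 12 x 10-second frames, 3 x 1-minute frames and 11 x 5-minute
#' frames, starting at injection (t = 0).
#'
#' @param groups Data frame (or list) with columns `n` (frame count per group)
#'   and `dur` (frame duration in minutes).
#' @param t0 Start time of the first frame (minutes), default 0.
#' @return A [frame_schedule()].
#' @examples
#' sch <- make_schedule()
#' sch$F                   # 26
#' max(sch$end)            # 60
#' @export
make_schedule <- function(groups = data.frame(n = c(12L, 3L, 11L),
                                              dur = c(1 / 6, 1, 5)),
                          t0 = 0) {
  n <- as.integer(groups$n)
  dur <- as.numeric(groups$dur)
  if (any(n <= 0L) || any(dur <= 0)) stop("frame counts and durations must be positive")
  durations <- rep(dur, times = n)
  start <- t0 + cumsum(c(0, durations[-length(durations)]))
  frame_schedule(start, durations)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.4g to %.4g min\n",
              x$F, x$start[1], x$end[x$F]))
  invisible(x)
}

is_frame_schedule <- function(x) inherits(x, "frame_schedule")

same_schedule <- function(a, b, tol = 1e-9) {
  a$F == b$F && max(abs(a$start - b$start)) < tol &&
    max(abs(a$duration - b$duration)) < tol
}
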