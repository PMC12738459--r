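#' Construct a frame schedule from frame durations
#'
#' @param durations numeric vector of frame durations in seconds; frames are
#'   laid out contiguously from t = 0.
#' @return a [FrameSchedule-class]
#' @examples
#' frameSchedule(c(10, rep(5, 8)))
#' @export
frameSchedule <- function(durations) {
  durations <- as.numeric(durations)
  starts <- cumsum(c(0, durations[-length(durations)]))
  new("FrameSchedule", start = starts, duration = durations)
}

#' The default 25-frame, 30-minute dynamic schedule
#'
#' Built from six duration groups (1 x 10, 8 x 5, 5 x 20, 5 x 60, 3 x 150 and
#' 3 x 300 s): 25 contiguous frames of progressively increasing duration
#' covering 0-1800 s. The final 300-s frame (25-30 min) supplies the
#' late-dynamic SUV window.
#'
#' @return a [FrameSchedule-class] with 25 frames totalling 1800 s
#' @export
defaultFrameSchedule <- function() {
  validateFrames()
}

#' Build and check a dynamic schedule from duration groups
#'
#' Expands `(count, duration)` groups into a contiguous schedule and asserts
#' the protocol invariants: with the default groups, exactly 25 frames
#' totalling 1800 s (30 min). Malformed custom schedules fail loudly.
#'
#' @param groups list of `c(count, duration_s)` pairs.
#' @param expectFrames,expectTotal expected frame count and total duration (s);
#'   set to `NA` to skip the corresponding assertion.
#' @return a [FrameSchedule-class]
#' @examples
#' validateFrames() # the scanning protocol's 25-frame schedule
#' @export
validateFrames <- function(groups = list(c(1, 10), c(8, 5), c(5, 20),
                                         c(5, 60), c(3, 150), c(3, 300)),
                           expectFrames = 25, expectTotal = 1800) {
  for (g in groups) {
    if (length(g) != 2 || any(!is.finite(g)) || g[1] < 1 || g[2] <= 0)
      stop("malformed duration group; need c(count >= 1, duration_s > 0)")
  }
  durations <- unlist(lapply(groups, function(g) rep(g[2], g[1])))
  sched <- frameSchedule(durations)
  if (!is.na(expectFrames) && length(durations) != expectFrames)
    stop(sprintf("schedule has %d frames, expected %d", length(durations), expectFrames))
  if (!is.na(expectTotal) && abs(sum(durations) - expectTotal) > 1e-9)
    stop(sprintf("schedule covers %.0f s, expected %.0f s", sum(durations), expectTotal))
  sched
}

#' @rdname frameAccessors
#' @export
nFrames <- function(schedule) length(schedule@start)

#' Frame schedule accessors
#'
#' Start times, durations, midpoints and total duration of a
#' [FrameSchedule-class], in seconds (`units = "s"`) or minutes.
#'
#' @param schedule a [FrameSchedule-class]
#' @param units `"s"` or `"min"`
#' @name frameAccessors
#' @export
frameStarts <- function(schedule, units = c("s", "min")) {
  units <- match.arg(units)
  if (units == "s") schedule@start else schedule@start / 60
}

#' @rdname frameAccessors
#' @export
frameDurations <- function(schedule, units = c("s", "min")) {
  units <- match.arg(units)
  if (units == "s") schedule@duration else schedule@duration / 60
}

#' @rdname frameAccessors
#' @export
frameMidpoints <- function(schedule, units = c("s", "min")) {
  units <- match.arg(units)
  m <- schedule@start + schedule@duration / 2
  if (units == "s") m else m / 60
}

#' @rdname frameAccessors
#' @export
totalDuration <- function(schedule, units = c("s", "min")) {
  units <- match.arg(units)
  tot <- sum(schedule@duration)
  if (units == "s") tot else tot / 60
}

#' Construct a time-activity curve
#'
#' @param schedule a [FrameSchedule-class]
#' @param activity numeric, frame-averaged activity (kBq/mL), one per frame
#' @return a [TimeActivityCurve-class]
#' @export
timeActivityCurve <- function(schedule, activity) {
  new("TimeActivityCurve", schedule = schedule, activity = as.numeric(activity))
}

#' @rdname timeActivityCurve
#' @param tac a [TimeActivityCurve-class]
#' @export
tacActivity <- function(tac) tac@activity

#' @rdname timeActivityCurve
#' @export
tacSchedule <- function(tac) tac@schedule
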