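#' Frame schedules for dynamic PET
#'
#' A frame schedule is the temporal backbone of all kinetics in this package:
#' an ordered set of acquisition frames, each with a start and end time in
#' minutes post-injection. Frames must not overlap, but gaps between frames
#' are allowed (e.g. a mid-scan break during which the subject leaves the
#' scanner).
#'
#' @param starts numeric vector of frame start times (minutes).
#' @param ends numeric vector of frame end times (minutes).
#' @return An object of class `frame_schedule`: a list with elements
#'   `starts`, `ends`, `durations`, `mids` (frame midpoints) and `gaps`
#'   (a two-column matrix of gap intervals, possibly zero rows).
#' @examples
#' sch <- frame_schedule(c(0, 1, 2), c(1, 2, 4))
#' sch$durations
#' @export
frame_schedule <- function(starts, ends) {
  starts <- as.numeric(starts)
  ends <- as.numeric(ends)
  if (length(starts) != length(ends) || length(starts) == 0L)
    stop("'starts' and 'ends' must be nonempty vectors of equal length")
  if (any(!is.finite(starts)) || any(!is.finite(ends)))
    stop("frame times must be finite")
  if (is.unsorted(starts, strictly = TRUE))
    stop("frame starts must be strictly increasing")
  if (any(ends <= starts))
    stop("every frame end must exceed its start")
  n <- length(starts)
  if (n > 1L && any(ends[-n] > starts[-1L] + 1e-9))
    stop("frames must not overlap (ends[i] <= starts[i+1])")
  gaps <- cbind(start = ends[-n], end = starts[-1L])
  gaps <- gaps[gaps[, "end"] - gaps[, "start"] > 1e-9, , drop = FALSE]
  structure(list(
    starts = starts, ends = ends,
    durations = ends - starts,
    mids = (starts + ends) / 2,
    gaps = gaps
  ), class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule: %d frames, %.4g-%.4g min", length(x$starts),
              x$starts[1], x$ends[length(x$ends)]))
  if (nrow(x$gaps) > 0)
    cat(sprintf(", %d gap(s) [%s]", nrow(x$gaps),
                paste(sprintf("%.4g-%.4g", x$gaps[, 1], x$gaps[, 2]),
                      collapse = ", ")))
  cat(">\n")
  invisible(x)
}

#' @export
length.frame_schedule <- function(x) length(x$starts)

#' Two-segment 37-frame tau-PET acquisition schedule
#'
#' The 120-minute dynamic acquisition used throughout this package's
#' validation work: a first segment of 29 frames covering 0-65 min
#' (6 x 10 s, 6 x 20 s, 2 x 30 s, 2 x 60 s, 2 x 120 s, 11 x 300 s),
#' a 15-minute break, then a second segment of 8 x 300 s frames covering
#' 80-120 min. The 90-110 min uptake window used for SUV corresponds to
#' four 5-min frames of the second segment.
#'
#' @return A [frame_schedule] with 37 frames spanning 0-65 and 80-120 min.
#' @export
mk6240_frame_schedule <- function() {
  dur_s <- c(rep(10, 6), rep(20, 6), rep(30, 2), rep(60, 2),
             rep(120, 2), rep(300, 11))
  starts1 <- cumsum(c(0, dur_s[-length(dur_s)])) / 60
  ends1 <- cumsum(dur_s) / 60
  starts2 <- 80 + 5 * (0:7)
  ends2 <- starts2 + 5
  frame_schedule(c(starts1, starts2), c(ends1, ends2))
}

#' Frames fully contained in a time window
#'
#' @param schedule a [frame_schedule].
#' @param t0,t1 window bounds in minutes, `t0 < t1`.
#' @return Integer vector of frame indices with `start >= t0` and
#'   `end <= t1`. Errors if no frame is fully contained (e.g. a window
#'   falling inside the acquisition break).
#' @export
frames_in_window <- function(schedule, t0, t1) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (!(t0 < t1)) stop("window requires t0 < t1")
  idx <- which(schedule$starts >= t0 - 1e-9 & schedule$ends <= t1 + 1e-9)
  if (length(idx) == 0L)
    stop(sprintf("no frames fully contained in window [%g, %g] min", t0, t1))
  idx
}

#' Read or write a frame schedule as JSON
#'
#' Serialized as a list of `[start, end]` pairs in minutes.
#'
#' @param schedule a [frame_schedule].
#' @param path file path.
#' @return `read_schedule_json` returns a [frame_schedule];
#'   `write_schedule_json` returns `path` invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  stopifnot(inherits(schedule, "frame_schedule"))
  frames <- Map(c, schedule$starts, schedule$ends)
  jsonlite::write_json(frames, path, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  frames <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(frames)) frames <- do.call(rbind, frames)
  frame_schedule(frames[, 1], frames[, 2])
}
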