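#' Dynamic PET frame schedules
#'
#' A frame schedule describes the temporal binning of a dynamic PET
#' acquisition: per-frame start and end times in minutes. The default
#' striatal [18F]-FDOPA protocol acquires 89 min in 24 frames
#' (4 x 1, 3 x 2, 3 x 3, 14 x 5 min).
#'
#' @param frame_start numeric, frame start times (min), strictly increasing.
#' @param frame_end numeric, frame end times (min), `frame_end > frame_start`
#'   per frame and frames must not overlap.
#' @return An object of class `frame_schedule`: a data frame with columns
#'   `start`, `end`, `mid` (minutes).
#' @export
frame_schedule <- function(frame_start, frame_end) {
  if (length(frame_start) == 0L) stop("schedule must contain at least one frame")
  if (length(frame_start) != length(frame_end))
    stop("frame_start and frame_end must have equal length")
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_end)))
    stop("frame times must be finite")
  if (frame_start[1] < 0) stop("first frame start must be >= 0")
  if (is.unsorted(frame_start, strictly = TRUE))
    stop("frame starts must be strictly increasing")
  if (any(frame_end <= frame_start)) stop("each frame must have end > start")
  if (length(frame_start) > 1 &&
      any(frame_end[-length(frame_end)] > frame_start[-1] + 1e-12))
    stop("frames must not overlap")
  out <- data.frame(start = frame_start, end = frame_end,
                    mid = (frame_start + frame_end) / 2)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Build a contiguous frame schedule from (count, duration) blocks
#'
#' @param blocks list of length-2 numeric vectors `c(count, duration_min)`.
#'   Frames are laid out consecutively starting at 0 min.
#' @return A [frame_schedule()].
#' @examples
#' # the 24-frame / 89-min dynamic FDOPA protocol
#' sched <- build_frame_schedule(list(c(4, 1), c(3, 2), c(3, 3), c(14, 5)))
#' nrow(sched)           # 24
#' max(sched$end)        # 89
#' @export
build_frame_schedule <- function(blocks) {
  if (length(blocks) == 0L) stop("block list must not be empty")
  durations <- unlist(lapply(blocks, function(b) {
    count <- b[[1]]; dur <- b[[2]]
    if (count < 1 || count != round(count)) stop("block counts must be integers >= 1")
    if (dur <= 0) stop("block durations must be > 0")
    rep(dur, count)
  }))
  ends <- cumsum(durations)
  frame_schedule(c(0, ends[-length(ends)]), ends)
}

#' The 24-frame, 89-minute dynamic FDOPA schedule
#'
#' Convenience wrapper for the standard striatal FDOPA acquisition:
#' 4 x 1, 3 x 2, 3 x 3, 14 x 5 min frames.
#' @return A [frame_schedule()] with 24 frames totalling 89 min.
#' @export
default_pet_schedule <- function() {
  build_frame_schedule(list(c(4, 1), c(3, 2), c(3, 3), c(14, 5)))
}

#' Frame-wise time-activity curve
#'
#' @param schedule a [frame_schedule()].
#' @param activity numeric, mean activity per frame (kBq/mL); finite, one
#'   value per frame.
#' @param region_label free-text region name.
#' @return An object of class `tac`: list with `schedule`, `activity`,
#'   `region_label`.
#' @export
tac <- function(schedule, activity, region_label = "") {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(activity) != nrow(schedule))
    stop("activity length must match the number of frames")
  if (any(!is.finite(activity))) stop("activity values must be finite")
  structure(list(schedule = schedule, activity = as.numeric(activity),
                 region_label = region_label),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("Time-activity curve '%s': %d frames over [%g, %g] min, peak %.3g kBq/mL\n",
              x$region_label, nrow(x$schedule), x$schedule$start[1],
              max(x$schedule$end), max(x$activity)))
  invisible(x)
}

#' Write / read a TAC as CSV
#'
#' Columns: `frame_start_min`, `frame_end_min`, `activity_kBq_ml`.
#' @param x a [tac()].
#' @param path file path.
#' @return `read_tac_csv` returns a [tac()].
#' @export
write_tac_csv <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  utils::write.csv(data.frame(frame_start_min = x$schedule$start,
                              frame_end_min = x$schedule$end,
                              activity_kBq_ml = x$activity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @param region_label region name attached on read.
#' @export
read_tac_csv <- function(path, region_label = "") {
  d <- utils::read.csv(path)
  need <- c("frame_start_min", "frame_end_min", "activity_kBq_ml")
  if (!all(need %in% names(d)))
    stop("TAC CSV must have columns ", paste(need, collapse = ", "))
  tac(frame_schedule(d$frame_start_min, d$frame_end_min),
      d$activity_kBq_ml, region_label)
}
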