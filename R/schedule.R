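#' Dynamic PET frame schedule
#'
#' Build a frame schedule as a tibble of contiguous acquisition frames. The
#' default reproduces the 27-frame, 90-minute dynamic schedule used for
#' bolus synaptic-density scans: 6 x 0.5 min, 3 x 1 min, 2 x 2 min,
#' 16 x 5 min.
#'
#' @param durations Numeric vector of frame durations in minutes, in
#'   acquisition order. Frames are contiguous and start at 0.
#' @return A tibble with columns `frame`, `start`, `end`, `mid` and `dur`
#'   (all times in minutes).
#' @examples
#' sched <- frame_schedule()
#' nrow(sched)          # 27
#' max(sched$end)       # 90
#' @export
frame_schedule <- function(durations = c(rep(0.5, 6), rep(1, 3), rep(2, 2), rep(5, 16))) {
  if (length(durations) == 0L || any(!is.finite(durations)) || any(durations <= 0)) {
    abort_invalid("`durations` must be a non-empty vector of positive finite minutes.")
  }
  end <- cumsum(durations)
  start <- c(0, end[-length(end)])
  tibble::tibble(
    frame = seq_along(durations),
    start = start,
    end = end,
    mid = (start + end) / 2,
    dur = durations
  )
}

# Validate that a data frame is a usable schedule (or TAC carrying schedule
# columns): contiguous, non-overlapping, first start at 0.
validate_schedule <- function(schedule) {
  need <- c("start", "end")
  if (!is.data.frame(schedule) || !all(need %in% names(schedule)) || nrow(schedule) == 0L) {
    abort_invalid("A frame schedule must be a data frame with `start` and `end` columns.")
  }
  if (schedule$start[1] != 0) abort_invalid("The first frame must start at 0.")
  if (any(schedule$end <= schedule$start)) abort_invalid("Each frame must have start < end.")
  n <- nrow(schedule)
  if (n > 1 && any(abs(schedule$start[-1] - schedule$end[-n]) > 1e-9)) {
    abort_invalid("Frames must be contiguous and non-overlapping.")
  }
  invisible(schedule)
}

#' Construct a time-activity curve on a schedule
#'
#' @param schedule A frame schedule from [frame_schedule()].
#' @param activity Per-frame mean activity (kBq/mL), one value per frame.
#' @param region Optional region label.
#' @return A tibble with the schedule columns plus `activity` (and `region`
#'   if supplied).
#' @export
new_tac <- function(schedule, activity, region = NULL) {
  validate_schedule(schedule)
  if (length(activity) != nrow(schedule)) {
    abort_invalid("`activity` must have one value per frame.")
  }
  if (any(!is.finite(activity))) abort_invalid("`activity` values must be finite.")
  out <- tibble::as_tibble(schedule)
  out$activity <- as.numeric(activity)
  if (!is.null(region)) out$region <- region
  out
}

#' Default decay-duration frame weights
#'
#' Weights proportional to frame duration times the physical decay factor at
#' the frame midpoint, the standard weighting for decay-corrected PET frames.
#'
#' @param schedule A frame schedule.
#' @return Numeric vector of weights, one per frame.
#' @export
frame_weights <- function(schedule) {
  validate_schedule(schedule)
  schedule$dur * exp(-lambda_c11 * schedule$mid)
}
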