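# Windowed SUVR outcomes: the simplified measure under validation.

#' Standard SUVR scan windows
#'
#' The nine 20- and 30-minute windows spanning 30 to 90 minutes used for
#' window-wise SUVR validation: 30-60, 40-70, 50-80, 60-90, 30-50, 40-60,
#' 50-70, 60-80, 70-90 min (30-minute windows first, then 20-minute
#' windows, each in chronological order).
#'
#' @return A tibble with columns `label`, `start`, `end`.
#' @export
standard_windows <- function() {
  tibble::tibble(
    label = c("30-60", "40-70", "50-80", "60-90",
              "30-50", "40-60", "50-70", "60-80", "70-90"),
    start = c(30, 40, 50, 60, 30, 40, 50, 60, 70),
    end   = c(60, 70, 80, 90, 50, 60, 70, 80, 90)
  )
}

#' Construct a scan window
#'
#' @param start,end Window bounds in minutes, 0 <= start < end.
#' @param label Optional label; default `"start-end"`.
#' @return A one-row tibble like [standard_windows()].
#' @export
scan_window <- function(start, end, label = NULL) {
  check_number(start, "start"); check_number(end, "end")
  if (start < 0 || end <= start) abort_invalid("Need 0 <= start < end.")
  tibble::tibble(label = label %||% sprintf("%g-%g", start, end),
                 start = start, end = end)
}

# Per-frame overlap durations with a window; warns on partial frames.
window_overlap <- function(schedule, start, end) {
  if (end > max(schedule$end) + 1e-9 || start < min(schedule$start) - 1e-9) {
    abort_invalid("Scan window must lie within the frame schedule.")
  }
  ov <- pmax(0, pmin(schedule$end, end) - pmax(schedule$start, start))
  partial <- ov > 1e-9 & ov < schedule$dur - 1e-9
  if (any(partial)) {
    warning("Scan window does not align with frame boundaries; partial frames prorated.",
            call. = FALSE)
  }
  ov
}

#' Windowed standardized uptake value ratio
#'
#' SUVR = (duration-weighted mean target activity over the window) /
#' (duration-weighted mean reference activity over the window). Summing
#' frames and ratioing is equivalent up to a constant that cancels; the
#' duration-weighted mean is robust to unequal frame lengths. Windows that
#' cut through a frame are prorated with a warning.
#'
#' @param target,ref Target and reference TAC tibbles on a shared schedule.
#' @param window A window: `c(start, end)` or a one-row tibble from
#'   [scan_window()] / [standard_windows()].
#' @return A one-row tibble: `window`, `suvr`, plus `region` if the target
#'   carries one.
#' @export
compute_suvr <- function(target, ref, window) {
  validate_schedule(target); validate_schedule(ref)
  if (nrow(target) != nrow(ref) || any(abs(target$mid - ref$mid) > 1e-9)) {
    abort_invalid("Target and reference TACs must share a frame schedule.")
  }
  if (is.data.frame(window)) {
    lab <- window$label[1]; w <- c(window$start[1], window$end[1])
  } else {
    if (length(window) != 2L) abort_invalid("`window` must be c(start, end) or a window tibble.")
    w <- as.numeric(window); lab <- sprintf("%g-%g", w[1], w[2])
  }
  if (w[1] < 0 || w[2] <= w[1]) abort_invalid("Need 0 <= start < end.")
  ov <- window_overlap(target, w[1], w[2])
  mt <- sum(ov * target$activity) / sum(ov)
  mr <- sum(ov * ref$activity) / sum(ov)
  if (!is.finite(mr) || mr <= 0) abort_invalid("Reference mean activity over the window must be > 0.")
  out <- tibble::tibble(window = lab, suvr = mt / mr)
  if ("region" %in% names(target)) out <- dplyr::mutate(out, region = target$region[1], .before = 1)
  out
}

#' Instantaneous target-to-reference ratio
#'
#' Pointwise \eqn{C_T(t)/C_R(t)}; at constant-infusion equilibrium this
#' ratio equals DVR. Times where the reference is zero yield `NA`.
#'
#' @param target,ref TAC tibbles on a shared schedule, or functions of time.
#' @param times Evaluation times; default the frame midpoints.
#' @return A tibble with `time` and `ratio`.
#' @export
instantaneous_ratio <- function(target, ref, times = NULL) {
  if (is.function(target) || is.function(ref)) {
    if (!is.function(target) || !is.function(ref)) {
      abort_invalid("Supply both curves as functions or both as TACs.")
    }
    if (is.null(times)) abort_invalid("`times` is required for function inputs.")
    ct <- target(times); cr <- ref(times)
  } else {
    validate_schedule(target); validate_schedule(ref)
    if (is.null(times)) times <- target$mid
    ft <- stats::approxfun(c(0, target$mid), c(0, target$activity), rule = 2)
    fr <- stats::approxfun(c(0, ref$mid), c(0, ref$activity), rule = 2)
    ct <- ft(times); cr <- fr(times)
  }
  ratio <- ifelse(abs(cr) > 0, ct / cr, NA_real_)
  tibble::tibble(time = times, ratio = ratio)
}

#' Window-wise SUVR for every subject and region of a cohort
#'
#' Computes SUVR against the cohort's reference region (whole cerebellum)
#' for each subject, target region and scan window; the reference region
#' itself (SUVR identically 1) is omitted.
#'
#' @param cohort A `pet_cohort` from [generate_cohort()].
#' @param windows A window tibble; default [standard_windows()].
#' @param reference Reference region name; default the cohort's.
#' @return A tibble: `subject`, `group`, `region`, `window`, `suvr`.
#' @export
cohort_suvr <- function(cohort, windows = standard_windows(), reference = NULL) {
  stopifnot(inherits(cohort, "pet_cohort"))
  reference <- reference %||% cohort$reference
  sched <- cohort$schedule
  tacs <- cohort$tacs
  if (!reference %in% tacs$region) abort_invalid(paste0("Reference region '", reference, "' not in cohort."))
  sched_key <- dplyr::select(sched, "frame", "start", "end", "dur")
  tl <- dplyr::left_join(tacs, sched_key, by = "frame")
  per_window <- purrr::pmap_dfr(windows, function(label, start, end) {
    ov <- window_overlap(sched, start, end)
    ovt <- tibble::tibble(frame = sched$frame, ov = ov)
    dplyr::left_join(tl, ovt, by = "frame") |>
      dplyr::group_by(.data$subject, .data$group, .data$region) |>
      dplyr::summarise(mean_act = sum(.data$ov * .data$activity) / sum(.data$ov),
                       .groups = "drop") |>
      dplyr::mutate(window = label)
  })
  refs <- per_window |>
    dplyr::filter(.data$region == reference) |>
    dplyr::select("subject", "window", ref_act = "mean_act")
  if (any(refs$ref_act <= 0)) abort_invalid("Reference mean activity must be > 0 in every window.")
  per_window |>
    dplyr::filter(.data$region != reference) |>
    dplyr::left_join(refs, by = c("subject", "window")) |>
    dplyr::mutate(suvr = .data$mean_act / .data$ref_act) |>
    dplyr::select("subject", "group", "region", "window", "suvr") |>
    dplyr::arrange(factor(.data$window, levels = windows$label), .data$subject, .data$region)
}
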