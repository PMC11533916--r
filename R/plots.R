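# ggplot2 displays for the main result types.

#' Plot time-activity curves
#'
#' @param tacs A long TAC tibble with `mid`, `activity` and grouping columns
#'   (`region`, optionally `subject`), e.g. a `pet_cohort$tacs`.
#' @param colour Column to colour by; default `region`.
#' @return A ggplot.
#' @export
plot_tac <- function(tacs, colour = "region") {
  ggplot2::ggplot(tacs, ggplot2::aes(x = .data$mid, y = .data$activity,
                                     colour = .data[[colour]],
                                     group = interaction(.data[[colour]],
                                                         if ("subject" %in% names(tacs)) .data$subject else 1))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Time (min)", y = "Activity (kBq/mL)", colour = colour) +
    ggplot2::theme_minimal()
}

#' Scatter of SUVR against DVR with fitted and identity lines
#'
#' @param pairs Tibble with `dvr`, `suvr`, `group` and optionally `window`
#'   (facetted when present).
#' @return A ggplot.
#' @export
plot_suvr_dvr <- function(pairs) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$dvr, y = .data$suvr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.5) +
    ggplot2::labs(x = "DVR (SRTM2)", y = "SUVR", colour = NULL) +
    ggplot2::theme_minimal()
  if ("window" %in% names(pairs)) p <- p + ggplot2::facet_wrap(~window)
  p
}

#' Perfusion-simulation timecourses
#'
#' Two-panel display of the simulation result: group percentage difference
#' in SUVR versus scan time for each K1 scenario, with the true DVR
#' percentage difference as a reference line, and Cohen's d versus time.
#'
#' @param x A `perfusion_sim` object.
#' @param which `"pct_diff"`, `"cohen_d"` or `"both"`.
#' @return A ggplot (patchwork-free: facetted when `"both"`).
#' @export
plot_perfusion_sim <- function(x, which = c("both", "pct_diff", "cohen_d")) {
  which <- match.arg(which)
  tc <- x$timecourse |>
    dplyr::mutate(scenario = factor(paste0(.data$scenario_pct, "% K1")))
  long <- tc |>
    tidyr::pivot_longer(c("pct_diff", "cohen_d"), names_to = "panel", values_to = "value") |>
    dplyr::mutate(panel = dplyr::recode(.data$panel,
                                        pct_diff = "SUVR group difference (%)",
                                        cohen_d = "Cohen's d"))
  if (which == "pct_diff") long <- dplyr::filter(long, .data$panel != "Cohen's d")
  if (which == "cohen_d") long <- dplyr::filter(long, .data$panel == "Cohen's d")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value,
                                          colour = .data$scenario)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Scan time (min)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
  if (which != "cohen_d") {
    ref <- data.frame(panel = "SUVR group difference (%)",
                      yint = tc$dvr_pct_diff[1])
    p <- p + ggplot2::geom_hline(data = ref,
                                 ggplot2::aes(yintercept = .data$yint),
                                 linetype = "dotted", colour = "grey30")
  }
  if (which == "both") p <- p + ggplot2::facet_wrap(~panel, scales = "free_y")
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.perfusion_sim <- function(object, ...) plot_perfusion_sim(object, ...)

#' Effect sizes by scan window
#'
#' Mean Cohen's d across regions per SUVR scan window, with the DVR effect
#' size as a reference line.
#'
#' @param x An `effect_size_table`.
#' @return A ggplot.
#' @export
plot_effect_sizes <- function(x) {
  s <- x$summary
  dvr_d <- s$mean_d[s$outcome == "DVR"]
  sw <- dplyr::filter(s, .data$outcome != "DVR") |>
    dplyr::mutate(outcome = factor(.data$outcome, levels = .data$outcome))
  ggplot2::ggplot(sw, ggplot2::aes(x = .data$outcome, y = .data$mean_d)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_d - .data$sd_d,
                                        ymax = .data$mean_d + .data$sd_d), width = 0.2) +
    ggplot2::geom_hline(yintercept = dvr_d, linetype = "dashed") +
    ggplot2::labs(x = "SUVR scan window (min)", y = "Mean Cohen's d across regions") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.effect_size_table <- function(object, ...) plot_effect_sizes(object)
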