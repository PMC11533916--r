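# Group-comparison and validation statistics: Cohen's d, SUVR-vs-DVR
# regression, identity-line bias, and the window-wise effect-size table.

#' Cohen's d with pooled standard deviation
#'
#' \deqn{d = (\bar a - \bar b) / s_p,\quad
#'   s_p = \sqrt{((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)}.}
#' The classic (uncorrected) form; group order fixes the sign, and the
#' package convention is CN minus AD, so reductions in AD give positive d.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return The standardized mean difference.
#' @examples
#' cohen_d(c(1, 2, 3), c(3, 4, 5))  # -2
#' @export
cohen_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) abort_invalid("Each group needs at least 2 observations.")
  if (anyNA(group_a) || anyNA(group_b)) abort_invalid("Groups must not contain missing values.")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) / (na + nb - 2)
  if (sp2 <= 0) abort_undefined("Pooled standard deviation is zero; Cohen's d is undefined.")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Regress SUVR on DVR
#'
#' Ordinary least squares of SUVR against DVR over subject-region pairs,
#' for all participants and within each diagnostic group, reporting slope,
#' intercept, Pearson r and its two-tailed p (t transform on n - 2 df).
#'
#' @param pairs Tibble with columns `dvr`, `suvr` and (for group strata)
#'   `group`; typically one row per subject-region pair.
#' @param strata Which strata to fit; any of `"all"`, `"CN"`, `"AD"`.
#' @return A tibble of class `suvr_dvr_regression`: `stratum`, `slope`,
#'   `intercept`, `r`, `p`, `n`.
#' @export
regress_suvr_on_dvr <- function(pairs, strata = c("all", "CN", "AD")) {
  if (!all(c("dvr", "suvr") %in% names(pairs))) {
    abort_invalid("`pairs` must have `dvr` and `suvr` columns.")
  }
  strata <- match.arg(strata, several.ok = TRUE)
  rows <- purrr::map_dfr(strata, function(s) {
    d <- if (s == "all") pairs else dplyr::filter(pairs, .data$group == s)
    n <- nrow(d)
    if (n < 3) abort_invalid(paste0("Stratum '", s, "' has fewer than 3 pairs."))
    if (stats::var(d$dvr) <= 0) abort_undefined("Predictor (DVR) variance is zero.")
    fit <- stats::lm(suvr ~ dvr, data = d)
    r <- stats::cor(d$dvr, d$suvr)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    tibble::tibble(stratum = s,
                   slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r = r, p = p, n = n)
  })
  class(rows) <- c("suvr_dvr_regression", class(rows))
  rows
}

#' Deviation of a fitted regression line from the identity line
#'
#' Summarises bias of the SUVR-DVR relationship as slope minus 1, the
#' intercept, and the mean signed deviation of the fitted line from y = x
#' over an evaluation range (for a line this is
#' `(slope - 1) * mean(range) + intercept`).
#'
#' @param reg A `suvr_dvr_regression` row (or tibble; one output row each).
#' @param range Evaluation range on the DVR axis, `c(lo, hi)`.
#' @return Tibble: `stratum`, `slope_minus_1`, `intercept`, `mean_deviation`.
#' @export
identity_bias <- function(reg, range = c(0.5, 1.5)) {
  if (!all(c("slope", "intercept") %in% names(reg))) {
    abort_invalid("`reg` must carry `slope` and `intercept`.")
  }
  if (length(range) != 2L || range[2] <= range[1]) abort_invalid("`range` must be c(lo, hi).")
  tibble::tibble(
    stratum = if ("stratum" %in% names(reg)) reg$stratum else NA_character_,
    slope_minus_1 = reg$slope - 1,
    intercept = reg$intercept,
    mean_deviation = (reg$slope - 1) * mean(range) + reg$intercept
  )
}

#' Window-wise effect sizes and their correlation with DVR effect sizes
#'
#' For every scan window, Cohen's d (CN minus AD) is computed per region
#' from the SUVR outcomes, and likewise per region from the DVR outcomes;
#' each window row then reports the Pearson correlation (and two-tailed p)
#' of its region-wise d values against the DVR d values, plus the mean and
#' SD of d across regions. Rows appear in standard-window order with the
#' DVR row last.
#'
#' @param suvr_outcomes Tibble: `subject`, `group`, `region`, `window`,
#'   `suvr` (as from [cohort_suvr()]).
#' @param dvr_outcomes Tibble: `subject`, `group`, `region`, `dvr` (as from
#'   [true_dvr()] or [fit_cohort_dvr()]).
#' @param windows Window tibble fixing row order; default the windows
#'   present in `suvr_outcomes` in [standard_windows()] order.
#' @return An object of class `effect_size_table`: `$summary` (outcome, r,
#'   p, mean_d, sd_d) and `$by_region` (outcome, region, d, per-group
#'   means, SDs and n).
#' @export
effect_size_table <- function(suvr_outcomes, dvr_outcomes, windows = NULL) {
  need <- c("subject", "group", "region", "window", "suvr")
  if (!all(need %in% names(suvr_outcomes))) {
    abort_invalid(paste("`suvr_outcomes` must have columns:", paste(need, collapse = ", ")))
  }
  if (!all(c("subject", "group", "region", "dvr") %in% names(dvr_outcomes))) {
    abort_invalid("`dvr_outcomes` must have subject, group, region, dvr.")
  }
  suvr_regions <- sort(unique(suvr_outcomes$region))
  dvr_regions <- sort(unique(dvr_outcomes$region))
  if (!identical(suvr_regions, dvr_regions)) {
    missing <- c(setdiff(suvr_regions, dvr_regions), setdiff(dvr_regions, suvr_regions))
    abort_invalid(paste0("Region sets differ between SUVR and DVR outcomes; mismatched: ",
                         paste(missing, collapse = ", ")))
  }
  win_labels <- if (is.null(windows)) {
    intersect(standard_windows()$label, unique(suvr_outcomes$window))
  } else windows$label
  d_of <- function(df, value_col) {
    df |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(
        d = cohen_d(.data[[value_col]][.data$group == "CN"],
                    .data[[value_col]][.data$group == "AD"]),
        mean_cn = mean(.data[[value_col]][.data$group == "CN"]),
        mean_ad = mean(.data[[value_col]][.data$group == "AD"]),
        sd_cn = stats::sd(.data[[value_col]][.data$group == "CN"]),
        sd_ad = stats::sd(.data[[value_col]][.data$group == "AD"]),
        n_cn = sum(.data$group == "CN"), n_ad = sum(.data$group == "AD"),
        .groups = "drop"
      )
  }
  dvr_d <- d_of(dvr_outcomes, "dvr") |> dplyr::mutate(outcome = "DVR", .before = 1)
  by_region <- purrr::map_dfr(win_labels, function(w) {
    d_of(dplyr::filter(suvr_outcomes, .data$window == w), "suvr") |>
      dplyr::mutate(outcome = w, .before = 1)
  }) |> dplyr::bind_rows(dvr_d)
  dvr_ref <- dvr_d |> dplyr::select("region", d_dvr = "d")
  summary <- purrr::map_dfr(c(win_labels, "DVR"), function(w) {
    dd <- by_region |> dplyr::filter(.data$outcome == w) |> dplyr::left_join(dvr_ref, by = "region")
    if (w == "DVR") {
      r <- NA_real_; p <- NA_real_
    } else {
      n <- nrow(dd)
      r <- stats::cor(dd$d, dd$d_dvr)
      if (is.na(r) || abs(r) >= 1 - 1e-12 || n < 3) {
        p <- if (is.na(r) || n < 3) NA_real_ else 0
      } else {
        tt <- r * sqrt((n - 2) / (1 - r^2))
        p <- 2 * stats::pt(-abs(tt), df = n - 2)
      }
    }
    tibble::tibble(outcome = w, r = r, p = p,
                   mean_d = mean(dd$d), sd_d = stats::sd(dd$d))
  })
  structure(list(summary = summary, by_region = by_region),
            class = "effect_size_table")
}

#' @export
print.effect_size_table <- function(x, ...) {
  cat("Effect sizes (Cohen's d, CN - AD) by outcome:\n")
  print(x$summary)
  invisible(x)
}

#' @rdname effect_size_table
#' @param x An `effect_size_table`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.effect_size_table <- function(x, ...) x$by_region

#' @rdname effect_size_table
#' @exportS3Method generics::glance
glance.effect_size_table <- function(x, ...) x$summary
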