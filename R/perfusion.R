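# Perfusion-confound simulation: perturb AD hippocampal delivery (K1)
# relative to the CN mean while holding each subject's VT (hence DVR)
# fixed, then trace the SUVR group percentage difference and Cohen's d
# across scan time.

#' Rescale AD delivery to a target group difference
#'
#' Multiplicatively rescales each AD subject's K1 so that the AD group mean
#' equals `cn_mean_k1 * (1 - pct_diff/100)`, preserving every subject's
#' relative deviation from the group mean. By default k2 is co-scaled by
#' the same factor so each subject's VT = K1/k2 — and therefore DVR — is
#' untouched, isolating the perfusion confound from binding differences.
#' With `preserve_vt = FALSE` k2 is left fixed and VT drifts with K1.
#'
#' @param ad_params Tibble of AD parameters with columns `k1`, `k2` (and
#'   any others, carried through).
#' @param cn_mean_k1 Mean K1 of the CN group (> 0).
#' @param pct_diff Target percentage difference, 0 <= pct_diff < 100.
#' @param preserve_vt Co-scale k2 to hold VT fixed (default TRUE).
#' @return `ad_params` with rescaled `k1` (and `k2`, `vt` updated).
#' @export
scale_k1 <- function(ad_params, cn_mean_k1, pct_diff, preserve_vt = TRUE) {
  check_number(cn_mean_k1, "cn_mean_k1", positive = TRUE)
  check_number(pct_diff, "pct_diff")
  if (pct_diff < 0) abort_invalid("`pct_diff` must be >= 0.")
  if (pct_diff >= 100) abort_invalid("`pct_diff` must be < 100.")
  if (!all(c("k1", "k2") %in% names(ad_params))) {
    abort_invalid("`ad_params` must have `k1` and `k2` columns.")
  }
  f <- cn_mean_k1 * (1 - pct_diff / 100) / mean(ad_params$k1)
  out <- dplyr::mutate(ad_params, k1 = .data$k1 * f)
  if (preserve_vt) out <- dplyr::mutate(out, k2 = .data$k2 * f)
  dplyr::mutate(out, vt = .data$k1 / .data$k2)
}

#' Group percentage difference in relative delivery (R1)
#'
#' R1 per subject is hippocampal K1 over cerebellar K1; the group
#' difference is `100 * (mean R1_CN - mean R1_AD) / mean R1_CN` (positive =
#' reduction in AD).
#'
#' @param params Parameter tibble with `subject`, `group`, `region`, `k1`
#'   including both `target` and `reference` regions for every subject.
#' @param target,reference Region names.
#' @return Percentage difference (scalar).
#' @export
group_r1_difference <- function(params, target = "hippocampus",
                                reference = "whole cerebellum") {
  wide <- params |>
    dplyr::filter(.data$region %in% c(target, reference)) |>
    dplyr::select("subject", "group", "region", "k1") |>
    tidyr::pivot_wider(names_from = "region", values_from = "k1")
  if (!all(c(target, reference) %in% names(wide)) || anyNA(wide[[reference]]) || anyNA(wide[[target]])) {
    abort_invalid("Every subject needs K1 for both the target and the reference region.")
  }
  r1 <- wide[[target]] / wide[[reference]]
  m_cn <- mean(r1[wide$group == "CN"])
  m_ad <- mean(r1[wide$group == "AD"])
  100 * (m_cn - m_ad) / m_cn
}

pct_diff_groups <- function(x, group) {
  m_cn <- mean(x[group == "CN"]); m_ad <- mean(x[group == "AD"])
  100 * (m_cn - m_ad) / m_cn
}

#' Run the perfusion-confound simulation
#'
#' For each K1 percentage-difference scenario (default 0/10/20/30/40%),
#' AD hippocampal K1 is rescaled toward the stated deficit relative to the
#' CN mean with VT preserved, TACs are simulated for hippocampus and the
#' reference region from the shared plasma input (noiseless by default:
#' group differences come from the parameter spread), and at each time
#' point the instantaneous target-to-reference ratio gives the group mean
#' SUVR, their percentage difference and Cohen's d. Windowed SUVRs over
#' the standard scan windows are emitted alongside. The true DVR
#' percentage difference (from VT ratios, identical across scenarios by
#' construction) and the scenario's realised R1 percentage difference are
#' attached to every row.
#'
#' @param cohort A `pet_cohort` with hippocampus and reference parameters.
#' @param scenarios K1 percentage differences to apply.
#' @param target Target region; default `"hippocampus"`.
#' @param times Evaluation time points (min); default the midpoints of the
#'   16 late 5-minute frames.
#' @param windows Scan windows for the windowed variant.
#' @param noise_scale Optional TAC noise (applied to windowed SUVR inputs).
#' @param seed Seed for the noise stream (unused when `noise_scale = 0`,
#'   but fixed so runs are reproducible either way).
#' @return An object of class `perfusion_sim`: `$timecourse` (scenario_pct,
#'   time_min, mean_suvr_cn, mean_suvr_ad, pct_diff, cohen_d, dvr_pct_diff,
#'   r1_pct_diff) and `$windowed` (same per scan window).
#' @export
run_perfusion_simulation <- function(cohort, scenarios = c(0, 10, 20, 30, 40),
                                     target = "hippocampus", times = NULL,
                                     windows = standard_windows(),
                                     noise_scale = 0, seed = 1L) {
  stopifnot(inherits(cohort, "pet_cohort"))
  reference <- cohort$reference
  params <- cohort$params
  if (!all(c(target, reference) %in% params$region)) {
    abort_invalid("Cohort must carry parameters for the target and reference regions.")
  }
  sched <- cohort$schedule
  if (is.null(times)) {
    late <- sched$dur == max(sched$dur)
    times <- sched$mid[late]
  }
  pre_bolus <- times <= cohort$plasma$delay
  if (any(pre_bolus)) {
    message("Dropping ", sum(pre_bolus), " time point(s) at or before the bolus delay.")
    times <- times[!pre_bolus]
  }
  if (length(times) == 0L) abort_invalid("No evaluation times after the bolus delay.")
  cn_mean_k1 <- params |>
    dplyr::filter(.data$group == "CN", .data$region == target) |>
    dplyr::pull("k1") |> mean()

  eval_curves <- function(p) {
    t(vapply(seq_len(nrow(p)),
             function(i) simulate_1tc(one_tissue_params(p$k1[i], p$k2[i]), cohort$plasma, times),
             numeric(length(times))))
  }

  base_t <- dplyr::filter(params, .data$region == target)
  base_r <- dplyr::filter(params, .data$region == reference)
  base_r <- base_r[match(base_t$subject, base_r$subject), ]
  ref_curves <- eval_curves(base_r)
  ref_tacs <- simulate_cohort_tacs(base_r, sched, cohort$plasma, noise_scale, seed)
  is_ad <- base_t$group == "AD"

  seeds <- derive_seeds(seed + 1L, length(scenarios))
  res_tc <- list(); res_win <- list()
  for (si in seq_along(scenarios)) {
    pct <- scenarios[si]
    p_t <- base_t
    p_t[is_ad, c("k1", "k2", "vt")] <-
      scale_k1(p_t[is_ad, ], cn_mean_k1, pct)[, c("k1", "k2", "vt")]

    dvr <- p_t$vt / base_r$vt
    dvr_pct <- pct_diff_groups(dvr, p_t$group)
    scen_params <- dplyr::bind_rows(p_t, base_r)
    r1_pct <- group_r1_difference(scen_params, target = target, reference = reference)

    tgt_curves <- eval_curves(p_t)
    ratios <- tgt_curves / ref_curves
    tc <- purrr::map_dfr(seq_along(times), function(j) {
      x <- ratios[, j]
      tibble::tibble(
        scenario_pct = pct, time_min = times[j],
        mean_suvr_cn = mean(x[!is_ad]), mean_suvr_ad = mean(x[is_ad]),
        pct_diff = pct_diff_groups(x, p_t$group),
        cohen_d = cohen_d(x[!is_ad], x[is_ad]),
        dvr_pct_diff = dvr_pct, r1_pct_diff = r1_pct
      )
    })
    res_tc[[si]] <- tc

    tgt_tacs <- simulate_cohort_tacs(p_t, sched, cohort$plasma, noise_scale, seeds[si])
    win <- purrr::pmap_dfr(windows, function(label, start, end) {
      ov <- window_overlap(sched, start, end)
      mean_act <- function(tl) {
        tl |>
          dplyr::left_join(tibble::tibble(frame = sched$frame, ov = ov), by = "frame") |>
          dplyr::group_by(.data$subject, .data$group) |>
          dplyr::summarise(m = sum(.data$ov * .data$activity) / sum(.data$ov), .groups = "drop")
      }
      mt <- mean_act(tgt_tacs); mr <- mean_act(ref_tacs)
      s <- dplyr::left_join(mt, dplyr::select(mr, "subject", mref = "m"), by = "subject") |>
        dplyr::mutate(suvr = .data$m / .data$mref)
      tibble::tibble(
        scenario_pct = pct, window = label,
        mean_suvr_cn = mean(s$suvr[s$group == "CN"]),
        mean_suvr_ad = mean(s$suvr[s$group == "AD"]),
        pct_diff = pct_diff_groups(s$suvr, s$group),
        cohen_d = cohen_d(s$suvr[s$group == "CN"], s$suvr[s$group == "AD"]),
        dvr_pct_diff = dvr_pct, r1_pct_diff = r1_pct
      )
    })
    res_win[[si]] <- win
  }
  structure(list(
    timecourse = dplyr::bind_rows(res_tc),
    windowed = dplyr::bind_rows(res_win),
    scenarios = scenarios, target = target, reference = reference,
    times = times, seed = as.integer(seed)
  ), class = "perfusion_sim")
}

#' @export
print.perfusion_sim <- function(x, ...) {
  cat(sprintf("Perfusion-confound simulation: scenarios %s%% K1 difference, %d time points (%s vs %s)\n",
              paste(x$scenarios, collapse = "/"), length(x$times), x$target, x$reference))
  print(utils::head(x$timecourse))
  invisible(x)
}

#' @rdname run_perfusion_simulation
#' @param x A `perfusion_sim` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.perfusion_sim <- function(x, ...) x$timecourse
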