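# Synthetic two-group cohort generator: per-subject one-tissue kinetic
# parameters for a set of cortical/limbic regions plus a whole-cerebellum
# reference, and frame-averaged TACs simulated from them.

default_region_table <- function() {
  tibble::tribble(
    ~region,                          ~k1_cn, ~vt_cn, ~vt_reduction, ~k1_reduction,
    "hippocampus",                     0.25,   12.0,   0.10,          0.15,
    "entorhinal cortex",               0.22,   11.0,   0.12,          0.16,
    "lateral temporal cortex",         0.30,   16.0,   0.08,          0.12,
    "prefrontal cortex",               0.30,   16.0,   0.06,          0.10,
    "posterior cingulate/precuneus",   0.33,   17.0,   0.08,          0.12,
    "lateral parietal cortex",         0.31,   16.0,   0.07,          0.11,
    "lateral occipital cortex",        0.31,   15.5,   0.05,          0.09,
    "medial occipital cortex",         0.33,   16.0,   0.04,          0.08,
    "whole cerebellum",                0.30,   14.0,   0.01,          0.03
  )
}

#' Cohort generator configuration
#'
#' Defines the statistical structure of a synthetic two-group study: group
#' sizes, per-region cognitively-normal (CN) means for delivery (K1) and
#' volume of distribution (VT), fractional reductions of both in the AD
#' group, and the between-subject spread. Kinetic means are invented,
#' literature-plausible values for an SV2A tracer (they are configuration,
#' not measured data); AD perfusion reductions default to being larger than
#' the density (VT) reductions in every region. Between-subject variation
#' is lognormal and split into a subject-global factor (shared by all
#' regions, so regional parameters correlate within subject) and a
#' region-specific residual.
#'
#' @param n_cn,n_ad Group sizes (default 16 CN, 31 AD).
#' @param regions Region table with columns `region`, `k1_cn`, `vt_cn`,
#'   `vt_reduction`, `k1_reduction`; reductions are fractions in [0, 1).
#' @param reference Name of the reference region; must appear in `regions`.
#' @param cv_global Coefficient of variation of the subject-global lognormal
#'   factor (applied separately to K1 and VT).
#' @param cv_region CV of the region-specific lognormal residual.
#' @param noise_scale TAC noise scale passed to [add_tac_noise()]; 0 for
#'   noiseless curves.
#' @param schedule Frame schedule; default the 27-frame 90-min schedule.
#' @param plasma Shared plasma input; default [plasma_input()].
#' @param seed Master seed used by [generate_cohort()] when none is given.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cn = 16, n_ad = 31,
                          regions = default_region_table(),
                          reference = "whole cerebellum",
                          cv_global = 0.15, cv_region = 0.08,
                          noise_scale = 0,
                          schedule = frame_schedule(),
                          plasma = plasma_input(),
                          seed = 1L) {
  problems <- character()
  if (!is.numeric(n_cn) || n_cn < 2) problems <- c(problems, "`n_cn` must be >= 2.")
  if (!is.numeric(n_ad) || n_ad < 2) problems <- c(problems, "`n_ad` must be >= 2.")
  need <- c("region", "k1_cn", "vt_cn", "vt_reduction", "k1_reduction")
  if (!is.data.frame(regions) || !all(need %in% names(regions))) {
    problems <- c(problems, paste("`regions` must have columns:", paste(need, collapse = ", ")))
  } else {
    if (any(regions$k1_cn <= 0) || any(regions$vt_cn <= 0)) {
      problems <- c(problems, "Region K1/VT means must be > 0.")
    }
    if (any(regions$vt_reduction < 0 | regions$vt_reduction >= 1) ||
        any(regions$k1_reduction < 0 | regions$k1_reduction >= 1)) {
      problems <- c(problems, "Reductions must lie in [0, 1).")
    }
    if (!reference %in% regions$region) {
      problems <- c(problems, paste0("Reference region '", reference, "' missing from `regions`."))
    }
  }
  if (!is.numeric(cv_global) || cv_global < 0) problems <- c(problems, "`cv_global` must be >= 0.")
  if (!is.numeric(cv_region) || cv_region < 0) problems <- c(problems, "`cv_region` must be >= 0.")
  if (!is.numeric(noise_scale) || noise_scale < 0) problems <- c(problems, "`noise_scale` must be >= 0.")
  if (length(problems)) {
    abort_invalid(paste(c("Invalid cohort configuration:", problems), collapse = "\n- "))
  }
  validate_schedule(schedule)
  stopifnot(inherits(plasma, "plasma_input"))
  structure(list(
    n_cn = as.integer(n_cn), n_ad = as.integer(n_ad),
    regions = tibble::as_tibble(regions), reference = reference,
    cv_global = cv_global, cv_region = cv_region, noise_scale = noise_scale,
    schedule = tibble::as_tibble(schedule), plasma = plasma, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Cohort configuration: %d CN + %d AD subjects, %d regions (reference: %s)\n",
              x$n_cn, x$n_ad, nrow(x$regions), x$reference))
  cat(sprintf("  CV global %.2f, CV region %.2f, noise scale %.3g, seed %d\n",
              x$cv_global, x$cv_region, x$noise_scale, x$seed))
  invisible(x)
}

# sdlog giving a lognormal with mean 1 and the requested CV.
lnorm_sdlog <- function(cv) sqrt(log(1 + cv^2))
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- lnorm_sdlog(cv)
  exp(stats::rnorm(n, mean = -s^2 / 2, sd = s))
}

#' Draw per-subject kinetic parameters for a cohort
#'
#' For each subject a global K1 factor and a global VT factor are drawn
#' (lognormal, mean 1, CV `cv_global`), then per-region residuals (CV
#' `cv_region`); region parameters are the group mean times both factors.
#' AD group means are the CN means scaled by `1 - reduction`. k2 is derived
#' as K1/VT.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; default the config's.
#' @return A tibble: `subject`, `group`, `region`, `k1`, `k2`, `vt`.
#' @export
draw_cohort_params <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  nr <- nrow(config$regions)
  subj <- tibble::tibble(
    subject = c(sprintf("cn%02d", seq_len(config$n_cn)),
                sprintf("ad%02d", seq_len(config$n_ad))),
    group = c(rep("CN", config$n_cn), rep("AD", config$n_ad))
  )
  with_local_seed(seed, {
    purrr::pmap_dfr(subj, function(subject, group) {
      gk1 <- rlnorm_mean1(1, config$cv_global)
      gvt <- rlnorm_mean1(1, config$cv_global)
      ek1 <- rlnorm_mean1(nr, config$cv_region)
      evt <- rlnorm_mean1(nr, config$cv_region)
      red_k1 <- if (group == "AD") 1 - config$regions$k1_reduction else rep(1, nr)
      red_vt <- if (group == "AD") 1 - config$regions$vt_reduction else rep(1, nr)
      k1 <- config$regions$k1_cn * red_k1 * gk1 * ek1
      vt <- config$regions$vt_cn * red_vt * gvt * evt
      tibble::tibble(subject = subject, group = group,
                     region = config$regions$region,
                     k1 = k1, k2 = k1 / vt, vt = vt)
    })
  })
}

#' Simulate frame-averaged TACs for a parameter table
#'
#' Each subject-region curve is the closed-form one-tissue solution for the
#' shared plasma input, averaged over the frame schedule; optional noise is
#' added per curve with sub-seeds derived deterministically from `seed`.
#'
#' @param params Parameter tibble as from [draw_cohort_params()].
#' @param schedule Frame schedule.
#' @param plasma Shared [plasma_input()].
#' @param noise_scale Noise scale for [add_tac_noise()] (0 = noiseless).
#' @param seed Integer seed for the noise stream.
#' @return A tibble: `subject`, `group`, `region`, `frame`, `mid`, `activity`.
#' @export
simulate_cohort_tacs <- function(params, schedule, plasma, noise_scale = 0, seed = 1L) {
  validate_schedule(schedule)
  need <- c("subject", "group", "region", "k1", "k2")
  if (!all(need %in% names(params))) {
    abort_invalid(paste("`params` must have columns:", paste(need, collapse = ", ")))
  }
  rows <- dplyr::distinct(params, .data$subject, .data$group, .data$region,
                          .data$k1, .data$k2)
  seeds <- derive_seeds(seed, nrow(rows))
  purrr::pmap_dfr(
    list(rows$subject, rows$group, rows$region, rows$k1, rows$k2, seeds),
    function(subject, group, region, k1, k2, sub_seed) {
      p <- one_tissue_params(k1, k2)
      tac <- frame_average(function(t) simulate_1tc(p, plasma, t), schedule, step = 0.025)
      if (noise_scale > 0) tac <- add_tac_noise(tac, noise_scale, sub_seed)
      tibble::tibble(subject = subject, group = group, region = region,
                     frame = tac$frame, mid = tac$mid, activity = tac$activity)
    }
  )
}

#' Generate a synthetic cohort
#'
#' Draws per-subject kinetic parameters and simulates every TAC, returning
#' the complete dataset that downstream quantification and statistics
#' consume. Reproducible: the same config and seed give a bit-identical
#' dataset.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed; default the config's.
#' @return An object of class `pet_cohort`: `config`, `seed`, `params`,
#'   `tacs`, `schedule`, `plasma`, `reference` and a deterministic
#'   `config_hash`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_cn = 3, n_ad = 3))
#' head(coh$params)
#' }
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  params <- draw_cohort_params(config, seed = seed)
  tacs <- simulate_cohort_tacs(params, config$schedule, config$plasma,
                               noise_scale = config$noise_scale,
                               seed = seed + 1L)
  structure(list(
    config = config, seed = as.integer(seed), params = params, tacs = tacs,
    schedule = config$schedule, plasma = config$plasma,
    reference = config$reference,
    config_hash = cohort_hash(config, seed)
  ), class = "pet_cohort")
}

cohort_hash <- function(config, seed) {
  rlang::hash(list(
    n_cn = config$n_cn, n_ad = config$n_ad,
    regions = as.data.frame(config$regions), reference = config$reference,
    cv_global = config$cv_global, cv_region = config$cv_region,
    noise_scale = config$noise_scale,
    schedule = as.data.frame(config$schedule),
    plasma = unclass(config$plasma), seed = as.integer(seed)
  ))
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf("Synthetic PET cohort: %d subjects x %d regions, %d frames (seed %d, hash %s)\n",
              length(unique(x$params$subject)), length(unique(x$params$region)),
              nrow(x$schedule), x$seed, substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' True distribution volume ratios of a cohort
#'
#' DVR by construction: each region's VT divided by the reference region's
#' VT for the same subject.
#'
#' @param cohort A `pet_cohort`.
#' @return A tibble: `subject`, `group`, `region`, `dvr`.
#' @export
true_dvr <- function(cohort) {
  stopifnot(inherits(cohort, "pet_cohort"))
  refs <- cohort$params |>
    dplyr::filter(.data$region == cohort$reference) |>
    dplyr::select("subject", vt_ref = "vt")
  cohort$params |>
    dplyr::left_join(refs, by = "subject") |>
    dplyr::mutate(dvr = .data$vt / .data$vt_ref) |>
    dplyr::select("subject", "group", "region", "dvr")
}
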