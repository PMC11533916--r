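# Plain-text serialization of cohorts: per-subject TAC TSVs in a simple
# dialect, a parameter table, a YAML config and a manifest carrying the
# seed and config hash.

# shortest decimal representation that parses back to the same double
num_to_chr <- function(x) {
  s <- trimws(formatC(x, format = "g", digits = 15))
  bad <- is.finite(x) & (as.numeric(s) != x)
  s[bad] <- sprintf("%.17g", x[bad])
  s
}

format_tsv_exact <- function(df) {
  cols <- lapply(df, function(col) if (is.numeric(col)) num_to_chr(col) else as.character(col))
  c(paste(names(df), collapse = "\t"),
    do.call(paste, c(cols, sep = "\t")))
}

#' Read and write regional TAC tables
#'
#' The TAC TSV dialect: a header row `frame_start`, `frame_end` followed by
#' one column per region; one row per frame; times in minutes; UTF-8.
#' Values round-trip exactly.
#'
#' @param x A data frame whose first two columns are `frame_start` and
#'   `frame_end`, the rest regional activities.
#' @param path File path.
#' @return `read_tac_tsv()` returns the parsed tibble; `write_tac_tsv()`
#'   returns `path` invisibly.
#' @export
write_tac_tsv <- function(x, path) {
  if (!all(names(x)[1:2] == c("frame_start", "frame_end"))) {
    abort_invalid("TAC table must start with `frame_start` and `frame_end` columns.")
  }
  writeLines(format_tsv_exact(x), path)
  invisible(path)
}

#' @rdname write_tac_tsv
#' @export
read_tac_tsv <- function(path) {
  # base parser: correctly-rounded doubles, so values round-trip exactly
  x <- tibble::as_tibble(utils::read.delim(path, sep = "\t", check.names = FALSE))
  if (ncol(x) < 3 || !all(names(x)[1:2] == c("frame_start", "frame_end"))) {
    abort_invalid(paste0("'", path, "' is not a TAC TSV (expected frame_start, frame_end, regions...)."))
  }
  x
}

config_to_list <- function(config) {
  list(
    n_cn = config$n_cn, n_ad = config$n_ad,
    regions = lapply(seq_len(nrow(config$regions)), function(i) as.list(config$regions[i, ])),
    reference = config$reference,
    cv_global = config$cv_global, cv_region = config$cv_region,
    noise_scale = config$noise_scale,
    frame_durations = config$schedule$dur,
    plasma = unclass(config$plasma),
    seed = config$seed
  )
}

config_from_list <- function(x) {
  cohort_config(
    n_cn = x$n_cn, n_ad = x$n_ad,
    regions = dplyr::bind_rows(lapply(x$regions, tibble::as_tibble)),
    reference = x$reference,
    cv_global = x$cv_global, cv_region = x$cv_region,
    noise_scale = x$noise_scale,
    schedule = frame_schedule(as.numeric(x$frame_durations)),
    plasma = do.call(plasma_input, x$plasma[c("a1", "a2", "a3", "l1", "l2", "l3", "delay")]),
    seed = x$seed
  )
}

#' Write / read a cohort directory
#'
#' Layout: `params.tsv` (subject, group, region, k1, k2, vt), one
#' `tacs/<subject>.tsv` per subject in the TAC dialect, `config.yaml` and
#' `manifest.yaml` (seed, config hash, subject list). Reading checks the
#' manifest and that every TAC file carries the reference-region column.
#'
#' @param cohort A `pet_cohort`.
#' @param dir Directory to create/read.
#' @return `read_cohort()` returns the reconstructed `pet_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pet_cohort"))
  dir.create(file.path(dir, "tacs"), recursive = TRUE, showWarnings = FALSE)
  writeLines(format_tsv_exact(cohort$params), file.path(dir, "params.tsv"))
  subjects <- unique(cohort$params$subject)
  for (s in subjects) {
    wide <- cohort$tacs |>
      dplyr::filter(.data$subject == s) |>
      dplyr::select("region", "frame", "activity") |>
      tidyr::pivot_wider(names_from = "region", values_from = "activity") |>
      dplyr::arrange(.data$frame)
    out <- dplyr::bind_cols(
      tibble::tibble(frame_start = cohort$schedule$start, frame_end = cohort$schedule$end),
      dplyr::select(wide, -"frame")
    )
    write_tac_tsv(out, file.path(dir, "tacs", paste0(s, ".tsv")))
  }
  yaml::write_yaml(config_to_list(cohort$config), file.path(dir, "config.yaml"))
  yaml::write_yaml(list(seed = cohort$seed, config_hash = cohort$config_hash,
                        subjects = as.list(subjects)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(man_path)) {
    rlang::abort(paste0("Cohort manifest not found: '", man_path, "'."),
                 class = "petsuvr_load_error")
  }
  man <- tryCatch(yaml::read_yaml(man_path), error = function(e) {
    rlang::abort(paste0("Corrupt cohort manifest '", man_path, "': ", conditionMessage(e)),
                 class = "petsuvr_load_error")
  })
  if (is.null(man$seed) || is.null(man$subjects)) {
    rlang::abort(paste0("Manifest '", man_path, "' is missing seed/subjects."),
                 class = "petsuvr_load_error")
  }
  config <- config_from_list(yaml::read_yaml(file.path(dir, "config.yaml")))
  params <- tibble::as_tibble(utils::read.delim(file.path(dir, "params.tsv"),
                                                sep = "\t", check.names = FALSE))
  tacs <- purrr::map_dfr(as.character(man$subjects), function(s) {
    x <- read_tac_tsv(file.path(dir, "tacs", paste0(s, ".tsv")))
    if (!config$reference %in% names(x)) {
      rlang::abort(paste0("TAC file for subject '", s, "' lacks the reference region column '",
                          config$reference, "'."),
                   class = "petsuvr_schema_error")
    }
    grp <- params$group[match(s, params$subject)]
    x |>
      dplyr::mutate(frame = dplyr::row_number(),
                    mid = (.data$frame_start + .data$frame_end) / 2) |>
      dplyr::select(-"frame_start", -"frame_end") |>
      tidyr::pivot_longer(-c("frame", "mid"), names_to = "region", values_to = "activity") |>
      dplyr::mutate(subject = s, group = grp) |>
      dplyr::select("subject", "group", "region", "frame", "mid", "activity")
  })
  region_order <- unique(params$region)
  tacs <- tacs |>
    dplyr::mutate(region = factor(.data$region, levels = region_order)) |>
    dplyr::arrange(match(.data$subject, params$subject), .data$region, .data$frame) |>
    dplyr::mutate(region = as.character(.data$region))
  structure(list(
    config = config, seed = as.integer(man$seed),
    params = tibble::as_tibble(params), tacs = tacs,
    schedule = config$schedule, plasma = config$plasma,
    reference = config$reference,
    config_hash = man$config_hash %||% cohort_hash(config, man$seed)
  ), class = "pet_cohort")
}
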