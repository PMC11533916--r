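test_that("cohort generation is bit-identical under a fixed seed", {
  c1 <- generate_cohort(small_config(), seed = 5L)
  c2 <- generate_cohort(small_config(), seed = 5L)
  expect_identical(c1$params, c2$params)
  expect_identical(c1$tacs, c2$tacs)
  expect_identical(c1$config_hash, c2$config_hash)
  c3 <- generate_cohort(small_config(), seed = 6L)
  expect_false(identical(c1$params, c3$params))
})

test_that("true DVR equals the VT ratio by construction", {
  coh <- generate_cohort(small_config(), seed = 2L)
  dvr <- true_dvr(coh)
  ref_vt <- coh$params$vt[coh$params$region == "whole cerebellum"]
  names(ref_vt) <- coh$params$subject[coh$params$region == "whole cerebellum"]
  manual <- coh$params$vt / ref_vt[coh$params$subject]
  expect_equal(dvr$dvr, unname(manual))
  expect_equal(dvr$dvr[dvr$region == "whole cerebellum"], rep(1, 9))
})

test_that("null reductions give group-indistinguishable DVR distributions", {
  cfg <- cohort_config(
    regions = dplyr::mutate(petsuvr:::default_region_table(),
                            vt_reduction = 0, k1_reduction = 0))
  par <- draw_cohort_params(cfg, seed = 101L)
  coh <- structure(list(params = par, reference = "whole cerebellum"), class = "pet_cohort")
  dvr <- true_dvr(coh)
  d_hip <- cohen_d(dvr$dvr[dvr$group == "CN" & dvr$region == "hippocampus"],
                   dvr$dvr[dvr$group == "AD" & dvr$region == "hippocampus"])
  expect_lt(abs(d_hip), 0.4)
})

test_that("generated group means converge to configured means at large n", {
  cfg <- small_config(n_cn = 500, n_ad = 500)
  par <- draw_cohort_params(cfg, seed = 9L)
  for (r in cfg$regions$region) {
    i <- match(r, cfg$regions$region)
    m_cn <- mean(par$k1[par$group == "CN" & par$region == r])
    expect_equal(m_cn, cfg$regions$k1_cn[i], tolerance = 0.02)
    m_ad <- mean(par$vt[par$group == "AD" & par$region == r])
    expect_equal(m_ad, cfg$regions$vt_cn[i] * (1 - cfg$regions$vt_reduction[i]),
                 tolerance = 0.02)
  }
})

test_that("a 20% density reduction is recovered by SRTM2 and late-window SUVR", {
  regions <- tibble::tribble(
    ~region,           ~k1_cn, ~vt_cn, ~vt_reduction, ~k1_reduction,
    "hippocampus",      0.25,   12.0,   0.20,          0,
    "whole cerebellum", 0.30,   14.0,   0,             0
  )
  cfg <- cohort_config(n_cn = 60, n_ad = 60, regions = regions, noise_scale = 0)
  coh <- generate_cohort(cfg, seed = 21L)
  dvr_true <- true_dvr(coh) |> dplyr::filter(region == "hippocampus")
  pct_true <- 100 * (mean(dvr_true$dvr[dvr_true$group == "CN"]) -
                     mean(dvr_true$dvr[dvr_true$group == "AD"])) /
    mean(dvr_true$dvr[dvr_true$group == "CN"])
  expect_equal(pct_true, 20, tolerance = 0.15)
  fits <- fit_cohort_dvr(coh)
  pct_fit <- 100 * (mean(fits$dvr[fits$group == "CN"]) - mean(fits$dvr[fits$group == "AD"])) /
    mean(fits$dvr[fits$group == "CN"])
  expect_lt(abs(pct_fit - pct_true), 2)
  # late-time tissue-to-reference ratio approaches the DVR difference
  ps <- run_perfusion_simulation(coh, scenarios = 0)
  tc <- ps$timecourse
  pct_late <- tc$pct_diff[tc$time_min == max(tc$time_min)]
  expect_lt(abs(pct_late - pct_true), 2)
})

test_that("cohort round-trips through its on-disk layout", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(small_config(noise_scale = 0.02), seed = 13L)
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  back <- read_cohort(dir)
  expect_equal(back$params, coh$params)
  expect_equal(back$tacs$activity, coh$tacs$activity)
  expect_equal(back$tacs$region, coh$tacs$region)
  expect_identical(back$seed, coh$seed)
  expect_identical(back$config_hash, coh$config_hash)
  # regeneration from the stored config + seed is bit-identical
  regen <- generate_cohort(back$config, seed = back$seed)
  expect_identical(regen$params, coh$params)
  expect_identical(regen$tacs, coh$tacs)
})

test_that("corrupt or incomplete cohort directories fail with named errors", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(small_config(), seed = 1L)
  write_cohort(coh, dir)
  # drop the reference-region column from one subject's TAC file
  f <- file.path(dir, "tacs", "cn01.tsv")
  x <- read_tac_tsv(f)
  write_tac_tsv(x[, setdiff(names(x), "whole cerebellum")], f)
  expect_error(read_cohort(dir), class = "petsuvr_schema_error", regexp = "cn01")
  # missing manifest names the file
  file.remove(file.path(dir, "manifest.yaml"))
  expect_error(read_cohort(dir), class = "petsuvr_load_error", regexp = "manifest")
})

test_that("TAC TSV dialect round-trips exactly", {
  dir <- withr::local_tempdir()
  x <- tibble::tibble(frame_start = sched27$start, frame_end = sched27$end,
                      hippocampus = simulate_1tc(one_tissue_params(0.25, 0.02), cp_default, sched27$mid),
                      `whole cerebellum` = simulate_1tc(one_tissue_params(0.3, 0.021), cp_default, sched27$mid))
  f <- file.path(dir, "tac.tsv")
  write_tac_tsv(x, f)
  y <- read_tac_tsv(f)
  expect_equal(as.data.frame(y), as.data.frame(x))
  # a second write of the parsed table reproduces the file byte for byte
  f2 <- file.path(dir, "tac2.tsv")
  write_tac_tsv(y, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("invalid configurations produce itemized validation errors", {
  expect_error(cohort_config(n_cn = 1), "n_cn")
  err <- tryCatch(
    cohort_config(n_cn = 1, cv_global = -1,
                  regions = dplyr::mutate(default_region_table <- petsuvr:::default_region_table(),
                                          vt_reduction = 2)),
    error = function(e) conditionMessage(e))
  expect_match(err, "n_cn")
  expect_match(err, "cv_global")
  expect_match(err, "Reductions")
})
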