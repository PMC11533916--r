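test_that("SRTM prediction reduces to the reference curve in the identity case", {
  ref <- mk_tac(0.3, 0.12)
  pred <- srtm_predict(ref, r1 = 1, k2a = 0.12, k2prime = 0.12)
  expect_equal(pred, ref$activity)
})

test_that("SRTM prediction is exact for 1TC target/reference pairs", {
  # both regions 1TC with shared input; dense sampling so the piecewise-
  # linear treatment of the reference is not the limiting factor
  fine <- frame_schedule(rep(0.1, 900))
  ref <- mk_tac_mid(0.3, 0.12, schedule = fine)
  target <- mk_tac_mid(0.3, 0.06, schedule = fine)
  pred <- srtm_predict(ref, r1 = 1, k2a = 0.06, k2prime = 0.12)
  keep <- target$activity > 1  # relative error where activity is non-negligible
  expect_lt(max(abs(pred[keep] / target$activity[keep] - 1)), 0.002)
})

test_that("SRTM prediction matches a fine-grid convolution oracle at large apparent efflux", {
  fine <- frame_schedule(rep(0.1, 900))
  ref <- mk_tac_mid(0.3, 0.12, schedule = fine)
  k2a_big <- 5
  pred <- srtm_predict(ref, r1 = 0.9, k2a = k2a_big, k2prime = 0.12)
  # independent trapezoid convolution of the interpolated reference
  dt <- 0.001
  grid <- seq(0, max(fine$mid), by = dt)
  cr <- stats::approx(c(0, ref$mid), c(0, ref$activity), xout = grid)$y
  e <- exp(-k2a_big * dt)
  b <- c(0, dt / 2 * (cr[-1] + e * cr[-length(cr)]))
  conv <- stats::approx(grid, as.numeric(stats::filter(b, e, method = "recursive")),
                        xout = ref$mid)$y
  oracle <- 0.9 * ref$activity + 0.9 * (0.12 - k2a_big) * conv
  keep <- abs(oracle) > 1
  expect_lt(max(abs(pred[keep] / oracle[keep] - 1)), 0.005)
})

test_that("SRTM fit returns the identity solution when target equals reference", {
  ref <- mk_tac(0.3, 0.12)
  f <- fit_srtm(ref, ref)
  expect_true(f$converged)
  expect_equal(f$r1, 1, tolerance = 1e-3)
  expect_equal(f$dvr, 1, tolerance = 0.01)
})

test_that("SRTM recovers DVR = VT ratio on noiseless 1TC pairs", {
  target <- mk_tac(0.3, 0.06)  # VT 5
  ref <- mk_tac(0.3, 0.12)     # VT 2.5
  f <- fit_srtm(target, ref)
  expect_equal(f$dvr, 2, tolerance = 0.01)
  expect_equal(f$k2prime, 0.12, tolerance = 0.02)
})

test_that("SRTM DVR is robust under frame noise (median bias small)", {
  target0 <- mk_tac(0.3, 0.06)
  ref0 <- mk_tac(0.3, 0.12)
  dvrs <- vapply(1:25, function(s) {
    t_n <- add_tac_noise(target0, 0.05, seed = 2000 + s)
    r_n <- add_tac_noise(ref0, 0.05, seed = 4000 + s)
    fit_srtm(t_n, r_n)$dvr
  }, numeric(1))
  expect_lt(abs(stats::median(dvrs) / 2 - 1), 0.03)
})

test_that("k2prime pooling follows the median strategy with fall-backs", {
  mkfit <- function(k2p, bpnd) structure(list(k2prime = k2p, bpnd = bpnd, converged = TRUE),
                                         class = "srtm_fit")
  expect_equal(estimate_k2prime(list(mkfit(0.11, 1))), 0.11)
  expect_equal(estimate_k2prime(list(mkfit(0.1, 1), mkfit(0.2, 1), mkfit(0.3, 1))), 0.2)
  # below-threshold BPND values trigger the all-converged fallback with a message
  expect_message(
    v <- estimate_k2prime(list(mkfit(0.1, 0.1), mkfit(0.2, 0.2))),
    "pooling"
  )
  expect_equal(v, 0.15)
  expect_equal(estimate_k2prime(list(), strategy = "fixed", value = 0.07), 0.07)
  expect_error(estimate_k2prime(list()), class = "petsuvr_invalid_input")
  # noiseless cohort sharing true reference k2 = 0.12
  ref <- mk_tac(0.3, 0.12)
  fits <- lapply(c(0.04, 0.05, 0.07), function(k2t) fit_srtm(mk_tac(0.28, k2t), ref))
  expect_equal(estimate_k2prime(fits, bpnd_threshold = 0), 0.12, tolerance = 0.01)
})

test_that("SRTM2 returns DVR 1 when target equals reference and the true k2' is supplied", {
  ref <- mk_tac(0.3, 0.12)
  f <- fit_srtm2(ref, ref, k2prime = 0.12)
  expect_true(f$converged)
  expect_equal(f$dvr, 1, tolerance = 0.005)
})

test_that("SRTM2 recovers the VT ratio across a parameter grid with correct k2'", {
  set.seed(11)
  for (i in 1:8) {
    k1t <- runif(1, 0.15, 0.45); vtt <- runif(1, 8, 20)
    k1r <- runif(1, 0.2, 0.4); vtr <- runif(1, 10, 18)
    f <- fit_srtm2(mk_tac(k1t, k1t / vtt), mk_tac(k1r, k1r / vtr), k2prime = k1r / vtr)
    expect_equal(f$dvr, vtt / vtr, tolerance = 0.01)
  }
})

test_that("basis-function SRTM2 matches a brute-force nonlinear refit, including mis-set k2'", {
  target <- mk_tac(0.28, 0.024)  # VT ~ 11.7
  ref <- mk_tac(0.30, 0.021)     # VT ~ 14.3
  true_dvr <- (0.28 / 0.024) / (0.30 / 0.021)
  for (fac in c(0.75, 1, 1.25)) {
    k2p <- 0.021 * fac
    f <- fit_srtm2(target, ref, k2prime = k2p)
    oracle <- brute_srtm2(target, ref, k2prime = k2p)
    expect_equal(f$dvr, oracle$dvr, tolerance = 0.005)
    if (fac == 1) expect_equal(f$dvr, true_dvr, tolerance = 0.01)
  }
  # a mis-set k2' biases DVR; the basis fit reproduces the same biased value
  f_lo <- fit_srtm2(target, ref, k2prime = 0.021 * 0.75)
  f_hi <- fit_srtm2(target, ref, k2prime = 0.021 * 1.25)
  expect_false(isTRUE(all.equal(f_lo$dvr, true_dvr, tolerance = 0.005)))
  expect_false(isTRUE(all.equal(f_hi$dvr, true_dvr, tolerance = 0.005)))
})

test_that("SRTM2 outputs are invariant to a common rescaling of both TACs", {
  target <- mk_tac(0.3, 0.06); ref <- mk_tac(0.3, 0.12)
  f1 <- fit_srtm2(target, ref, k2prime = 0.12)
  t2 <- target; t2$activity <- 3.7 * t2$activity
  r2 <- ref; r2$activity <- 3.7 * r2$activity
  f2 <- fit_srtm2(t2, r2, k2prime = 0.12)
  expect_equal(f2$dvr, f1$dvr)
  expect_equal(f2$r1, f1$r1)
  expect_equal(f2$k2a, f1$k2a)
})

test_that("fitted DVR increases strictly with target VT on noiseless data", {
  ref <- mk_tac(0.3, 0.12)
  vts <- c(2, 3, 5, 8)
  dvrs <- vapply(vts, function(vt) fit_srtm2(mk_tac(0.3, 0.3 / vt), ref, k2prime = 0.12)$dvr,
                 numeric(1))
  expect_true(all(diff(dvrs) > 0))
})

test_that("tidy methods expose the fitted reference-model parameters", {
  target <- mk_tac(0.3, 0.06); ref <- mk_tac(0.3, 0.12)
  t1 <- tidy(fit_srtm(target, ref))
  expect_named(t1, c("r1", "k2", "k2a", "k2prime", "bpnd", "dvr", "rss", "converged"))
  t2 <- tidy(fit_srtm2(target, ref, k2prime = 0.12))
  expect_true(all(c("r1", "k2a", "dvr") %in% names(t2)))
})
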