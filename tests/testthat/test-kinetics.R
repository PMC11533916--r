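test_that("frame schedule reproduces the 27-frame 90-min protocol and enforces invariants", {
  s <- frame_schedule()
  expect_equal(nrow(s), 27)
  expect_equal(max(s$end), 90)
  expect_equal(s$start[1], 0)
  expect_equal(s$start[-1], s$end[-27])
  expect_equal(s$dur, c(rep(0.5, 6), rep(1, 3), rep(2, 2), rep(5, 16)))
  expect_error(frame_schedule(c(1, -1)), class = "petsuvr_invalid_input")
  bad <- s; bad$start[5] <- bad$start[5] + 0.1
  expect_error(petsuvr:::validate_schedule(bad), class = "petsuvr_invalid_input")
})

test_that("plasma input is zero before the delay and matches its closed form", {
  cp <- plasma_input(delay = 2)
  expect_equal(eval_plasma(cp, c(0, 0.5, 1.9)), c(0, 0, 0))
  # pure single-exponential case evaluates to its amplitude at the origin
  cp1 <- plasma_input(a1 = 0, a2 = 1, a3 = 0, l2 = 0.1, delay = 0)
  expect_equal(eval_plasma(cp1, 0), 1)
  # default parameters against a direct evaluation of the expression
  cp0 <- plasma_input()
  t <- 10; u <- t - cp0$delay
  manual <- cp0$a1 * u * exp(-cp0$l1 * u) + cp0$a2 * exp(-cp0$l2 * u) + cp0$a3 * exp(-cp0$l3 * u)
  expect_equal(eval_plasma(cp0, t), manual)
  expect_error(plasma_input(l1 = 0.1, l2 = 0.5), class = "petsuvr_invalid_input")
  expect_error(eval_plasma(cp0, c(-1, 5)), class = "petsuvr_invalid_input")
})

test_that("1TC simulation matches closed forms for constant and mono-exponential inputs", {
  k1 <- 0.3; k2 <- 0.1
  p <- one_tissue_params(k1, k2)
  ts <- c(1, 5, 20, 60)
  # constant infusion
  cst <- simulate_1tc(p, function(t) rep(2, length(t)), ts, dt = 0.001)
  expect_equal(cst, k1 * 2 / k2 * (1 - exp(-k2 * ts)), tolerance = 1e-4)
  # mono-exponential input
  lam <- 0.04
  mono <- simulate_1tc(p, function(t) exp(-lam * t), ts, dt = 0.001)
  expect_equal(mono, k1 * (exp(-lam * ts) - exp(-k2 * ts)) / (k2 - lam), tolerance = 1e-4)
  expect_error(one_tissue_params(0.3, -0.1), class = "petsuvr_invalid_input")
})

test_that("closed-form convolution agrees with a fine-grid brute-force oracle", {
  ts <- c(5, 30, 60, 90)
  for (pars in list(c(0.3, 0.1), c(0.15, 0.02), c(0.5, 0.25))) {
    ct <- simulate_1tc(one_tissue_params(pars[1], pars[2]), cp_default, ts)
    bf <- brute_1tc(pars[1], pars[2], cp_default, ts)
    expect_lt(max(abs(ct / bf - 1)), 1e-3)
  }
})

test_that("constant-infusion tissue-to-plasma ratio converges to VT", {
  k1 <- 0.3; k2 <- 0.1
  t_eq <- 10 / k2
  ct <- simulate_1tc(one_tissue_params(k1, k2), function(t) rep(1, length(t)), t_eq, dt = 0.005)
  expect_equal(ct / 1, k1 / k2, tolerance = 0.01)
})

test_that("frame averaging reproduces analytic frame means", {
  s <- frame_schedule(c(1, 1, 2))
  const <- frame_average(function(t) rep(3.5, length(t)), s)
  expect_equal(const$activity, rep(3.5, 3))
  lin <- frame_average(function(t) t, frame_schedule(1))
  expect_equal(lin$activity, 0.5)
  # simulated curve against adaptive quadrature
  p <- one_tissue_params(0.3, 0.1)
  f <- function(t) simulate_1tc(p, cp_default, t)
  tac <- frame_average(f, sched27)
  for (i in c(2, 7, 20, 27)) {
    oracle <- stats::integrate(f, sched27$start[i], sched27$end[i],
                               rel.tol = 1e-9)$value / sched27$dur[i]
    expect_equal(tac$activity[i], oracle, tolerance = 1e-3)
  }
  expect_error(frame_average(f, sched27[0, ]), class = "petsuvr_invalid_input")
})

test_that("frame averaging accepts dense samples as well as functions", {
  grid <- seq(0, 90, by = 0.01)
  p <- one_tissue_params(0.3, 0.1)
  dense <- data.frame(t = grid, y = simulate_1tc(p, cp_default, grid))
  tac_fn <- frame_average(function(t) simulate_1tc(p, cp_default, t), sched27)
  tac_ds <- frame_average(dense, sched27)
  expect_equal(tac_ds$activity, tac_fn$activity, tolerance = 1e-4)
})

test_that("noise model is reproducible, vanishes at scale 0, and matches its variance contract", {
  tac <- mk_tac(0.3, 0.1)
  expect_identical(add_tac_noise(tac, 0, seed = 1), tac)
  n1 <- add_tac_noise(tac, 0.05, seed = 42)
  n2 <- add_tac_noise(tac, 0.05, seed = 42)
  expect_identical(n1, n2)
  expect_false(identical(n1$activity, tac$activity))
  expect_error(add_tac_noise(tac, -1, seed = 1), class = "petsuvr_invalid_input")
  # Monte-Carlo check of the stated variance at one late frame
  i <- 20
  lam <- log(2) / 20.4
  target_var <- 0.05^2 * tac$activity[i] * exp(lam * tac$mid[i]) / tac$dur[i]
  draws <- vapply(seq_len(1000), function(s) add_tac_noise(tac, 0.05, seed = s)$activity[i],
                  numeric(1))
  expect_equal(stats::var(draws), target_var, tolerance = 0.1)
})

test_that("1TC fitting recovers generating parameters and is linear in K1", {
  tac <- mk_tac(0.3, 0.1)
  f <- fit_1tc(tac, cp_default)
  expect_true(f$converged)
  expect_equal(f$k1, 0.3, tolerance = 0.005)
  expect_equal(f$k2, 0.1, tolerance = 0.005)
  # doubling the TAC doubles K1, leaves k2 unchanged
  tac2 <- tac; tac2$activity <- 2 * tac2$activity
  f2 <- fit_1tc(tac2, cp_default)
  expect_equal(f2$k1, 2 * f$k1, tolerance = 0.005)
  expect_equal(f2$k2, f$k2, tolerance = 0.005)
  expect_equal(tidy(f)$estimate, c(f$k1, f$k2, f$vt))
  expect_true(glance(f)$converged)
  expect_error(fit_1tc(tac[1:3, ], cp_default), class = "petsuvr_invalid_input")
})

test_that("simulated tissue curves start at zero and stay non-negative", {
  for (pars in list(c(0.1, 0.02), c(0.6, 0.3))) {
    ct <- simulate_1tc(one_tissue_params(pars[1], pars[2]), cp_default,
                       c(0, 0.25, seq(1, 90, by = 7)))
    expect_equal(ct[1], 0)
    expect_true(all(ct >= 0))
  }
})
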