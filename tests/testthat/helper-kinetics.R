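# Shared fixtures: default input, schedule, and TAC builders.

cp_default <- plasma_input()
sched27 <- frame_schedule()

# frame-averaged TAC for 1TC parameters under the default input
mk_tac <- function(k1, k2, schedule = sched27, input = cp_default, region = NULL) {
  p <- one_tissue_params(k1, k2)
  frame_average(function(t) simulate_1tc(p, input, t), schedule, region = region)
}

# TAC sampled instantaneously at frame midpoints (continuous-sampling mode)
mk_tac_mid <- function(k1, k2, schedule = sched27, input = cp_default, region = NULL) {
  p <- one_tissue_params(k1, k2)
  new_tac(schedule, simulate_1tc(p, input, schedule$mid), region = region)
}

# brute-force discrete-convolution oracle for the 1TC model (trapezoid rule)
brute_1tc <- function(k1, k2, input, times, dt = 0.001) {
  tmax <- max(times)
  grid <- seq(0, tmax, by = dt)
  cp <- eval_plasma(input, grid)
  e <- exp(-k2 * dt)
  b <- c(0, dt / 2 * (cp[-1] + e * cp[-length(cp)]))
  y <- as.numeric(stats::filter(b, e, method = "recursive"))
  k1 * stats::approx(grid, y, xout = times)$y
}

# brute-force SRTM2 oracle: dense nonlinear least squares over (R1, k2a)
# with k2' fixed, same weighted objective as the basis fit
brute_srtm2 <- function(target, ref, k2prime, window = c(0, 60)) {
  idx <- which(target$start >= window[1] & target$end <= window[2])
  w <- frame_weights(target)[idx]
  ct <- target$activity[idx]
  obj <- function(par) {
    r1 <- par[1]; k2a <- exp(par[2])
    conv <- petsuvr:::expconv_lin(target$mid, ref$activity, k2a)[idx, 1]
    pred <- r1 * ref$activity[idx] + r1 * (k2prime - k2a) * conv
    sum(w * (ct - pred)^2)
  }
  best <- NULL
  for (k2a0 in c(0.01, 0.03, 0.1, 0.3)) {
    o <- stats::optim(c(1, log(k2a0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  r1 <- best$par[1]; k2a <- exp(best$par[2])
  list(r1 = r1, k2a = k2a, bpnd = r1 * k2prime / k2a - 1,
       dvr = r1 * k2prime / k2a, rss = best$value)
}

# tiny cohort config used across tests (fast to simulate)
small_config <- function(n_cn = 4, n_ad = 5, ...) {
  cohort_config(
    n_cn = n_cn, n_ad = n_ad,
    regions = tibble::tribble(
      ~region,            ~k1_cn, ~vt_cn, ~vt_reduction, ~k1_reduction,
      "hippocampus",       0.25,   12.0,   0.10,          0.15,
      "lateral temporal cortex", 0.30, 16.0, 0.08,        0.12,
      "whole cerebellum",  0.30,   14.0,   0.01,          0.03
    ),
    ...
  )
}
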