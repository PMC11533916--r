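# Reference-tissue models: SRTM (three-parameter first pass) and SRTM2
# (fixed reference efflux k2'), both via basis-function estimation.

# Exact exponential convolution of a piecewise-linear curve:
# y(t_i) = int_0^{t_i} C(s) exp(-theta (t_i - s)) ds, where C is the linear
# interpolant of (times, values) anchored at C(0) = 0 (tracer starts at
# zero). `theta` may be a vector; returns a length(times) x length(theta)
# matrix.
expconv_lin <- function(times, values, theta) {
  if (length(times) != length(values)) abort_invalid("times/values length mismatch.")
  tt <- c(0, times)
  yy <- c(0, values)
  nt <- length(theta)
  out <- matrix(0, nrow = length(times), ncol = nt)
  acc <- numeric(nt)
  for (i in seq_along(times)) {
    d <- tt[i + 1] - tt[i]
    if (d <= 0) abort_invalid("`times` must be strictly increasing and > 0.")
    e <- exp(-theta * d)
    m <- (yy[i + 1] - yy[i]) / d
    acc <- acc * e + yy[i + 1] * (1 - e) / theta - m * (1 - e * (1 + theta * d)) / theta^2
    out[i, ] <- acc
  }
  out
}

default_k2a_grid <- function(n = 128L, range = c(0.006, 0.6)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

# Frames whose span lies inside the fit window.
window_frames <- function(schedule, window) {
  if (length(window) != 2L || window[1] < 0 || window[2] <= window[1]) {
    abort_invalid("`window` must be c(start, end) minutes with start < end.")
  }
  idx <- which(schedule$start >= window[1] - 1e-9 & schedule$end <= window[2] + 1e-9)
  if (length(idx) < 3L) abort_invalid("Fit window contains fewer than 3 frames.")
  idx
}

#' Predict a target TAC under the simplified reference tissue model
#'
#' Operational equation
#' \deqn{C_T(t) = R_1 C_R(t) + R_1 (k_2' - k_{2a}) \int_0^t C_R(s) e^{-k_{2a}(t-s)} ds,}
#' with the reference curve treated as piecewise linear between frame
#' midpoints (anchored at zero at t = 0). Exact when target and reference
#' both follow one-tissue kinetics with a shared plasma input.
#'
#' @param ref_tac Reference-region TAC tibble.
#' @param r1 Relative delivery R1 (unitless), > 0.
#' @param k2a Apparent target efflux (1/min), > 0.
#' @param k2prime Reference efflux k2' (1/min), > 0.
#' @param times Evaluation times; default the reference frame midpoints.
#' @return Predicted target activity at `times`.
#' @export
srtm_predict <- function(ref_tac, r1, k2a, k2prime, times = NULL) {
  validate_schedule(ref_tac)
  check_number(r1, "r1", positive = TRUE)
  check_number(k2a, "k2a", positive = TRUE)
  check_number(k2prime, "k2prime", positive = TRUE)
  if (is.null(times)) {
    cr <- ref_tac$activity
    conv <- expconv_lin(ref_tac$mid, cr, k2a)[, 1]
  } else {
    f <- stats::approxfun(c(0, ref_tac$mid), c(0, ref_tac$activity), rule = 2)
    cr <- f(times)
    conv <- expconv_lin(times, cr, k2a)[, 1]
  }
  r1 * cr + r1 * (k2prime - k2a) * conv
}

# Shared machinery: weighted basis-function solve on window frames.
srtm_basis_env <- function(target, ref, window, weights, grid) {
  validate_schedule(target); validate_schedule(ref)
  if (nrow(target) != nrow(ref) || any(abs(target$mid - ref$mid) > 1e-9)) {
    abort_invalid("Target and reference TACs must share a frame schedule.")
  }
  idx <- window_frames(target, window)
  if (is.null(weights)) weights <- frame_weights(target)
  conv <- expconv_lin(target$mid, ref$activity, grid)  # all frames, then subset
  list(
    idx = idx,
    t_mid = target$mid[idx],
    ct = target$activity[idx],
    cr = ref$activity[idx],
    conv = conv[idx, , drop = FALSE],
    w = weights[idx]
  )
}

#' Fit the simplified reference tissue model (SRTM)
#'
#' Basis-function estimation: for each apparent-efflux value k2a on a
#' log-spaced grid the operational equation is linear in two coefficients,
#' solved by weighted least squares; the grid point with minimum weighted
#' RSS wins (ties broken toward the smallest k2a). Returns R1, k2, BPND,
#' DVR and the derived reference efflux k2' = k2/R1, the quantity SRTM2
#' needs as its fixed input.
#'
#' @param target,ref Target and reference TAC tibbles on a shared schedule.
#' @param window Fit window `c(start, end)` in minutes; default 0-60.
#' @param weights Per-frame weights; default [frame_weights()].
#' @param k2a_grid Basis grid of k2a values (1/min).
#' @return An object of class `srtm_fit`: `r1`, `k2`, `k2a`, `k2prime`,
#'   `bpnd`, `dvr`, `rss`, `converged`. Negative BPND is reported, not
#'   clipped, and flagged in `negative_bpnd`.
#' @export
fit_srtm <- function(target, ref, window = c(0, 60), weights = NULL,
                     k2a_grid = default_k2a_grid()) {
  be <- srtm_basis_env(target, ref, window, weights, k2a_grid)
  n <- length(k2a_grid)
  rss <- rep(Inf, n); th1 <- numeric(n); th2 <- numeric(n)
  sw_cc <- sum(be$w * be$cr * be$cr)
  sw_cy <- sum(be$w * be$cr * be$ct)
  for (j in seq_len(n)) {
    b2 <- be$conv[, j]
    a12 <- sum(be$w * be$cr * b2)
    a22 <- sum(be$w * b2 * b2)
    det <- sw_cc * a22 - a12^2
    if (!is.finite(det) || det <= 1e-300) next
    b2y <- sum(be$w * b2 * be$ct)
    t1 <- (a22 * sw_cy - a12 * b2y) / det
    t2 <- (sw_cc * b2y - a12 * sw_cy) / det
    res <- be$ct - t1 * be$cr - t2 * b2
    rss[j] <- sum(be$w * res^2)
    th1[j] <- t1; th2[j] <- t2
  }
  if (all(!is.finite(rss))) {
    return(structure(list(r1 = NA_real_, k2 = NA_real_, k2a = NA_real_,
                          k2prime = NA_real_, bpnd = NA_real_, dvr = NA_real_,
                          rss = NA_real_, converged = FALSE, negative_bpnd = NA,
                          window = window, message = "all basis solves failed"),
                     class = "srtm_fit"))
  }
  j <- which.min(rss)  # first minimum = smallest k2a on the ascending grid
  # local continuous refinement between the neighbouring grid points
  rss_at <- function(k2a) {
    b2 <- expconv_lin(be$t_mid, be$cr, k2a)[, 1]
    a12 <- sum(be$w * be$cr * b2); a22 <- sum(be$w * b2 * b2)
    det <- sw_cc * a22 - a12^2
    if (!is.finite(det) || det <= 1e-300) return(list(rss = Inf))
    b2y <- sum(be$w * b2 * be$ct)
    t1 <- (a22 * sw_cy - a12 * b2y) / det
    t2 <- (sw_cc * b2y - a12 * sw_cy) / det
    res <- be$ct - t1 * be$cr - t2 * b2
    list(rss = sum(be$w * res^2), t1 = t1, t2 = t2)
  }
  lo <- k2a_grid[max(j - 1L, 1L)]; hi <- k2a_grid[min(j + 1L, n)]
  opt <- stats::optimize(function(k) rss_at(k)$rss, c(lo, hi), tol = 1e-8)
  sol <- rss_at(opt$minimum)
  if (is.finite(sol$rss) && sol$rss <= rss[j]) {
    k2a <- opt$minimum; r1 <- sol$t1; th2j <- sol$t2; rssj <- sol$rss
  } else {
    k2a <- k2a_grid[j]; r1 <- th1[j]; th2j <- th2[j]; rssj <- rss[j]
  }
  rss[j] <- rssj
  k2 <- th2j + r1 * k2a
  bpnd <- k2 / k2a - 1
  structure(list(
    r1 = r1, k2 = k2, k2a = k2a, k2prime = k2 / r1,
    bpnd = bpnd, dvr = bpnd + 1, rss = rss[j],
    converged = is.finite(rss[j]) && r1 > 0,
    negative_bpnd = bpnd < 0, window = window, message = "ok"
  ), class = "srtm_fit")
}

#' Fit SRTM2 (fixed reference efflux)
#'
#' As [fit_srtm()] but with the reference efflux k2' fixed, leaving one
#' linear coefficient (R1) per basis value: the standard second-pass model
#' used to quantify DVR with a whole-cerebellum reference. BPND is
#' recovered as R1 k2'/k2a - 1 and DVR = BPND + 1.
#'
#' @inheritParams fit_srtm
#' @param k2prime Fixed reference efflux (1/min), > 0.
#' @return An object of class `srtm2_fit` with `r1`, `k2a`, `k2prime`,
#'   `bpnd`, `dvr`, `rss`, `window`, `converged`.
#' @export
fit_srtm2 <- function(target, ref, k2prime, window = c(0, 60), weights = NULL,
                      k2a_grid = default_k2a_grid()) {
  check_number(k2prime, "k2prime", positive = TRUE)
  be <- srtm_basis_env(target, ref, window, weights, k2a_grid)
  n <- length(k2a_grid)
  rss <- rep(Inf, n); r1s <- numeric(n)
  for (j in seq_len(n)) {
    basis <- be$cr + (k2prime - k2a_grid[j]) * be$conv[, j]
    denom <- sum(be$w * basis^2)
    if (!is.finite(denom) || denom <= 1e-300) next
    r1 <- sum(be$w * basis * be$ct) / denom
    res <- be$ct - r1 * basis
    rss[j] <- sum(be$w * res^2)
    r1s[j] <- r1
  }
  if (all(!is.finite(rss))) {
    return(structure(list(r1 = NA_real_, k2a = NA_real_, k2prime = k2prime,
                          bpnd = NA_real_, dvr = NA_real_, rss = NA_real_,
                          window = window, converged = FALSE, negative_bpnd = NA,
                          message = "all basis solves failed"),
                     class = "srtm2_fit"))
  }
  j <- which.min(rss)
  rss_at <- function(k2a) {
    basis <- be$cr + (k2prime - k2a) * expconv_lin(be$t_mid, be$cr, k2a)[, 1]
    denom <- sum(be$w * basis^2)
    if (!is.finite(denom) || denom <= 1e-300) return(list(rss = Inf))
    r1 <- sum(be$w * basis * be$ct) / denom
    list(rss = sum(be$w * (be$ct - r1 * basis)^2), r1 = r1)
  }
  lo <- k2a_grid[max(j - 1L, 1L)]; hi <- k2a_grid[min(j + 1L, n)]
  opt <- stats::optimize(function(k) rss_at(k)$rss, c(lo, hi), tol = 1e-8)
  sol <- rss_at(opt$minimum)
  if (is.finite(sol$rss) && sol$rss <= rss[j]) {
    k2a <- opt$minimum; r1 <- sol$r1; rss[j] <- sol$rss
  } else {
    k2a <- k2a_grid[j]; r1 <- r1s[j]
  }
  bpnd <- r1 * k2prime / k2a - 1
  structure(list(
    r1 = r1, k2a = k2a, k2prime = k2prime, bpnd = bpnd, dvr = bpnd + 1,
    rss = rss[j], window = window,
    converged = is.finite(rss[j]) && r1 > 0,
    negative_bpnd = bpnd < 0, message = "ok"
  ), class = "srtm2_fit")
}

#' @export
print.srtm_fit <- function(x, ...) {
  cat(sprintf("SRTM fit: R1 = %.4g, k2a = %.4g, k2' = %.4g, BPND = %.4g, DVR = %.4g\n",
              x$r1, x$k2a, x$k2prime, x$bpnd, x$dvr))
  invisible(x)
}

#' @export
print.srtm2_fit <- function(x, ...) {
  cat(sprintf("SRTM2 fit (k2' = %.4g fixed, %g-%g min): R1 = %.4g, k2a = %.4g, BPND = %.4g, DVR = %.4g\n",
              x$k2prime, x$window[1], x$window[2], x$r1, x$k2a, x$bpnd, x$dvr))
  invisible(x)
}

#' @rdname fit_srtm
#' @param x An `srtm_fit` / `srtm2_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.srtm_fit <- function(x, ...) {
  tibble::tibble(
    r1 = x$r1, k2 = x$k2, k2a = x$k2a, k2prime = x$k2prime,
    bpnd = x$bpnd, dvr = x$dvr, rss = x$rss, converged = x$converged
  )
}

#' @rdname fit_srtm2
#' @param x An `srtm2_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.srtm2_fit <- function(x, ...) {
  tibble::tibble(
    r1 = x$r1, k2a = x$k2a, k2prime = x$k2prime,
    bpnd = x$bpnd, dvr = x$dvr, rss = x$rss, converged = x$converged
  )
}

#' Pool a reference-efflux value from first-pass SRTM fits
#'
#' Default strategy: the median k2' over converged fits with BPND above a
#' threshold. For tracers whose target-to-reference DVR sits near 1 (as
#' with a whole-cerebellum reference for SV2A tracers) no fit may exceed the
#' classic threshold of 0.5; in that case the median over all converged
#' fits is used and a message is emitted. The alternative strategy returns
#' a fixed configured value.
#'
#' @param fits A list of `srtm_fit` objects, or a data frame with columns
#'   `k2prime`, `bpnd` and optionally `converged`.
#' @param strategy `"median"` (default) or `"fixed"`.
#' @param value The fixed k2' when `strategy = "fixed"`.
#' @param bpnd_threshold BPND cutoff for inclusion under `"median"`.
#' @return The pooled k2' (1/min).
#' @export
estimate_k2prime <- function(fits, strategy = c("median", "fixed"), value = NULL,
                             bpnd_threshold = 0.5) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed") {
    check_number(value, "value", positive = TRUE)
    return(value)
  }
  if (is.data.frame(fits)) {
    df <- fits
  } else {
    if (length(fits) == 0L) abort_invalid("`fits` must contain at least one fit.")
    df <- dplyr::bind_rows(lapply(fits, function(f) {
      tibble::tibble(k2prime = f$k2prime, bpnd = f$bpnd, converged = isTRUE(f$converged))
    }))
  }
  if (!all(c("k2prime", "bpnd") %in% names(df))) {
    abort_invalid("`fits` must carry `k2prime` and `bpnd`.")
  }
  if (!"converged" %in% names(df)) df$converged <- TRUE
  ok <- df$converged & is.finite(df$k2prime) & df$k2prime > 0
  if (!any(ok)) abort_invalid("No converged fits to pool k2' from.")
  sel <- ok & df$bpnd > bpnd_threshold
  if (!any(sel)) {
    message("No fits with BPND > ", bpnd_threshold,
            "; pooling k2' over all converged fits.")
    sel <- ok
  }
  stats::median(df$k2prime[sel])
}
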