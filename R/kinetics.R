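#' One-tissue-compartment parameters
#'
#' @param k1 Delivery rate constant K1 (mL cm^-3 min^-1), > 0.
#' @param k2 Efflux rate constant k2 (min^-1), > 0.
#' @return An object of class `onetc_params` with fields `k1`, `k2` and the
#'   derived volume of distribution `vt = k1/k2`.
#' @examples
#' one_tissue_params(0.3, 0.1)$vt   # 3
#' @export
one_tissue_params <- function(k1, k2) {
  check_number(k1, "k1", positive = TRUE)
  check_number(k2, "k2", positive = TRUE)
  structure(list(k1 = k1, k2 = k2, vt = k1 / k2), class = "onetc_params")
}

#' @export
print.onetc_params <- function(x, ...) {
  cat(sprintf("1TC parameters: K1 = %.4g mL/cm^3/min, k2 = %.4g 1/min, VT = %.4g\n",
              x$k1, x$k2, x$vt))
  invisible(x)
}

# conv_exp(lambda, k2, u) = int_0^u exp(-lambda s) exp(-k2 (u - s)) ds,
# written with expm1 so the lambda -> k2 limit (u exp(-k2 u)) is stable.
conv_exp <- function(lambda, k2, u) {
  a <- k2 - lambda
  ifelse(abs(a) * pmax(u, 1) < 1e-10,
         u * exp(-k2 * u),
         exp(-lambda * u) * (-expm1(-a * u)) / a)
}

# conv_ramp(lambda, k2, u) = int_0^u s exp(-lambda s) exp(-k2 (u - s)) ds.
conv_ramp <- function(lambda, k2, u) {
  a <- k2 - lambda
  small <- abs(a) * pmax(u, 1) < 1e-6
  out <- numeric(length(u))
  if (any(!small)) {
    us <- u[!small]
    out[!small] <- exp(-lambda * us) * (us / a - 1 / a^2) + exp(-k2 * us) / a^2
  }
  if (any(small)) {
    us <- u[small]
    # series of exp(-k2 u) * int_0^u s e^{a s} ds in a
    out[small] <- exp(-k2 * us) * (us^2 / 2 + a * us^3 / 3 + a^2 * us^4 / 8)
  }
  out
}

#' Simulate a one-tissue-compartment tissue curve
#'
#' Computes \eqn{C_T(t) = K_1 \int_0^t C_p(s) e^{-k_2 (t - s)} ds}. For a
#' [plasma_input()] the convolution is evaluated in closed form (the input is
#' a sum of exponential and ramp-exponential terms); for an arbitrary input
#' function a fine-grid numeric convolution (step 0.005 min) is used.
#'
#' @param params A [one_tissue_params()] object.
#' @param input A [plasma_input()] object, or a function of time (minutes).
#' @param times Times (minutes, >= 0) at which to evaluate the tissue curve.
#' @param dt Grid step for the numeric fallback, minutes.
#' @return Tissue activity at each time.
#' @examples
#' p <- one_tissue_params(0.3, 0.1)
#' simulate_1tc(p, plasma_input(), c(1, 10, 30, 60))
#' @export
simulate_1tc <- function(params, input, times, dt = 0.005) {
  if (!inherits(params, "onetc_params")) {
    if (is.list(params) && all(c("k1", "k2") %in% names(params))) {
      params <- one_tissue_params(params$k1, params$k2)
    } else {
      abort_invalid("`params` must be a `onetc_params` object.")
    }
  }
  if (any(!is.finite(times)) || any(times < 0)) abort_invalid("`times` must be finite and >= 0.")
  if (inherits(input, "plasma_input")) {
    # shift by the delay: C_p(s) = f(s - tau) for s >= tau, so for t >= tau
    # C_T(t) = K1 int_0^{t - tau} f(u) e^{-k2 (t - tau - u)} du
    u <- pmax(times - input$delay, 0)
    ct <- params$k1 * (
      input$a1 * conv_ramp(input$l1, params$k2, u) +
      input$a2 * conv_exp(input$l2, params$k2, u) +
      input$a3 * conv_exp(input$l3, params$k2, u)
    )
    return(ct)
  }
  if (is.function(input)) {
    tmax <- max(times)
    grid <- seq(0, tmax, by = dt)
    cp <- input(grid)
    if (any(!is.finite(cp))) abort_invalid("Plasma input function returned non-finite values.")
    e <- exp(-params$k2 * dt)
    # trapezoidal update of y_i = e y_{i-1} + dt/2 (cp_i + e cp_{i-1})
    b <- c(0, dt / 2 * (cp[-1] + e * cp[-length(cp)]))
    y <- stats::filter(b, e, method = "recursive")
    yi <- stats::approx(grid, as.numeric(y), xout = times, rule = 2)$y
    return(params$k1 * yi)
  }
  abort_invalid("`input` must be a `plasma_input` or a function of time.")
}

#' Average a continuous curve over acquisition frames
#'
#' Frame value = (1/frame duration) * integral of the curve over the frame,
#' computed by composite Simpson quadrature on a fine subgrid of each frame.
#'
#' @param curve A function of time (minutes), or a two-column data frame /
#'   matrix of dense `(time, value)` samples to be linearly interpolated.
#' @param schedule A frame schedule from [frame_schedule()].
#' @param region Optional region label passed to [new_tac()].
#' @param step Target quadrature step within each frame, minutes.
#' @return A time-activity curve tibble (see [new_tac()]).
#' @export
frame_average <- function(curve, schedule, region = NULL, step = 0.01) {
  validate_schedule(schedule)
  if (nrow(schedule) == 0L) abort_invalid("`schedule` must contain at least one frame.")
  f <- curve
  if (!is.function(f)) {
    m <- as.data.frame(curve)
    if (ncol(m) < 2) abort_invalid("`curve` samples must have time and value columns.")
    f <- stats::approxfun(m[[1]], m[[2]], rule = 2)
  }
  vapply(seq_len(nrow(schedule)), function(i) {
    a <- schedule$start[i]; b <- schedule$end[i]
    n <- max(8L, 2L * ceiling((b - a) / (2 * step)))
    x <- seq(a, b, length.out = n + 1L)
    y <- f(x)
    h <- (b - a) / n
    s <- h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, by = 2)]) + 2 * sum(y[seq(3, n - 1, by = 2)]))
    s / (b - a)
  }, numeric(1)) -> means
  new_tac(schedule, means, region = region)
}

#' Add frame-count noise to a time-activity curve
#'
#' Gaussian per-frame noise with variance
#' \deqn{\sigma_i^2 = \mathrm{scale}^2 \, C(t_i) \, e^{\lambda_{phys} t_i} / \Delta t_i,}
#' where \eqn{\lambda_{phys} = \ln 2 / 20.4} min^-1 is the C-11 decay
#' constant, \eqn{t_i} the frame midpoint and \eqn{\Delta t_i} the frame
#' duration: noise grows for short, late frames as counts decay, while the
#' TAC itself stays decay-corrected.
#'
#' @param tac A time-activity curve tibble (from [new_tac()] or
#'   [frame_average()]); must carry schedule columns.
#' @param scale Unitless noise scale, >= 0; 0 returns the input unchanged.
#' @param seed Integer seed; identical seeds give identical noise.
#' @return The TAC with perturbed `activity`.
#' @export
add_tac_noise <- function(tac, scale, seed) {
  validate_schedule(tac)
  if (!"activity" %in% names(tac)) abort_invalid("`tac` must have an `activity` column.")
  check_number(scale, "scale")
  if (scale < 0) abort_invalid("`scale` must be >= 0.")
  if (scale == 0) return(tac)
  v <- scale^2 * pmax(tac$activity, 0) * exp(lambda_c11 * tac$mid) / tac$dur
  eps <- with_local_seed(seed, stats::rnorm(nrow(tac), sd = sqrt(v)))
  dplyr::mutate(tac, activity = .data$activity + eps)
}

# Predicted frame-averaged activities for a parameter pair, used by fit_1tc.
predict_1tc_frames <- function(k1, k2, input, schedule, step = 0.025) {
  frame_average(function(t) simulate_1tc(one_tissue_params(k1, k2), input, t),
                schedule, step = step)$activity
}

#' Fit a one-tissue-compartment model to a TAC
#'
#' Weighted nonlinear least squares on (K1, k2), with the model evaluated as
#' frame averages on the TAC's own schedule. K1 is initialised from the
#' early-frame uptake relative to the integrated plasma input and k2 at
#' 0.05 min^-1; on failure up to three restarts from jittered starting
#' values (fixed jitter seeds) are attempted. Non-convergence is reported in
#' the returned object, not thrown, so batch fits survive bad curves.
#'
#' @param tac A time-activity curve tibble.
#' @param input A [plasma_input()] object.
#' @param weights Per-frame weights; default decay-duration weights from
#'   [frame_weights()].
#' @return An object of class `onetc_fit` with elements `k1`, `k2`, `vt`,
#'   `rss`, `converged` and `message`. Use [generics::tidy()] for a tibble.
#' @export
fit_1tc <- function(tac, input, weights = NULL) {
  validate_schedule(tac)
  if (nrow(tac) < 4L) abort_invalid("At least 4 frames are required to fit a 1TC model.")
  if (!inherits(input, "plasma_input")) abort_invalid("`input` must be a `plasma_input`.")
  if (is.null(weights)) weights <- frame_weights(tac)
  if (length(weights) != nrow(tac) || any(weights < 0)) {
    abort_invalid("`weights` must be non-negative, one per frame.")
  }

  # early-slope heuristic: K1 ~ observed early uptake over integrated plasma
  early <- which(tac$end <= max(4, tac$end[min(6, nrow(tac))]))
  tg <- seq(0, max(tac$end[early]), by = 0.01)
  cum_cp <- sum(eval_plasma(input, tg)) * 0.01
  k1_0 <- max(sum(tac$activity[early] * tac$dur[early]) / max(cum_cp * sum(tac$dur[early]) / max(tac$end[early]), 1e-9), 1e-3)
  starts <- list(c(k1 = k1_0, k2 = 0.05))
  for (j in 1:3) {
    jit <- with_local_seed(1000L + j, exp(stats::rnorm(2, sd = 0.4)))
    starts[[j + 1]] <- c(k1 = k1_0 * jit[1], k2 = 0.05 * jit[2])
  }

  df <- data.frame(y = tac$activity)
  last_err <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ predict_1tc_frames(k1, k2, input, tac),
        data = df, start = as.list(s), weights = weights,
        lower = c(1e-5, 1e-5), upper = c(10, 5),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (!inherits(fit, "error")) {
      cf <- stats::coef(fit)
      res <- tac$activity - predict_1tc_frames(cf[["k1"]], cf[["k2"]], input, tac)
      return(structure(
        list(k1 = cf[["k1"]], k2 = cf[["k2"]], vt = cf[["k1"]] / cf[["k2"]],
             rss = sum(weights * res^2), converged = TRUE, message = "converged"),
        class = "onetc_fit"
      ))
    }
    last_err <- conditionMessage(fit)
  }
  structure(
    list(k1 = NA_real_, k2 = NA_real_, vt = NA_real_, rss = NA_real_,
         converged = FALSE, message = paste("fit failed:", last_err)),
    class = "onetc_fit"
  )
}

#' @export
print.onetc_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("1TC fit: K1 = %.4g, k2 = %.4g, VT = %.4g (wRSS %.4g)\n",
                x$k1, x$k2, x$vt, x$rss))
  } else {
    cat("1TC fit: FAILED -", x$message, "\n")
  }
  invisible(x)
}

#' @rdname fit_1tc
#' @param x An `onetc_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.onetc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k1", "k2", "vt"),
    estimate = c(x$k1, x$k2, x$vt)
  )
}

#' @rdname fit_1tc
#' @exportS3Method generics::glance
glance.onetc_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged, message = x$message)
}
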