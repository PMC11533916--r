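#' Tri-exponential bolus plasma input function
#'
#' Arterial input model for a bolus injection: after a delay `delay` the
#' concentration is a linear-rise term plus two decaying exponentials,
#' \deqn{C_p(t) = A_1 u e^{-\lambda_1 u} + A_2 e^{-\lambda_2 u} + A_3 e^{-\lambda_3 u},
#'   \quad u = t - \tau,}
#' and zero before the delay. This Feng-type family is the standard
#' parameterisation for bolus PET input functions; all outcome measures in
#' this package are ratios, so the absolute scale is arbitrary.
#'
#' @param a1 Linear-rise coefficient (activity/min).
#' @param a2,a3 Exponential amplitudes (activity).
#' @param l1,l2,l3 Rate constants (1/min), required to satisfy l1 > l2 > l3 > 0.
#' @param delay Bolus arrival delay tau (min), >= 0.
#' @return An object of class `plasma_input`.
#' @examples
#' cp <- plasma_input()
#' eval_plasma(cp, c(0, 1, 10, 60))
#' @export
plasma_input <- function(a1 = 300, a2 = 20, a3 = 15,
                         l1 = 1.5, l2 = 0.12, l3 = 0.01,
                         delay = 0.5) {
  for (nm in c("a1", "a2", "a3", "l1", "l2", "l3", "delay")) {
    check_number(get(nm), nm)
  }
  if (a1 < 0 || a2 < 0 || a3 < 0) abort_invalid("Amplitudes must be >= 0.")
  if (!(l1 > l2 && l2 > l3 && l3 > 0)) {
    abort_invalid("Rate constants must satisfy l1 > l2 > l3 > 0.")
  }
  if (delay < 0) abort_invalid("`delay` must be >= 0.")
  structure(
    list(a1 = a1, a2 = a2, a3 = a3, l1 = l1, l2 = l2, l3 = l3, delay = delay),
    class = "plasma_input"
  )
}

#' @export
print.plasma_input <- function(x, ...) {
  cat("Tri-exponential bolus plasma input\n")
  cat(sprintf("  C_p(t) = %.4g u e^(-%.4g u) + %.4g e^(-%.4g u) + %.4g e^(-%.4g u), u = t - %.4g\n",
              x$a1, x$l1, x$a2, x$l2, x$a3, x$l3, x$delay))
  invisible(x)
}

#' Evaluate a plasma input function
#'
#' @param input A [plasma_input()] object.
#' @param times Times in minutes (>= 0).
#' @return Plasma activity at each time; zero before the delay.
#' @export
eval_plasma <- function(input, times) {
  if (!inherits(input, "plasma_input")) abort_invalid("`input` must be a `plasma_input`.")
  if (any(!is.finite(times)) || any(times < 0)) abort_invalid("`times` must be finite and >= 0.")
  u <- times - input$delay
  out <- numeric(length(times))
  pos <- u >= 0
  up <- u[pos]
  out[pos] <- input$a1 * up * exp(-input$l1 * up) +
    input$a2 * exp(-input$l2 * up) +
    input$a3 * exp(-input$l3 * up)
  out
}
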