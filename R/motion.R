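#' Two-step motional model of a C-H bond
#'
#' Bundles the three parameters that describe the reorientation of a C-H bond
#' vector in the two-step picture: a fast local motion with correlation time
#' `tau_c` that leaves a residual anisotropy quantified by the order parameter
#' `|S_CH|`, and a slow global process with correlation time `tau_s` that
#' modulates the residual.  `order_parameter = 0` corresponds to isotropic
#' reorientation, `1` to a fully ordered (rigid) bond.
#'
#' @param order_parameter Absolute C-H bond order parameter, in `[0, 1]`.
#' @param tau_c Fast reorientational correlation time in seconds (`> 0`).
#' @param tau_s Slow/global correlation time in seconds; must satisfy
#'   `tau_s >= tau_c` and may be `Inf` (no slow process).  Defaults to 1 s,
#'   i.e. an effectively static global environment.
#'
#' @return An object of class `motion_model`.
#' @examples
#' motion_model(0.5, tau_c = 1e-9)
#' @export
motion_model <- function(order_parameter, tau_c, tau_s = 1) {
  if (!is.numeric(order_parameter) || length(order_parameter) != 1 ||
      is.na(order_parameter) || order_parameter < 0 || order_parameter > 1) {
    pt_usage_error("`order_parameter` must be a single number in [0, 1].")
  }
  if (!is.numeric(tau_c) || length(tau_c) != 1 || is.na(tau_c) || tau_c <= 0) {
    pt_usage_error("`tau_c` must be a single positive number (seconds).")
  }
  if (!is.numeric(tau_s) || length(tau_s) != 1 || is.na(tau_s) || tau_s < tau_c) {
    pt_usage_error("`tau_s` must be a single number >= `tau_c` (seconds); Inf is allowed.")
  }
  structure(
    list(order_parameter = as.numeric(order_parameter),
         tau_c = as.numeric(tau_c), tau_s = as.numeric(tau_s)),
    class = "motion_model"
  )
}

#' @export
print.motion_model <- function(x, ...) {
  cat(sprintf("<motion_model> |S_CH| = %g, tau_c = %g s, tau_s = %g s\n",
              x$order_parameter, x$tau_c, x$tau_s))
  invisible(x)
}

#' Two-step orientational correlation function
#'
#' Evaluates
#' `C(t) = (1 - S^2) exp(-t / tau_c) + S^2 exp(-t / tau_s)`
#' with `S` the order parameter of `motion`.  `C(0) = 1` and `C` is
#' non-increasing in `t`.
#'
#' @param motion A [motion_model()].
#' @param t Time(s) in seconds, `>= 0`; vectorised.
#'
#' @return Numeric vector of correlation-function values.
#' @examples
#' m <- motion_model(0.5, 1e-9, 1e-3)
#' correlation_function(m, c(0, 1e-9, 1e-6))
#' @export
correlation_function <- function(motion, t) {
  stopifnot(inherits(motion, "motion_model"))
  if (!is.numeric(t) || any(is.na(t)) || any(t < 0)) {
    pt_usage_error("`t` must be non-negative (seconds).")
  }
  s2 <- motion$order_parameter^2
  # exp(-t/Inf) = 1 for the static slow limit
  (1 - s2) * exp(-t / motion$tau_c) + s2 * exp(-t / motion$tau_s)
}

#' Reduced spectral density of the two-step motional model
#'
#' Fourier transform of [correlation_function()] in the reduced `(2/5)`
#' convention used throughout the package (all dipolar prefactors are carried
#' by [relaxation_parameters()]):
#' `J(w) = (2/5) [ (1 - S^2) tau_c / (1 + w^2 tau_c^2) + S^2 tau_s / (1 + w^2 tau_s^2) ]`.
#' `J` is even in `w` and non-increasing in `|w|`.
#'
#' @inheritParams correlation_function
#' @param omega Angular frequency(ies), rad/s; vectorised, any sign.
#'
#' @return Numeric vector of spectral-density values (seconds).
#' @examples
#' m <- motion_model(0, 1e-9)
#' spectral_density(m, 0)      # (2/5) * tau_c
#' @export
spectral_density <- function(motion, omega) {
  stopifnot(inherits(motion, "motion_model"))
  if (!is.numeric(omega) || any(is.na(omega))) {
    pt_usage_error("`omega` must be numeric (rad/s).")
  }
  s2 <- motion$order_parameter^2
  .j_two_lorentz(1 - s2, motion$tau_c, s2, motion$tau_s, omega)
}

# Reduced two-Lorentzian spectral density with explicit amplitudes.
# Used internally so the relaxation model can apply the librational
# amplitude floor without changing the exported, exact form.
.j_two_lorentz <- function(a_fast, tau_c, a_slow, tau_s, omega) {
  slow <- if (a_slow == 0) {
    0
  } else if (is.infinite(tau_s)) {
    a_slow * ifelse(omega == 0, Inf, 0)
  } else {
    a_slow * tau_s / (1 + omega^2 * tau_s^2)
  }
  (2 / 5) * (a_fast * tau_c / (1 + omega^2 * tau_c^2) + slow)
}
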