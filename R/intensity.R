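#' Cross-polarization signal intensity
#'
#' Two-reservoir CP kinetics evaluated at the contact time:
#' `I_CP = gamma_ratio (1 - T_CH / T1rho_H)^-1 [exp(-t_CP / T1rho_H) - exp(-t_CP / T_CH)]`,
#' clipped at zero.  The degenerate case `T_CH = T1rho_H` is handled by the
#' analytic limit `gamma_ratio (t_CP / T1rho_H) exp(-t_CP / T1rho_H)`.
#'
#' @param relax A `relaxation_set` from [relaxation_parameters()].
#' @param settings An [experiment_settings()].
#' @param gamma_ratio Maximum transfer enhancement; defaults to
#'   `settings$gamma_ratio`.
#'
#' @return Single non-negative intensity on the DP = 1 scale.
#' @export
cp_intensity <- function(relax, settings, gamma_ratio = settings$gamma_ratio) {
  stopifnot(inherits(relax, "relaxation_set"), inherits(settings, "experiment_settings"))
  k <- 1 / relax$t_ch      # build-up rate; 0 when T_CH = Inf
  r <- 1 / relax$t1rho_h   # rotating-frame loss rate
  t <- settings$t_cp
  if (k == 0) return(0)
  amp <- if (abs(k - r) < 1e-9 * max(k, r)) {
    r * t * exp(-r * t)
  } else {
    k / (k - r) * (exp(-r * t) - exp(-k * t))
  }
  max(0, gamma_ratio * amp)
}

#' Refocused-INEPT signal intensity
#'
#' Product formula for the refocused INEPT amplitude of a C-Hn segment:
#' `I = gamma_ratio sin(pi J tau2) Fn(pi J tau2') exp(-tau2 / T2_H) exp(-tau2' / T2_C)`
#' with `tau2 = 2 tau`, `tau2' = 2 tau'` and the multiplicity refocusing
#' factor `F1 = sin`, `F2 = sin cos`, `F3 = sin cos^2`.  Negative amplitudes
#' (mis-set delays) are clipped to zero.
#'
#' @inheritParams cp_intensity
#' @param segment A [spin_segment()] supplying multiplicity and `J_CH`.
#'
#' @return Single non-negative intensity on the DP = 1 scale.
#' @export
inept_intensity <- function(relax, segment, settings,
                            gamma_ratio = settings$gamma_ratio) {
  stopifnot(inherits(relax, "relaxation_set"), inherits(segment, "spin_segment"),
            inherits(settings, "experiment_settings"))
  tau2 <- 2 * settings$inept_tau
  tau2p <- 2 * settings$inept_tau_prime
  th <- pi * segment$j_ch * tau2
  thp <- pi * segment$j_ch * tau2p
  fn <- switch(segment$multiplicity,
               sin(thp),
               sin(thp) * cos(thp),
               sin(thp) * cos(thp)^2)
  amp <- sin(th) * fn * exp(-tau2 / relax$t2_h) * exp(-tau2p / relax$t2_c)
  max(0, gamma_ratio * amp)
}

#' Direct-polarization signal intensity
#'
#' The DP amplitude is the unit reference against which CP and INEPT
#' enhancements are expressed.  Optionally, a visibility factor
#' `exp(-t_dead / T2_C)` models signal lost during the receiver dead time for
#' extremely fast-relaxing carbons; it is off by default.
#'
#' @inheritParams cp_intensity
#' @param visibility Apply the dead-time visibility attenuation?
#' @param t_dead Receiver dead time in seconds (used when
#'   `visibility = TRUE`).
#'
#' @return Intensity in `(0, 1]`.
#' @export
dp_intensity <- function(relax, visibility = FALSE, t_dead = 30e-6) {
  stopifnot(inherits(relax, "relaxation_set"))
  if (!visibility) return(1.0)
  exp(-t_dead / relax$t2_c)
}

#' DP/CP/INEPT efficiency triplet of one segment
#'
#' Composes [relaxation_parameters()], [dp_intensity()], [cp_intensity()] and
#' [inept_intensity()] into the normalized intensity triplet that is the unit
#' of dynamic-state classification.
#'
#' @inheritParams relaxation_parameters
#' @param visibility Passed to [dp_intensity()].
#'
#' @return One-row tibble with columns `i_dp`, `i_cp`, `i_inept` plus the
#'   motional parameters used.
#' @examples
#' efficiency_triplet(motion_model(0.005, 2e-9), spin_segment(2),
#'                    experiment_settings())
#' @export
efficiency_triplet <- function(motion, segment, settings, visibility = FALSE) {
  relax <- relaxation_parameters(motion, segment, settings)
  tibble(
    order_parameter = motion$order_parameter,
    tau_c = motion$tau_c,
    tau_s = motion$tau_s,
    i_dp = dp_intensity(relax, visibility = visibility),
    i_cp = cp_intensity(relax, settings),
    i_inept = inept_intensity(relax, segment, settings)
  )
}

#' Transfer-efficiency map over correlation time and order parameter
#'
#' Evaluates [efficiency_triplet()] on the outer grid of `tau_grid` by
#' `s_grid`, producing the long-format table behind the familiar red/blue
#' (INEPT/CP) regime map.  Rows are ordered with `tau_c` varying fastest
#' within each `order_parameter`.
#'
#' @param tau_grid Correlation times in seconds, within `[1e-12, 1]`.
#'   Defaults to a log10 grid over that full range.
#' @param s_grid Order parameters, within `[1e-3, 1]`; defaults to a log10
#'   grid over that range.
#' @inheritParams relaxation_parameters
#' @param tau_s Slow correlation time shared by all grid points.
#'
#' @return A tibble of class `efficiency_map` with columns
#'   `order_parameter`, `tau_c`, `i_dp`, `i_cp`, `i_inept`.
#' @examples
#' m <- efficiency_map(tau_grid = 10^seq(-12, 0, length.out = 13),
#'                     s_grid = 10^seq(-3, 0, length.out = 7))
#' @export
efficiency_map <- function(tau_grid = 10^seq(-12, 0, length.out = 49),
                           s_grid = 10^seq(-3, 0, length.out = 25),
                           segment = spin_segment(2),
                           settings = experiment_settings(),
                           tau_s = 1) {
  if (length(tau_grid) == 0 || length(s_grid) == 0) {
    pt_usage_error("`tau_grid` and `s_grid` must be non-empty.")
  }
  if (any(tau_grid < 1e-12 | tau_grid > 1)) {
    pt_usage_error("`tau_grid` values must lie in [1e-12, 1] s.")
  }
  if (any(s_grid < 1e-3 | s_grid > 1)) {
    pt_usage_error("`s_grid` values must lie in [1e-3, 1].")
  }
  grid <- tidyr::expand_grid(order_parameter = s_grid, tau_c = tau_grid)
  trip <- purrr::pmap_dfr(grid, function(order_parameter, tau_c) {
    efficiency_triplet(
      motion_model(order_parameter, tau_c, tau_s = max(tau_s, tau_c)),
      segment, settings
    )[, c("i_dp", "i_cp", "i_inept")]
  })
  out <- dplyr::bind_cols(grid, trip)
  class(out) <- c("efficiency_map", class(out))
  attr(out, "settings") <- settings
  attr(out, "segment") <- segment
  out
}

#' Classify the dynamic regime of an intensity triplet
#'
#' Thresholded reading of a DP/CP/INEPT triplet: INEPT-only gives
#' `mobile_isotropic`, CP-only `rigid_slow`, comparable CP and INEPT
#' `mobile_anisotropic`, neither (with DP present) `intermediate`, and an
#' all-zero triplet `ambiguous`.  "Present" means exceeding `frac` of the
#' per-scheme maximum (`cp_max`, `inept_max`, by default the theoretical
#' enhancement bound); "comparable" means the raw CP/INEPT ratio falls inside
#' `comparable_band`, mirroring the visual criterion of identical line shapes
#' with comparable amplitudes.
#'
#' @param i_dp,i_cp,i_inept Intensity triplet (vectorised).
#' @param frac Presence threshold as a fraction of the per-scheme maximum.
#' @param cp_max,inept_max,dp_max Per-scheme maxima used for the presence
#'   test.
#' @param comparable_band Length-2 numeric; CP/INEPT ratio band read as
#'   "comparable amplitudes".
#' @param gamma_ratio Default scale for `cp_max` and `inept_max`.
#'
#' @return Character vector of regime labels.
#' @examples
#' classify_regime(1, 0, 3.5)    # mobile_isotropic
#' classify_regime(1, 1.8, 1.7)  # mobile_anisotropic
#' classify_regime(1, 3.6, 0)    # rigid_slow
#' @export
classify_regime <- function(i_dp, i_cp, i_inept, frac = 0.05,
                            gamma_ratio = 4,
                            cp_max = gamma_ratio, inept_max = gamma_ratio,
                            dp_max = 1,
                            comparable_band = c(0.5, 2)) {
  n <- max(length(i_dp), length(i_cp), length(i_inept))
  i_dp <- rep_len(pmax(i_dp, 0), n)
  i_cp <- rep_len(pmax(i_cp, 0), n)
  i_inept <- rep_len(pmax(i_inept, 0), n)
  cp_sig <- i_cp >= frac * cp_max
  in_sig <- i_inept >= frac * inept_max
  dp_sig <- i_dp >= frac * dp_max
  ratio <- ifelse(i_inept > 0, i_cp / i_inept, Inf)
  out <- rep("ambiguous", n)
  out[dp_sig & !cp_sig & !in_sig] <- "intermediate"
  out[in_sig & !cp_sig] <- "mobile_isotropic"
  out[cp_sig & !in_sig] <- "rigid_slow"
  both <- cp_sig & in_sig
  out[both & ratio >= comparable_band[1] & ratio <= comparable_band[2]] <-
    "mobile_anisotropic"
  out[both & ratio > comparable_band[2]] <- "rigid_slow"
  out[both & ratio < comparable_band[1]] <- "mobile_isotropic"
  out
}
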