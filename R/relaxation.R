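#' Relaxation and polarization-transfer parameters of a segment
#'
#' Computes the four time constants that govern polarization transfer for one
#' C-Hn segment under magic-angle spinning: the transverse relaxation times
#' `t2_h` and `t2_c`, the rotating-frame proton relaxation time `t1rho_h`,
#' and the CP build-up time constant `t_ch`.
#'
#' Rates are built from the heteronuclear dipolar coupling
#' `d_CH = (mu0/4pi) gamma_H gamma_C hbar / r_CH^3` and the geminal/bath
#' homonuclear coupling `d_HH`, with spectral densities of the two-step
#' motional model.  Under MAS the secular (zero-frequency) contributions are
#' replaced by the average of `J(omega_R)` and `J(2 omega_R)`; `t1rho_h` uses
#' the spectral density at the 1H spin-lock nutation frequency (ramp
#' midpoint) split over the `+/- omega_R` MAS sidebands; `t_ch` follows the
#' residual-coupling Hartmann-Hahn picture with the ramp sweeping the
#' `n = +/-1` sideband condition, `1/T_CH = (n_H/2) S^2 / T_CH0` with
#' `T_CH0` the rigid-limit CH2 build-up time.  A quasi-static coherent
#' dephasing term `zeta S^2 d_HH^2 / omega_R` accounts for the MAS-residual
#' proton-proton coupling, and a small librational amplitude floor keeps a
#' fast motional component even at `|S_CH| = 1` (see the methods vignette for
#' the closure constants).
#'
#' @param motion A [motion_model()].
#' @param segment A [spin_segment()].
#' @param settings An [experiment_settings()].
#'
#' @return A one-row tibble of class `relaxation_set` with columns `t2_h`,
#'   `t2_c`, `t1rho_h`, `t_ch` (seconds; `t_ch` is `Inf` for a vanishing
#'   order parameter).
#' @examples
#' relaxation_parameters(motion_model(0.9, 1e-9), spin_segment(2),
#'                       experiment_settings())
#' @export
relaxation_parameters <- function(motion, segment, settings) {
  stopifnot(inherits(motion, "motion_model"))
  if (!inherits(segment, "spin_segment")) {
    abort("`segment` must be a spin_segment.",
          class = c("ptnmr_config_error", "ptnmr_error"))
  }
  stopifnot(inherits(settings, "experiment_settings"))

  n <- segment$multiplicity
  s2 <- motion$order_parameter^2
  # librational floor: rigid segments keep a small fast component
  a_fast <- max(1 - s2, .pt$a_lib)
  a_slow <- 1 - a_fast

  r_ch <- segment$r_ch * 1e-10
  d_ch <- .pt$mu0_4pi * .pt$gamma_h * .pt$gamma_c * .pt$hbar / r_ch^3
  d_hh <- .pt$mu0_4pi * .pt$gamma_h^2 * .pt$hbar / .pt$r_hh^3

  w_h <- 2 * pi * settings$larmor_h
  w_c <- 2 * pi * settings$larmor_c
  w_r <- 2 * pi * settings$mas_rate
  w_1h <- 2 * pi * (settings$nut_h_start + settings$nut_h_end) / 2

  jf <- function(w) .j_two_lorentz(a_fast, motion$tau_c, a_slow, motion$tau_s, w)
  j_mas0 <- (jf(w_r) + jf(2 * w_r)) / 2

  # 13C transverse relaxation (heteronuclear dipolar, n attached protons)
  r2_c <- (n * d_ch^2 / 8) *
    (4 * j_mas0 + jf(w_h - w_c) + 3 * jf(w_c) + 6 * jf(w_h) + 6 * jf(w_h + w_c))

  # 1H transverse relaxation: homonuclear Redfield terms with MAS-averaged
  # secular part, plus the coherent MAS-residual dephasing of the quasi-static
  # residual coupling (scales with S^2, inversely with the spinning rate)
  r2_h_bpp <- .pt$z_hh * (3 / 8) * d_hh^2 *
    (3 * j_mas0 + 5 * jf(w_h) + 2 * jf(2 * w_h))
  r2_h_coh <- .pt$zeta_mas * s2 * d_hh^2 / w_r
  r2_h <- r2_h_bpp + r2_h_coh

  # 1H rotating-frame relaxation; spin-lock term split over the +/- omega_R
  # sidebands of the ramp-midpoint nutation frequency
  j_sl <- (jf(abs(w_1h - w_r)) + jf(w_1h + w_r)) / 2
  r1rho_h <- .pt$z_hh * (3 / 8) * d_hh^2 *
    (2 * j_sl + 5 * jf(w_h) + 2 * jf(2 * w_h))

  # CP build-up via the residual heteronuclear coupling at the n = +/-1
  # Hartmann-Hahn sideband; per-proton rates add
  r_cp <- (n / 2) * s2 / .pt$t_ch0 * (d_ch / .d_ch_ref())^2

  new_tibble(
    list(t2_h = 1 / r2_h, t2_c = 1 / r2_c,
         t1rho_h = 1 / r1rho_h, t_ch = 1 / r_cp),
    nrow = 1L, class = "relaxation_set"
  )
}

# reference CH dipolar coupling at r = 1.09 A, so t_ch0 is quoted for a
# standard methylene geometry
.d_ch_ref <- function() {
  .pt$mu0_4pi * .pt$gamma_h * .pt$gamma_c * .pt$hbar / (1.09e-10)^3
}
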