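# Shared fixtures and independent numerical oracles.

default_settings <- experiment_settings()
ch2 <- spin_segment(2)

# Composite-Simpson cosine transform of the two-step correlation function:
# an independent quadrature route to the spectral density.
j_quadrature <- function(S, tau_c, tau_s, omega) {
  piece <- function(a, tau) {
    if (a == 0 || is.infinite(tau)) return(0)
    tmax <- 45 * tau
    h <- min(tau, 1 / max(abs(omega), 1 / tau)) / 30
    n <- ceiling(tmax / h)
    if (n %% 2 == 1) n <- n + 1
    t <- seq(0, tmax, length.out = n + 1)
    f <- exp(-t / tau) * cos(omega * t)
    w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
    a * sum(w * f) * (t[2] - t[1]) / 3
  }
  (2 / 5) * (piece(1 - S^2, tau_c) + piece(S^2, tau_s))
}

# Lorentzian area for measure_peak checks: integral of A * hw^2 / ((x-x0)^2 + hw^2)
lorentz_area <- function(A, hw) A * hw * pi

make_lorentz_spectrum <- function(ppm_axis, x0, A, hw_ppm, offset = 0) {
  y <- A * hw_ppm^2 / ((ppm_axis - x0)^2 + hw_ppm^2) + offset
  sp <- tibble::new_tibble(
    list(ppm = ppm_axis, re = y, im = rep(0, length(y)), intensity = y),
    nrow = length(y), class = "nmr_spectrum")
  attr(sp, "scheme") <- "DP"
  sp
}

descending_axis <- function(from = 230, to = -10, n = 4096) {
  seq(from, to, length.out = n)
}

triplet_from_intensities <- function(ppm, dp, cp, inept, sample_state = NULL) {
  mk <- function(y, scheme) {
    sp <- tibble::new_tibble(
      list(ppm = ppm, re = y, im = rep(0, length(y)), intensity = y),
      nrow = length(ppm), class = "nmr_spectrum")
    attr(sp, "scheme") <- scheme
    sp
  }
  spectrum_triplet(mk(dp, "DP"), mk(cp, "CP"), mk(inept, "INEPT"),
                   sample_state = sample_state)
}
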