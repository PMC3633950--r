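# Saturated-salt humidity control: NaCl molality vs. equilibrium RH pairs
# used to condition the samples (32 C).
.rh_nacl <- data.frame(
  molality = c(5.12, 4.02, 2.81, 2.02, 1.19, 0.156),
  rh = c(80.0, 85.0, 90.0, 93.0, 96.0, 99.5)
)

# gravimetric water contents reported for the conditioned samples
.rh_water <- data.frame(
  rh = c(0, 80, 85, 90, 93, 96),
  wt = c(0, 24, 30, 37, 46, 50)
)

#' Relative humidity regulated by a NaCl solution
#'
#' Monotone interpolation of the tabulated NaCl molality / equilibrium RH
#' pairs (5.12, 4.02, 2.81, 2.02, 1.19, 0.156 mol/kg giving 80.0, 85.0,
#' 90.0, 93.0, 96.0, 99.5 % RH).  Values outside the tabulated molality
#' range are refused rather than extrapolated.
#'
#' @param molality NaCl molality in mol/kg; vectorised.
#' @return RH in percent.
#' @examples
#' rh_for_nacl_molality(5.12)   # 80
#' rh_for_nacl_molality(0.156)  # 99.5
#' @export
rh_for_nacl_molality <- function(molality) {
  if (!is.numeric(molality) || any(is.na(molality))) {
    pt_usage_error("`molality` must be numeric (mol/kg).")
  }
  rng <- range(.rh_nacl$molality)
  if (any(molality < rng[1] | molality > rng[2])) {
    pt_usage_error(sprintf(
      "Molality outside the tabulated range [%g, %g] mol/kg; extrapolation refused.",
      rng[1], rng[2]))
  }
  approx(.rh_nacl$molality, .rh_nacl$rh, xout = molality, method = "linear")$y
}

#' Gravimetric water content
#'
#' `(m_humid - m_dry) / m_humid`: the water weight fraction of a humidified
#' sample relative to its hydrated mass.
#'
#' @param m_dry Dry mass.
#' @param m_humid Humidified mass; must satisfy `m_humid >= m_dry > 0`.
#' @return Water weight fraction in `[0, 1)`.
#' @examples
#' water_content(70, 100)  # 0.30
#' @export
water_content <- function(m_dry, m_humid) {
  if (any(m_dry <= 0) || any(m_humid < m_dry)) {
    pt_usage_error("Masses must satisfy m_humid >= m_dry > 0.")
  }
  (m_humid - m_dry) / m_humid
}

#' Approximate water content at a given RH
#'
#' Interpolates the reported RH / water-weight-percent pairs (80 -> 24,
#' 85 -> 30, 90 -> 37, 93 -> 46, 96 -> 50 wt%) for sample-state metadata.
#'
#' @param rh_percent RH in percent (0-100); `"dry"` maps to 0.
#' @return Water content in weight percent.
#' @export
rh_water_content <- function(rh_percent) {
  rh <- .parse_rh(rh_percent)
  approx(.rh_water$rh, .rh_water$wt, xout = rh, method = "linear", rule = 2)$y
}

.parse_rh <- function(rh_percent) {
  if (is.character(rh_percent)) {
    if (!all(rh_percent == "dry")) pt_usage_error("Character RH must be \"dry\".")
    return(rep(0, length(rh_percent)))
  }
  if (!is.numeric(rh_percent) || any(rh_percent < 0 | rh_percent > 100)) {
    pt_usage_error("`rh_percent` must lie in [0, 100] (or be \"dry\").")
  }
  rh_percent
}

# run code with a temporary, restored RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic stratum-corneum component specification
#'
#' Builds the per-segment table (spin parameters, motional parameters,
#' abundances) of an SC-like sample at a given hydration and temperature,
#' encoding the qualitative hydration/heating narrative: a rigid all-trans
#' lipid pool that melts on heating (gone by 60 C at high hydration), a
#' mobile isotropic lipid pool growing with hydration and temperature, a
#' keratin core that stays rigid under all conditions, keratin terminal
#' domains that switch abruptly from rigid to mobile between 80 and 85 % RH
#' and keep gaining amplitude on further hydration, and mobile cholesterol
#' lines visible only in the narrow hydration window around 85 % RH.
#' Abundances per state are package defaults (documented in the methods
#' vignette); the underlying study is qualitative on this point.
#'
#' @param rh_percent Relative humidity in percent, or `"dry"`.
#' @param temperature_c Sample temperature in Celsius.
#' @param seed Integer seed; identical (state, seed) give identical specs.
#'   The seed drives only a small reproducible jitter on abundances and
#'   correlation times.
#' @param jitter Relative jitter amplitude (0 disables).
#'
#' @return Tibble of class `component_spec` with one row per simulated
#'   segment: `label`, `group`, `shift_ppm`, `multiplicity`, `j_ch`,
#'   `order_parameter`, `tau_c`, `tau_s`, `abundance`, `extra_lw_hz`, and
#'   the ground-truth `dynamic_state` of each segment under the default
#'   experiment settings.  Attributes record the sample state.
#' @examples
#' sc_sample(80, 32)
#' sc_sample(96, 60)
#' @export
sc_sample <- function(rh_percent, temperature_c = 32, seed = 1, jitter = 0.02) {
  rh <- .parse_rh(rh_percent)
  if (!is.numeric(temperature_c) || length(temperature_c) != 1) {
    pt_usage_error("`temperature_c` must be a single number.")
  }

  s_rigid <- 0.92
  s_iso <- 0.005
  tau_rigid <- 2e-9
  # fluid-lipid dynamics speeds up with temperature
  tau_mobile <- 2e-9 / (1 + (temperature_c - 32) / 40)

  # hydration scaling of the mobile-lipid pool (gradual, nonzero when dry)
  lip_scale <- approx(c(0, 80, 85, 90, 93, 96, 100),
                      c(0.15, 0.25, 0.45, 0.65, 0.85, 1.0, 1.0),
                      xout = rh, rule = 2)$y
  lip_scale <- lip_scale * (1 + 0.3 * pmax(0, temperature_c - 32) / 28)

  # melt fraction of the all-trans pool: weak below 42 C, complete at 60 C
  # for well-hydrated samples; a small solid pool survives at low hydration
  melt <- approx(c(20, 32, 42, 60), c(0.1, 0.2, 0.5, 1.0),
                 xout = temperature_c, rule = 2)$y
  if (temperature_c >= 55 && rh < 90) melt <- min(melt, 0.9)
  solid_lipid <- 2.0 * (1 - melt)

  # keratin terminals: abrupt rigid->mobile switch between RH 80 and 85
  f_term <- approx(c(0, 80, 84.99, 85, 90, 93, 96, 100),
                   c(0, 0, 0, 0.55, 0.7, 0.85, 1.0, 1.0),
                   xout = rh, rule = 2)$y

  seg <- function(label, group, shift, mult, S, tau_c, ab, lw, j = 139) {
    tibble(label = label, group = group, shift_ppm = shift,
           multiplicity = as.integer(mult), j_ch = j,
           order_parameter = S, tau_c = tau_c, tau_s = 1,
           abundance = ab, extra_lw_hz = lw)
  }

  rows <- list(
    # keratin filament core: rigid under all conditions
    seg("Leu C_beta / Lys C_epsilon", "keratin_core", 40.6, 2,
        s_rigid, tau_rigid, 3.0, 70),
    seg("keratin C_alpha region", "keratin_core", 57.35, 1,
        s_rigid, tau_rigid, 4.0, 160),
    # terminal domains: rigid pool at the terminal shifts below the switch,
    # mobile isotropic pool above it
    seg("Gly C_alpha", "keratin_terminal", 43.7, 2,
        if (f_term > 0) s_iso else s_rigid,
        if (f_term > 0) tau_mobile else tau_rigid,
        2.0 * max(f_term, 0.9 * (f_term == 0)), if (f_term > 0) 8 else 70),
    seg("Ser C_alpha", "keratin_terminal", 56.7, 1,
        if (f_term > 0) s_iso else s_rigid,
        if (f_term > 0) tau_mobile else tau_rigid,
        1.2 * max(f_term, 0.9 * (f_term == 0)), if (f_term > 0) 8 else 70),
    seg("Ser C_beta", "keratin_terminal", 62.4, 2,
        if (f_term > 0) s_iso else s_rigid,
        if (f_term > 0) tau_mobile else tau_rigid,
        1.5 * max(f_term, 0.9 * (f_term == 0)), if (f_term > 0) 8 else 70),
    # lipids: rigid all-trans pool + mobile trans/gauche pool
    if (solid_lipid > 0.02)
      seg("(CH2)n all-trans", "lipid_solid", 33.4, 2,
          0.95, tau_rigid, solid_lipid, 30),
    seg("(CH2)n trans/gauche", "lipid_mobile", 30.5, 2,
        s_iso, tau_mobile, 1.0 * lip_scale, 6),
    seg("(omega-1) CH2", "lipid_mobile", 23.3, 2,
        s_iso, tau_mobile * 0.6, 0.4 * lip_scale, 5),
    seg("omega CH3", "lipid_mobile", 14.6, 3,
        s_iso, tau_mobile * 0.4, 0.4 * lip_scale, 5)
  )
  # mobile cholesterol only in the narrow window around RH = 85
  if (abs(rh - 85) <= 2.5 && temperature_c < 55) {
    chol <- list(
      seg("cholesterol C24/C12", "cholesterol", 40.65, 2, s_iso, 5e-9, 0.15, 8),
      seg("cholesterol C4", "cholesterol", 42.8, 2, s_iso, 5e-9, 0.15, 8),
      seg("cholesterol C9", "cholesterol", 51.8, 1, s_iso, 5e-9, 0.12, 8),
      seg("cholesterol C14/C17", "cholesterol", 57.6, 1, s_iso, 5e-9, 0.2, 8)
    )
    rows <- c(rows, chol)
  }
  out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])

  if (jitter > 0) {
    out <- with_seed(seed, {
      out$abundance <- out$abundance * (1 + jitter * stats::rnorm(nrow(out)))
      out$tau_c <- out$tau_c * (1 + jitter * stats::rnorm(nrow(out)))
      out
    })
    out$abundance <- pmax(out$abundance, 0)
  }

  # ground-truth regime of every segment under the default settings
  st <- experiment_settings()
  out$dynamic_state <- vapply(seq_len(nrow(out)), function(i) {
    tr <- efficiency_triplet(
      motion_model(out$order_parameter[i], out$tau_c[i], out$tau_s[i]),
      spin_segment(out$multiplicity[i], j_ch = out$j_ch[i],
                   shift_ppm = out$shift_ppm[i]),
      st)
    classify_regime(tr$i_dp, tr$i_cp, tr$i_inept,
                    gamma_ratio = st$gamma_ratio)
  }, character(1))

  class(out) <- c("component_spec", class(out))
  attr(out, "sample_state") <- list(rh_percent = rh,
                                    water_wt_percent = rh_water_content(rh),
                                    temperature_c = temperature_c,
                                    seed = seed)
  out
}

#' Simulate one FID of a component specification
#'
#' Each segment contributes an exponentially decaying complex sinusoid at
#' its chemical shift.  The decay rate is `pi * linewidth` with the
#' linewidth the sum of the motional contribution `1 / (pi * T2_C)` and the
#' segment's static `extra_lw_hz`; the amplitude is abundance times the
#' segment's transfer efficiency for the requested scheme, so a DP FID is
#' exactly linear in abundance.  Circular Gaussian noise of standard
#' deviation `noise_sigma` (per real/imaginary point) is added under `seed`.
#'
#' @param spec A [sc_sample()] / `component_spec` table.
#' @param scheme `"DP"`, `"CP"` or `"INEPT"`.
#' @param settings [experiment_settings()].
#' @param noise_sigma Time-domain noise standard deviation.
#' @param seed Integer noise seed (required whenever `noise_sigma > 0`).
#' @param n_points,sw_hz Acquisition grid (defaults: 1597 points, 31.94 kHz
#'   spectral width, i.e. a 50 ms acquisition time).
#' @param carrier_ppm Axis centre.
#'
#' @return An `nmr_fid`.
#' @export
simulate_fid <- function(spec, scheme = c("DP", "CP", "INEPT"),
                         settings = experiment_settings(),
                         noise_sigma = 0, seed = 1,
                         n_points = 1597, sw_hz = 31940, carrier_ppm = 110) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(spec))
  dwell <- 1 / sw_hz
  t <- (seq_len(n_points) - 1) * dwell
  x <- complex(real = rep(0, n_points))
  for (i in seq_len(nrow(spec))) {
    seg <- spin_segment(spec$multiplicity[i], j_ch = spec$j_ch[i],
                        shift_ppm = spec$shift_ppm[i], label = spec$label[i])
    mot <- motion_model(spec$order_parameter[i], spec$tau_c[i], spec$tau_s[i])
    relax <- relaxation_parameters(mot, seg, settings)
    amp <- spec$abundance[i] * switch(scheme,
      DP = dp_intensity(relax),
      CP = cp_intensity(relax, settings),
      INEPT = inept_intensity(relax, seg, settings))
    if (amp <= 0) next
    lw <- 1 / (pi * relax$t2_c) + spec$extra_lw_hz[i]
    f <- (spec$shift_ppm[i] - carrier_ppm) * settings$larmor_c * 1e-6
    x <- x + amp * exp((2i * pi * f - pi * lw) * t)
  }
  if (noise_sigma > 0) {
    x <- x + with_seed(seed, complex(real = stats::rnorm(n_points, 0, noise_sigma),
                                     imaginary = stats::rnorm(n_points, 0, noise_sigma)))
  }
  new_fid(x, dwell_time = dwell, scheme = scheme,
          larmor_c = settings$larmor_c, carrier_ppm = carrier_ppm)
}

#' Simulate and process a DP/CP/INEPT spectrum triplet
#'
#' Convenience wrapper running [simulate_fid()] and [process_fid()] for the
#' three schemes of one sample and assembling a [spectrum_triplet()].
#'
#' @inheritParams simulate_fid
#' @param snr Target spectral signal-to-noise ratio of the DP spectrum
#'   (peak height over noise standard deviation); `Inf` for noiseless.
#' @param phase,baseline Passed to [process_fid()].
#' @return A `spectrum_triplet`.
#' @export
simulate_triplet <- function(spec, settings = experiment_settings(),
                             snr = Inf, seed = 1,
                             phase = "none", baseline = TRUE) {
  sigma <- if (is.finite(snr)) noise_sigma_for_snr(spec, snr, settings) else 0
  sps <- lapply(c(DP = "DP", CP = "CP", INEPT = "INEPT"), function(sch) {
    fid <- simulate_fid(spec, sch, settings, noise_sigma = sigma,
                        seed = seed + match(sch, c("DP", "CP", "INEPT")))
    process_fid(fid, phase = phase, baseline = baseline)
  })
  spectrum_triplet(sps$DP, sps$CP, sps$INEPT,
                   sample_state = attr(spec, "sample_state"))
}

#' Time-domain noise level for a target DP spectral SNR
#'
#' Computes the time-domain standard deviation for which the processed DP
#' spectrum of `spec` has `max(height) / sd(noise) = snr`, accounting for
#' the apodization window applied during processing.
#'
#' @inheritParams simulate_triplet
#' @param lb_hz Line broadening assumed for processing.
#' @param snr Target signal-to-noise ratio.
#' @return Noise standard deviation per (real or imaginary) point.
#' @export
noise_sigma_for_snr <- function(spec, snr, settings = experiment_settings(),
                                lb_hz = 10) {
  fid <- simulate_fid(spec, "DP", settings, noise_sigma = 0)
  sp <- process_fid(fid, lb_hz = lb_hz, phase = "none", baseline = FALSE)
  peak <- max(sp$intensity)
  w <- exp(-pi * lb_hz * fid$t)
  # Var(Re FFT) = sigma^2 * sum(w^2) for circular complex noise
  peak / (snr * sqrt(sum(w^2)))
}
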