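#' One C-Hn spin segment
#'
#' Describes a single carbon-bearing moiety: the number of directly bonded
#' protons, its one-bond scalar coupling, C-H distance, isotropic chemical
#' shift and a free-text label.  The defaults (`j_ch = 139` Hz, so that the
#' 1.8 ms INEPT delay is close to `1/(4 J)`, and `r_ch = 1.09` angstrom) are
#' typical for aliphatic carbons.
#'
#' @param multiplicity Number of directly bonded 1H; one of 1, 2, 3.
#' @param j_ch One-bond scalar coupling in Hz, within `[100, 250]`.
#' @param r_ch C-H internuclear distance in angstrom, within `[1.0, 1.2]`.
#' @param shift_ppm Isotropic 13C chemical shift (ppm); may be `NA` for
#'   intensity-only calculations.
#' @param label Free-text segment label.
#'
#' @return An object of class `spin_segment`.
#' @examples
#' spin_segment(2, shift_ppm = 30.5, label = "(CH2)n trans/gauche")
#' @export
spin_segment <- function(multiplicity, j_ch = 139, r_ch = 1.09,
                         shift_ppm = NA_real_, label = "") {
  if (!is.numeric(multiplicity) || length(multiplicity) != 1 ||
      !multiplicity %in% c(1, 2, 3)) {
    pt_usage_error("`multiplicity` must be 1, 2 or 3.")
  }
  if (!is.numeric(j_ch) || length(j_ch) != 1 || j_ch < 100 || j_ch > 250) {
    pt_usage_error("`j_ch` must be a single value in [100, 250] Hz.")
  }
  if (!is.numeric(r_ch) || length(r_ch) != 1 || r_ch < 1.0 || r_ch > 1.2) {
    pt_usage_error("`r_ch` must be a single value in [1.0, 1.2] angstrom.")
  }
  structure(
    list(multiplicity = as.integer(multiplicity), j_ch = as.numeric(j_ch),
         r_ch = as.numeric(r_ch), shift_ppm = as.numeric(shift_ppm),
         label = as.character(label)),
    class = "spin_segment"
  )
}

#' @export
print.spin_segment <- function(x, ...) {
  cat(sprintf("<spin_segment> C-H%d, J = %g Hz, r = %g A, shift = %g ppm%s\n",
              x$multiplicity, x$j_ch, x$r_ch, x$shift_ppm,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}

#' Acquisition and pulse-sequence settings
#'
#' Houses every acquisition symbol of the experiment: static field, Larmor
#' frequencies, MAS rate, CP contact time and ramp, 13C nutation frequency,
#' and the refocused-INEPT delays.  The defaults reproduce a 11.74 T
#' instrument with 5 kHz MAS, 1 ms ramped CP (1H nutation 72-88 kHz, 13C
#' 80 kHz) and INEPT delays tau = 1.8 ms, tau' = 1.2 ms.
#'
#' @param b0 Static magnetic field, tesla.
#' @param larmor_c,larmor_h 13C and 1H resonance frequencies, Hz.
#' @param mas_rate MAS frequency `omega_R / 2 pi`, Hz.
#' @param t_cp CP contact time, seconds.
#' @param nut_c 13C nutation frequency `omega_1C / 2 pi`, Hz.
#' @param nut_h_start,nut_h_end Endpoints of the linear 1H nutation ramp
#'   `omega_1H / 2 pi`, Hz.
#' @param inept_tau,inept_tau_prime INEPT delays tau and tau', seconds.
#'
#' @return An object of class `experiment_settings`.  The derived element
#'   `gamma_ratio` is `larmor_h / larmor_c`, the theoretical maximum signal
#'   enhancement of a full 1H to 13C polarization transfer.
#' @examples
#' experiment_settings()
#' experiment_settings(mas_rate = 10e3)
#' @export
experiment_settings <- function(b0 = 11.74,
                                larmor_c = 125e6, larmor_h = 500e6,
                                mas_rate = 5000,
                                t_cp = 1e-3,
                                nut_c = 80e3,
                                nut_h_start = 72e3, nut_h_end = 88e3,
                                inept_tau = 1.8e-3, inept_tau_prime = 1.2e-3) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
      pt_usage_error(sprintf("`%s` must be a single positive number.", nm))
    }
    as.numeric(x)
  }
  out <- list(
    b0 = num1(b0, "b0"),
    larmor_c = num1(larmor_c, "larmor_c"),
    larmor_h = num1(larmor_h, "larmor_h"),
    mas_rate = num1(mas_rate, "mas_rate"),
    t_cp = num1(t_cp, "t_cp"),
    nut_c = num1(nut_c, "nut_c"),
    nut_h_start = num1(nut_h_start, "nut_h_start"),
    nut_h_end = num1(nut_h_end, "nut_h_end"),
    inept_tau = num1(inept_tau, "inept_tau"),
    inept_tau_prime = num1(inept_tau_prime, "inept_tau_prime")
  )
  if (out$nut_h_start > out$nut_h_end) {
    pt_usage_error("`nut_h_start` must not exceed `nut_h_end`.")
  }
  out$gamma_ratio <- out$larmor_h / out$larmor_c
  structure(out, class = "experiment_settings")
}

#' @export
print.experiment_settings <- function(x, ...) {
  cat(sprintf(
    paste0("<experiment_settings> B0 = %g T (13C %g MHz), MAS %g kHz, ",
           "t_CP = %g ms, 1H ramp %g-%g kHz, 13C %g kHz, ",
           "INEPT tau/tau' = %g/%g ms\n"),
    x$b0, x$larmor_c / 1e6, x$mas_rate / 1e3, x$t_cp * 1e3,
    x$nut_h_start / 1e3, x$nut_h_end / 1e3, x$nut_c / 1e3,
    x$inept_tau * 1e3, x$inept_tau_prime * 1e3))
  invisible(x)
}

#' Read experiment settings from a flat key/value config file
#'
#' Reads a YAML file whose keys mirror the [experiment_settings()] argument
#' names; unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return An `experiment_settings` object.
#' @export
read_experiment_settings <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) pt_data_error("Settings file must contain a key/value mapping.")
  allowed <- setdiff(names(formals(experiment_settings)), "")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    pt_usage_error(sprintf("Unknown settings key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(experiment_settings, cfg)
}
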