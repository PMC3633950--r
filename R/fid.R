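#' Construct a free-induction decay object
#'
#' An FID is stored as a tibble with columns `t` (seconds), `re` and `im`
#' (complex time-domain samples), carrying the acquisition metadata needed to
#' build a ppm axis as attributes.  The defaults mirror the reference
#' acquisition: 1597 points over a 50 ms acquisition time and a spectral
#' width of about 250 ppm at a 125 MHz carbon frequency.
#'
#' @param points Complex vector of time-domain samples.
#' @param dwell_time Seconds per point.
#' @param scheme One of `"DP"`, `"CP"`, `"INEPT"`.
#' @param larmor_c 13C Larmor frequency, Hz.
#' @param carrier_ppm Carrier (axis centre) position, ppm.
#'
#' @return Tibble of class `nmr_fid`.
#' @export
new_fid <- function(points, dwell_time, scheme = c("DP", "CP", "INEPT"),
                    larmor_c = 125e6, carrier_ppm = 110) {
  scheme <- match.arg(scheme)
  if (!is.complex(points)) points <- as.complex(points)
  if (length(points) < 2) pt_usage_error("An FID needs at least 2 points.")
  if (!is.numeric(dwell_time) || dwell_time <= 0) {
    pt_usage_error("`dwell_time` must be positive (seconds).")
  }
  n <- length(points)
  out <- new_tibble(
    list(t = (seq_len(n) - 1) * dwell_time,
         re = Re(points), im = Im(points)),
    nrow = n, class = "nmr_fid")
  attr(out, "dwell_time") <- dwell_time
  attr(out, "scheme") <- scheme
  attr(out, "larmor_c") <- larmor_c
  attr(out, "carrier_ppm") <- carrier_ppm
  out
}

fid_points <- function(fid) complex(real = fid$re, imaginary = fid$im)

fid_meta <- function(fid) {
  list(dwell_time = attr(fid, "dwell_time"), scheme = attr(fid, "scheme"),
       larmor_c = attr(fid, "larmor_c"), carrier_ppm = attr(fid, "carrier_ppm"))
}

.rebuild_fid <- function(points, meta) {
  new_fid(points, dwell_time = meta$dwell_time, scheme = meta$scheme,
          larmor_c = meta$larmor_c, carrier_ppm = meta$carrier_ppm)
}

#' @export
print.nmr_fid <- function(x, ...) {
  m <- fid_meta(x)
  cat(sprintf("<nmr_fid> %s, %d points, dwell %.3g us, aq %.3g ms\n",
              m$scheme, nrow(x), m$dwell_time * 1e6, nrow(x) * m$dwell_time * 1e3))
  NextMethod()
}

.spectrum_attr_names <- c("scheme", "larmor_c", "carrier_ppm", "sw_hz",
                          "reference_ppm", "phases", "baseline")

spectrum_meta <- function(x) {
  setNames(lapply(.spectrum_attr_names, function(a) attr(x, a)),
           .spectrum_attr_names)
}

.rebuild_spectrum <- function(tbl, meta) {
  out <- new_tibble(as.list(tbl), nrow = nrow(tbl), class = "nmr_spectrum")
  for (a in .spectrum_attr_names) attr(out, a) <- meta[[a]]
  out
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s, %d points, %.1f to %.1f ppm%s\n",
              attr(x, "scheme") %||% "?", nrow(x),
              max(x$ppm), min(x$ppm),
              if (!is.null(attr(x, "reference_ppm")) &&
                  !is.na(attr(x, "reference_ppm")))
                sprintf(", referenced at %.1f ppm", attr(x, "reference_ppm"))
              else ""))
  NextMethod()
}

#' @method tidy nmr_spectrum
#' @export
tidy.nmr_spectrum <- function(x, ...) {
  tibble(ppm = x$ppm, intensity = x$intensity)
}

#' @method tidy nmr_fid
#' @export
tidy.nmr_fid <- function(x, ...) {
  tibble(t = x$t, re = x$re, im = x$im)
}

#' @method glance nmr_spectrum
#' @export
glance.nmr_spectrum <- function(x, ...) {
  tibble(scheme = attr(x, "scheme") %||% NA_character_,
         n_points = nrow(x),
         ppm_min = min(x$ppm), ppm_max = max(x$ppm),
         reference_ppm = attr(x, "reference_ppm") %||% NA_real_)
}

#' @method glance nmr_fid
#' @export
glance.nmr_fid <- function(x, ...) {
  m <- fid_meta(x)
  tibble(scheme = m$scheme, n_points = nrow(x), dwell_time = m$dwell_time,
         acquisition_time = nrow(x) * m$dwell_time)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
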