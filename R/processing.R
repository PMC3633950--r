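#' Exponential apodization (line broadening)
#'
#' Multiplies the FID pointwise by `exp(-pi * lb_hz * t)`, adding `lb_hz` of
#' Lorentzian width to every line.  `lb_hz = 0` is the identity.
#'
#' @param fid An [new_fid()] object.
#' @param lb_hz Line broadening in Hz, `>= 0`; default 10.
#' @return Apodized `nmr_fid`.
#' @export
apodize <- function(fid, lb_hz = 10) {
  stopifnot(inherits(fid, "nmr_fid"))
  if (!is.numeric(lb_hz) || length(lb_hz) != 1 || lb_hz < 0) {
    pt_usage_error("`lb_hz` must be a single non-negative number.")
  }
  .rebuild_fid(fid_points(fid) * exp(-pi * lb_hz * fid$t), fid_meta(fid))
}

#' Zero-fill an FID
#'
#' Appends zeros up to `target` points (default 8192, the canonical
#' extension of a 1597-point acquisition), improving digital resolution
#' without adding information.
#'
#' @inheritParams apodize
#' @param target Total number of points after filling; must be `>= nrow(fid)`.
#' @return Zero-filled `nmr_fid`.
#' @export
zero_fill <- function(fid, target = 8192) {
  stopifnot(inherits(fid, "nmr_fid"))
  n <- nrow(fid)
  if (!is.numeric(target) || length(target) != 1 || target < n) {
    pt_usage_error("`target` must be >= the current number of points.")
  }
  .rebuild_fid(c(fid_points(fid), complex(real = rep(0, target - n))),
               fid_meta(fid))
}

#' Fourier transform an FID into a spectrum
#'
#' Discrete Fourier transform with the package's fixed conventions: a signal
#' `exp(+2 pi i f t)` appears at `+f`; the axis is reported in ppm
#' (descending, standard NMR orientation) computed from the dwell time, the
#' 13C Larmor frequency and the carrier position.  The first FID point is
#' scaled by `first_point_scale` (default 1/2, the standard correction that
#' removes the constant baseline offset of a half-sampled first dwell).
#'
#' @inheritParams apodize
#' @param first_point_scale Weight applied to the first time-domain point.
#' @return A tibble of class `nmr_spectrum` with columns `ppm`, `re`, `im`
#'   and `intensity` (the real part).
#' @export
transform <- function(fid, first_point_scale = 0.5) {
  stopifnot(inherits(fid, "nmr_fid"))
  m <- fid_meta(fid)
  x <- fid_points(fid)
  x[1] <- x[1] * first_point_scale
  n <- length(x)
  sw <- 1 / m$dwell_time
  spec <- fft(x)
  # reorder so frequencies run from -sw/2 to +sw/2
  k <- c(seq(floor(n / 2) + 1L, n), seq_len(floor(n / 2)))
  spec <- spec[k]
  f <- (seq_len(n) - 1 - floor(n / 2)) * sw / n
  ppm <- m$carrier_ppm + f / (m$larmor_c * 1e-6)
  ord <- order(ppm, decreasing = TRUE)
  out <- new_tibble(
    list(ppm = ppm[ord], re = Re(spec)[ord], im = Im(spec)[ord],
         intensity = Re(spec)[ord]),
    nrow = n, class = "nmr_spectrum")
  attr(out, "scheme") <- m$scheme
  attr(out, "larmor_c") <- m$larmor_c
  attr(out, "carrier_ppm") <- m$carrier_ppm
  attr(out, "sw_hz") <- sw
  attr(out, "reference_ppm") <- NA_real_
  out
}

#' Apply a zero- and first-order phase correction
#'
#' @param spectrum An `nmr_spectrum` with `re`/`im` columns.
#' @param phi0,phi1 Zero- and first-order phase in degrees; the first-order
#'   term varies linearly from `-phi1/2` to `+phi1/2` across the axis.
#' @return Phased `nmr_spectrum` (`intensity` is the new real part).
#' @export
phase_spectrum <- function(spectrum, phi0, phi1 = 0) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  meta <- spectrum_meta(spectrum)
  z <- complex(real = spectrum$re, imaginary = spectrum$im)
  x <- seq(-0.5, 0.5, length.out = length(z))
  ph <- (phi0 + phi1 * x) * pi / 180
  z <- z * exp(1i * ph)
  tbl <- list(ppm = spectrum$ppm, re = Re(z), im = Im(z), intensity = Re(z))
  meta$phases <- c(phi0 = phi0, phi1 = phi1) +
    (meta$phases %||% c(phi0 = 0, phi1 = 0))
  .rebuild_spectrum(tibble::as_tibble(tbl), meta)
}

#' Automatic phase correction
#'
#' Chooses zero- and first-order phases by minimizing a documented
#' objective: the Shannon entropy of the magnitude of the first derivative
#' of the real part, plus a penalty on negative intensity (negative-area
#' penalty weight `gamma`).  A deterministic coarse grid over the
#' zero-order phase seeds a Nelder-Mead refinement of both phases, so the
#' result depends only on the input spectrum.
#'
#' @inheritParams phase_spectrum
#' @param gamma Weight of the negative-intensity penalty.
#' @param fit_phi1 Also optimize the first-order phase?
#' @return Phased `nmr_spectrum`; the total applied phases accumulate in
#'   `attr(x, "phases")`.
#' @export
auto_phase <- function(spectrum, gamma = 1000, fit_phi1 = TRUE) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  z <- complex(real = spectrum$re, imaginary = spectrum$im)
  x <- seq(-0.5, 0.5, length.out = length(z))
  scale <- sum(Mod(z)^2)
  if (scale == 0) return(spectrum)
  obj <- function(par) {
    re <- Re(z * exp(1i * (par[1] + par[2] * x) * pi / 180))
    h <- abs(diff(re))
    s <- sum(h)
    ent <- if (s > 0) {
      p <- h / s
      -sum(p[p > 0] * log(p[p > 0]))
    } else 0
    ent + gamma * sum(pmin(re, 0)^2) / scale
  }
  grid <- seq(-180, 175, by = 5)
  best0 <- grid[which.min(vapply(grid, function(p) obj(c(p, 0)), numeric(1)))]
  fit <- if (fit_phi1) {
    optim(c(best0, 0), obj, method = "Nelder-Mead",
          control = list(maxit = 400, reltol = 1e-10))
  } else {
    o <- optimize(function(p) obj(c(p, 0)), interval = best0 + c(-10, 10))
    list(par = c(o$minimum, 0), convergence = 0)
  }
  if (!identical(fit$convergence, 0L) && !identical(fit$convergence, 0)) {
    warn("auto_phase: optimizer did not fully converge; using best phases found.")
  }
  phase_spectrum(spectrum, phi0 = fit$par[1], phi1 = fit$par[2])
}

#' Asymmetric-least-squares baseline correction
#'
#' Estimates a smooth baseline by the Eilers asymmetric-least-squares
#' scheme (second-difference penalty `lambda`, asymmetry `p`) and subtracts
#' it from the real part.  Flat offsets and slow drifts are removed while
#' peaks are left intact.
#'
#' @inheritParams phase_spectrum
#' @param lambda Smoothness penalty (larger = stiffer baseline).
#' @param p Asymmetry parameter; points above the baseline get weight `p`.
#' @param maxit Reweighting iterations.
#' @return Baseline-corrected `nmr_spectrum`; the subtracted baseline is
#'   stored in `attr(x, "baseline")`.
#' @export
baseline_correct <- function(spectrum, lambda = 1e7, p = 0.001, maxit = 10) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  meta <- spectrum_meta(spectrum)
  y <- spectrum$intensity
  z <- als_baseline(y, lambda = lambda, p = p, maxit = maxit)
  tbl <- list(ppm = spectrum$ppm, re = spectrum$re - z, im = spectrum$im,
              intensity = y - z)
  meta$baseline <- z
  .rebuild_spectrum(tibble::as_tibble(tbl), meta)
}

als_baseline <- function(y, lambda = 1e7, p = 0.001, maxit = 10) {
  # centre and scale for conditioning; a constant input is its own baseline
  mid <- stats::median(y)
  scl <- max(abs(y - mid))
  if (scl == 0) return(y)
  y0 <- y
  y <- (y - mid) / scl
  n <- length(y)
  d <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  ddt <- lambda * Matrix::crossprod(d)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(maxit)) {
    wmat <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(wmat + ddt, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (max(abs(w_new - w)) < 1e-12) break
    w <- w_new
  }
  # the penalized system is badly conditioned (lambda D'D vs. weights p);
  # a couple of iterative-refinement steps recover full double precision
  a <- Matrix::Diagonal(n, w) + ddt
  for (i in 1:2) {
    r <- w * y - as.numeric(a %*% z)
    z <- z + as.numeric(Matrix::solve(a, r))
  }
  z * scl + mid
}

#' Reference the ppm axis to solid alpha-glycine
#'
#' Shifts the ppm axis by a constant so that the supplied (or auto-picked)
#' anchor peak sits at exactly the glycine methylene shift of 43.7 ppm.
#'
#' @inheritParams phase_spectrum
#' @param observed_ppm Observed position of the anchor peak; when `NULL` the
#'   maximum within `search_halfwidth_ppm` of the anchor is picked.
#' @param anchor_ppm Target anchor position (43.7 ppm).
#' @param search_halfwidth_ppm Search half-width for auto-picking.
#' @return Referenced `nmr_spectrum` with `attr(x, "reference_ppm")` set.
#' @export
reference_to_glycine <- function(spectrum, observed_ppm = NULL,
                                 anchor_ppm = 43.7,
                                 search_halfwidth_ppm = 1) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  meta <- spectrum_meta(spectrum)
  if (is.null(observed_ppm)) {
    sel <- abs(spectrum$ppm - anchor_ppm) <= search_halfwidth_ppm
    if (!any(sel)) pt_data_error("No axis points near the anchor to auto-pick from.")
    observed_ppm <- spectrum$ppm[sel][which.max(spectrum$intensity[sel])]
  }
  if (observed_ppm < min(spectrum$ppm) || observed_ppm > max(spectrum$ppm)) {
    pt_data_error("`observed_ppm` lies outside the spectral axis.")
  }
  tbl <- as.list(spectrum)
  # anchor point maps to anchor_ppm exactly, bit for bit
  tbl$ppm <- (spectrum$ppm - observed_ppm) + anchor_ppm
  meta$reference_ppm <- anchor_ppm
  .rebuild_spectrum(tibble::as_tibble(tbl), meta)
}

#' Full FID-to-spectrum processing pipeline
#'
#' Applies, in order: exponential apodization (default 10 Hz), zero-filling
#' (default to 8192 points), Fourier transformation, automatic (or no)
#' phase correction and asymmetric-least-squares baseline correction.  The
#' pipeline is deterministic: identical input and configuration give
#' identical output.
#'
#' @inheritParams apodize
#' @param zero_fill_to Target length for [zero_fill()].
#' @param phase `"auto"` for [auto_phase()], `"none"` to keep phases as-is.
#' @param baseline Apply [baseline_correct()]?
#' @param lambda,p Baseline parameters.
#' @return Processed `nmr_spectrum`.
#' @examples
#' fid <- simulate_fid(sc_sample(96, 32), "INEPT")
#' sp <- process_fid(fid, phase = "none")
#' @export
process_fid <- function(fid, lb_hz = 10, zero_fill_to = 8192,
                        phase = c("auto", "none"), baseline = TRUE,
                        lambda = 1e7, p = 0.001) {
  phase <- match.arg(phase)
  zero_fill_to <- max(zero_fill_to, nrow(fid))
  sp <- transform(zero_fill(apodize(fid, lb_hz = lb_hz), target = zero_fill_to))
  if (phase == "auto") sp <- auto_phase(sp)
  if (baseline) sp <- baseline_correct(sp, lambda = lambda, p = p)
  sp
}
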