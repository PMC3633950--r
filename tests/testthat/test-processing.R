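make_test_fid <- function(freqs_hz = 1000, amps = 1, lw_hz = 30,
                          n = 1597, sw = 31940, noise = 0, seed = 1,
                          phase_deg = 0) {
  t <- (seq_len(n) - 1) / sw
  x <- complex(real = rep(0, n))
  for (i in seq_along(freqs_hz)) {
    x <- x + amps[min(i, length(amps))] *
      exp(2i * pi * freqs_hz[i] * t - pi * lw_hz * t)
  }
  x <- x * exp(1i * phase_deg * pi / 180)
  if (noise > 0) {
    set.seed(seed)
    x <- x + complex(real = rnorm(n, 0, noise), imaginary = rnorm(n, 0, noise))
  }
  new_fid(x, dwell_time = 1 / sw, scheme = "DP")
}

test_that("apodization weights the FID as exp(-pi lb t)", {
  fid <- make_test_fid()
  expect_equal(apodize(fid, 0)$re, fid$re)
  ap <- apodize(fid, 10)
  expect_equal(ap$re[1], fid$re[1])  # t = 0 weight is 1
  tn <- fid$t[nrow(fid)]
  expect_equal(ap$re[nrow(ap)] / fid$re[nrow(fid)], exp(-pi * 10 * tn),
               tolerance = 1e-12)
  # the reference acquisition time gives a last-point weight of exp(-pi/2)
  expect_equal(exp(-pi * 10 * 0.05), exp(-pi * 0.5))
  expect_error(apodize(fid, -1), class = "ptnmr_usage_error")
})

test_that("zero filling appends zeros and preserves the acquired points", {
  fid <- make_test_fid(n = 1597)
  zf <- zero_fill(fid)
  expect_identical(nrow(zf), 8192L)
  expect_equal(zf$re[1:1597], fid$re)
  expect_equal(sum(abs(complex(real = zf$re, imaginary = zf$im))),
               sum(abs(complex(real = fid$re, imaginary = fid$im))))
  expect_identical(nrow(zero_fill(fid, 1597)), 1597L)
  expect_error(zero_fill(fid, 1000), class = "ptnmr_usage_error")
})

test_that("the transform satisfies Parseval's identity and linearity", {
  fid <- make_test_fid(freqs_hz = c(-3000, 1200), amps = c(1, 0.4))
  sp <- transform(fid, first_point_scale = 1)
  e_time <- sum(Mod(complex(real = fid$re, imaginary = fid$im))^2)
  e_freq <- sum(Mod(complex(real = sp$re, imaginary = sp$im))^2) / nrow(fid)
  expect_equal(e_freq, e_time, tolerance = 1e-10)

  fa <- make_test_fid(freqs_hz = -3000)
  fb <- make_test_fid(freqs_hz = 1200)
  xs <- complex(real = fa$re + fb$re, imaginary = fa$im + fb$im)
  fsum <- new_fid(xs, dwell_time = attr(fa, "dwell_time"), scheme = "DP")
  expect_equal(transform(fsum)$re,
               transform(fa)$re + transform(fb)$re, tolerance = 1e-9)

  # a delta FID gives a flat magnitude spectrum
  delta <- new_fid(c(1 + 0i, rep(0 + 0i, 255)), dwell_time = 1 / 31940)
  spd <- transform(delta, first_point_scale = 1)
  expect_equal(Mod(complex(real = spd$re, imaginary = spd$im)),
               rep(1, 256), tolerance = 1e-12)
})

test_that("a single-exponential FID transforms into the matching Lorentzian", {
  lw <- 50
  sw <- 31940
  fid <- make_test_fid(freqs_hz = 2000, lw_hz = lw, n = 8192, sw = sw)
  sp <- transform(fid)
  # closed-form continuous Lorentzian, in points-per-bin units
  f <- (sp$ppm - 110) * 125  # back to Hz
  r <- pi * lw
  lor <- Re(1 / (r + 2i * pi * (f - 2000))) * sw
  sel <- abs(f - 2000) < 2000
  expect_lt(max(abs(sp$intensity[sel] - lor[sel])) / max(lor), 1e-3)
  # peak lands at the input frequency
  expect_equal(f[which.max(sp$intensity)], 2000, tolerance = sw / 8192)
})

test_that("automatic phasing recovers known phase errors within a degree", {
  fid <- make_test_fid(freqs_hz = c(-5000, 0, 4000), amps = c(1, 0.6, 0.8),
                       lw_hz = 40, n = 4096)
  sp0 <- transform(fid)
  for (err in c(30, -60)) {
    ph <- auto_phase(phase_spectrum(sp0, err))
    total <- attr(ph, "phases")[["phi0"]]
    # total applied phase returns to 0 (mod 360)
    expect_lt(min(abs((total %% 360) - c(0, 360))), 1)
    expect_gt(max(ph$intensity), 0.99 * max(sp0$intensity))
  }
  # pure noise completes without error
  set.seed(9)
  noise_fid <- new_fid(complex(real = rnorm(512), imaginary = rnorm(512)),
                       dwell_time = 1 / 31940)
  expect_s3_class(auto_phase(transform(noise_fid)), "nmr_spectrum")
})

test_that("baseline correction removes offsets and ramps but keeps peaks", {
  axis <- descending_axis(n = 2048)
  # flat offset
  flat <- make_lorentz_spectrum(axis, 110, 0, 1, offset = 5)
  bc <- baseline_correct(flat)
  expect_lt(max(abs(bc$intensity)), 1e-9 * 5)
  # linear ramp
  ramp_y <- seq(0, 10, length.out = 2048)
  ramp <- make_lorentz_spectrum(axis, 110, 0, 1)
  ramp$intensity <- ramp$intensity + ramp_y
  ramp$re <- ramp$intensity
  bc2 <- baseline_correct(ramp)
  expect_lt(max(abs(bc2$intensity)), 0.01 * 10)
  # Lorentzian + offset: peak height preserved within 2 %
  pk <- make_lorentz_spectrum(axis, 110, 100, 0.8, offset = 3)
  bc3 <- baseline_correct(pk)
  expect_equal(max(bc3$intensity), 100, tolerance = 0.02)
})

test_that("glycine referencing pins the anchor exactly", {
  axis <- descending_axis(n = 2048)
  sp <- make_lorentz_spectrum(axis, 43.2, 50, 0.3)
  ref <- reference_to_glycine(sp, observed_ppm = 43.2)
  expect_equal(max(ref$ppm) - max(sp$ppm), 0.5, tolerance = 1e-12)
  # auto-pick finds the anchor peak and lands it at exactly 43.7
  ref2 <- reference_to_glycine(sp)
  expect_equal(ref2$ppm[which.max(ref2$intensity)], 43.7, tolerance = 1e-9)
  # already-referenced axis is unchanged
  sp2 <- make_lorentz_spectrum(axis, 43.7, 50, 0.3)
  expect_equal(reference_to_glycine(sp2)$ppm, sp2$ppm, tolerance = 0.05)
  expect_error(reference_to_glycine(sp, observed_ppm = 500),
               class = "ptnmr_data_error")
})

test_that("the pipeline is deterministic and recovers simulated peak positions", {
  spec <- sc_sample(96, 32, seed = 2)
  fid <- simulate_fid(spec, "DP", noise_sigma = 0)
  a <- process_fid(fid)
  b <- process_fid(fid)
  expect_identical(a$intensity, b$intensity)
  # every simulated mobile segment peak is found within 0.05 ppm
  sp <- process_fid(simulate_fid(spec, "INEPT"), phase = "none")
  for (shift in spec$shift_ppm[spec$order_parameter < 0.01]) {
    sel <- abs(sp$ppm - shift) < 0.5
    found <- sp$ppm[sel][which.max(sp$intensity[sel])]
    expect_lt(abs(found - shift), 0.05)
  }
})
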