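test_that("peak areas match the analytic Lorentzian integral", {
  axis <- descending_axis(n = 16384)
  hw <- 0.4
  sp <- make_lorentz_spectrum(axis, 110, 20, hw)
  # window wide enough to hold essentially the whole line
  got <- as.numeric(measure_peak(sp, 110 - 100 * hw, 110 + 100 * hw))
  expect_equal(got, lorentz_area(20, hw), tolerance = 0.02)
  # zero spectrum gives exactly zero
  z <- make_lorentz_spectrum(axis, 110, 0, hw)
  expect_identical(as.numeric(measure_peak(z, 100, 120)), 0)
  # noise-only window stays within a noise-propagation bound
  set.seed(13)
  noisy <- make_lorentz_spectrum(axis, 110, 0, hw)
  noisy$intensity <- rnorm(length(axis), 0, 1)
  sel <- sum(noisy$ppm >= 150 & noisy$ppm <= 160)
  dppm <- abs(diff(axis[1:2]))
  # 3 sigma bound: trapezoid sum of `sel` unit normals plus the variance of
  # the subtracted chord (median-of-3 edge levels, var ~ 0.449 each)
  bound <- 3 * sqrt(sel * dppm^2 + 10^2 * 2 * 0.449 / 4)
  expect_lt(abs(attr(measure_peak(noisy, 150, 160), "signed")), bound)
  expect_error(measure_peak(sp, 120, 110), class = "ptnmr_usage_error")
  expect_error(measure_peak(sp, -100, -50), class = "ptnmr_data_error")
})

test_that("synthetic rigid and mobile samples classify correctly at zero noise", {
  rigid_tr <- simulate_triplet(sc_sample(70, 32, seed = 2))
  calls <- classify_peaks(rigid_tr)
  ker <- calls[calls$group %in% c("keratin_terminals", "keratin_core"), ]
  expect_true(all(ker$state_call == "rigid_slow"))

  wet_tr <- simulate_triplet(sc_sample(96, 32, seed = 2))
  calls2 <- classify_peaks(wet_tr)
  expect_identical(calls2$state_call[calls2$moiety == "omega CH3"],
                   "mobile_isotropic")
  expect_identical(calls2$state_call[calls2$moiety == "Gly C_alpha"],
                   "mobile_isotropic")
  expect_identical(
    calls2$state_call[calls2$moiety == "Leu C_beta / Lys C_epsilon"],
    "rigid_slow")
})

test_that("all-zero spectra yield only ambiguous calls, never an error", {
  axis <- descending_axis(n = 2048)
  zero <- rep(0, length(axis))
  tr <- triplet_from_intensities(axis, zero, zero, zero)
  calls <- classify_peaks(tr)
  expect_true(all(calls$state_call == "ambiguous"))
})

test_that("classification is invariant to uniform rescaling of all three spectra", {
  tr <- simulate_triplet(sc_sample(90, 32, seed = 6), snr = 80, seed = 21)
  scaled <- spectrum_triplet(
    ptnmr:::.rebuild_spectrum(
      tibble::as_tibble(dplyr::mutate(tibble::as_tibble(tr$dp),
                                      re = re * 37, im = im * 37,
                                      intensity = intensity * 37)),
      ptnmr:::spectrum_meta(tr$dp)),
    ptnmr:::.rebuild_spectrum(
      tibble::as_tibble(dplyr::mutate(tibble::as_tibble(tr$cp),
                                      re = re * 37, im = im * 37,
                                      intensity = intensity * 37)),
      ptnmr:::spectrum_meta(tr$cp)),
    ptnmr:::.rebuild_spectrum(
      tibble::as_tibble(dplyr::mutate(tibble::as_tibble(tr$inept),
                                      re = re * 37, im = im * 37,
                                      intensity = intensity * 37)),
      ptnmr:::spectrum_meta(tr$inept)),
    sample_state = tr$sample_state)
  expect_identical(classify_peaks(tr)$state_call,
                   classify_peaks(scaled)$state_call)
})

test_that("series reports flag the hydration trends and transitions", {
  series <- lapply(c(80, 85, 90, 93, 96), function(rh) {
    simulate_triplet(sc_sample(rh, 32, seed = 30 + rh))
  })
  rep <- series_report(series)
  g <- rep$groups
  expect_identical(g$trend[g$group == "lipids"], "increasing")
  expect_identical(g$trend[g$group == "keratin_terminals"], "increasing")
  expect_true(g$monotone_increase[g$group == "lipids"])

  expect_equal(unname(detect_transition(rep, "keratin_terminals")), c(80, 85))
  expect_null(detect_transition(rep, "keratin_core"))
  # gradual lipid growth, already mobile when dryish: no abrupt step
  expect_null(detect_transition(rep, "lipids"))

  expect_error(series_report(series[1]), class = "ptnmr_usage_error")
  expect_error(series_report(rev(series)), class = "ptnmr_usage_error")
})

test_that("a hot, hydrated sample shows a fully mobile lipid pool", {
  tr <- simulate_triplet(sc_sample(96, 60, seed = 8))
  calls <- classify_peaks(tr)
  lip <- calls[calls$group == "lipids", ]
  # no rigid all-trans window left; trans/gauche and chain ends all mobile
  expect_true(all(lip$state_call[lip$moiety != "(CH2)n all-trans"] ==
                  "mobile_isotropic"))
  expect_false("rigid_slow" %in% lip$state_call)
})

test_that("flat series produce no transition", {
  axis <- descending_axis(n = 2048)
  peak <- 30 * exp(-(axis - 30.5)^2 / 0.02)
  trs <- lapply(c(80, 90), function(rh) {
    triplet_from_intensities(axis, peak, peak * 0, peak,
                             sample_state = list(rh_percent = rh))
  })
  rep <- series_report(trs)
  expect_null(detect_transition(rep, "lipids"))
})
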