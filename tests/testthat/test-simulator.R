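test_that("NaCl molality maps to the tabulated humidities, monotonically", {
  expect_equal(rh_for_nacl_molality(5.12), 80.0)
  expect_equal(rh_for_nacl_molality(0.156), 99.5)
  expect_equal(rh_for_nacl_molality(2.02), 93.0)
  m <- seq(0.2, 5.1, length.out = 50)
  expect_true(all(diff(rh_for_nacl_molality(m)) < 0))
  expect_error(rh_for_nacl_molality(6), class = "ptnmr_usage_error")
  expect_error(rh_for_nacl_molality(0.01), class = "ptnmr_usage_error")
})

test_that("water content follows the gravimetric definition", {
  expect_equal(water_content(70, 100), 0.30)
  expect_equal(water_content(100, 100), 0)
  expect_equal(water_content(50, 100), 0.50)
  expect_error(water_content(100, 70), class = "ptnmr_usage_error")
  expect_error(water_content(0, 10), class = "ptnmr_usage_error")
})

test_that("sample specs encode the hydration/temperature rules", {
  # terminals rigid at RH 80
  s80 <- sc_sample(80, 32, seed = 1)
  term80 <- s80[s80$group == "keratin_terminal", ]
  expect_true(all(term80$order_parameter > 0.8))
  expect_true(all(term80$dynamic_state == "rigid_slow"))
  # terminals mobile at RH 85 and above
  s85 <- sc_sample(85, 32, seed = 1)
  term85 <- s85[s85$group == "keratin_terminal", ]
  expect_true(all(term85$order_parameter < 0.01))
  expect_true(all(term85$dynamic_state == "mobile_isotropic"))
  # keratin core rigid in every state
  for (st in list(s80, s85, sc_sample(96, 60, seed = 1))) {
    expect_true(all(st$dynamic_state[st$group == "keratin_core"] == "rigid_slow"))
  }
  # no rigid all-trans pool at 60 C and high hydration
  expect_false("lipid_solid" %in% sc_sample(96, 60, seed = 1)$group)
  expect_true("lipid_solid" %in% sc_sample(80, 60, seed = 1)$group)
  # mobile cholesterol only near RH 85
  expect_true("cholesterol" %in% s85$group)
  expect_false("cholesterol" %in% sc_sample(96, 32, seed = 1)$group)
  # dry state still holds a small mobile lipid pool
  dry <- sc_sample("dry", 32, seed = 1)
  expect_gt(sum(dry$abundance[dry$group == "lipid_mobile"]), 0)
})

test_that("sample specs are deterministic in (state, seed)", {
  a <- sc_sample(90, 32, seed = 11)
  b <- sc_sample(90, 32, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- sc_sample(90, 32, seed = 12)
  expect_false(identical(a$abundance, c$abundance))
})

test_that("simulated FIDs are linear in abundance and scheme-faithful", {
  spec <- sc_sample(90, 32, seed = 1, jitter = 0)
  f1 <- simulate_fid(spec, "DP")
  spec2 <- spec
  spec2$abundance <- 2 * spec$abundance
  f2 <- simulate_fid(spec2, "DP")
  expect_equal(f2$re, 2 * f1$re, tolerance = 1e-9)
  expect_equal(f2$im, 2 * f1$im, tolerance = 1e-9)

  # CP of a purely mobile isotropic segment is essentially empty
  mob <- spec[spec$label == "omega CH3", ]
  fcp <- simulate_fid(mob, "CP")
  fdp <- simulate_fid(mob, "DP")
  expect_lt(max(Mod(complex(real = fcp$re, imaginary = fcp$im))),
            1e-2 * max(Mod(complex(real = fdp$re, imaginary = fdp$im))))

  # fixed seed reproduces the noise exactly
  n1 <- simulate_fid(spec, "DP", noise_sigma = 0.1, seed = 5)
  n2 <- simulate_fid(spec, "DP", noise_sigma = 0.1, seed = 5)
  expect_identical(n1$re, n2$re)
})

test_that("noise calibration hits the requested DP spectral SNR", {
  spec <- sc_sample(90, 32, seed = 1)
  sigma <- noise_sigma_for_snr(spec, snr = 50)
  sp <- process_fid(simulate_fid(spec, "DP", noise_sigma = sigma, seed = 3),
                    phase = "none", baseline = FALSE)
  # empirical noise from a signal-free region
  noise_sd <- stats::sd(sp$intensity[sp$ppm > 180 & sp$ppm < 220])
  snr_emp <- max(sp$intensity) / noise_sd
  expect_gt(snr_emp, 30)
  expect_lt(snr_emp, 85)
})

test_that("mobile-lipid INEPT grows while the lipid spectrum stays peak-faithful", {
  areas <- vapply(c(80, 85, 90, 93, 96), function(rh) {
    spec <- sc_sample(rh, 32, seed = 4, jitter = 0)
    sp <- process_fid(simulate_fid(spec, "INEPT"), phase = "none")
    sum(vapply(c(30.5, 23.3, 14.6), function(x0) {
      as.numeric(measure_peak(sp, x0 - 0.3, x0 + 0.3))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})
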