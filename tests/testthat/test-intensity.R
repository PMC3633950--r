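fake_relax <- function(t2_h = Inf, t2_c = Inf, t1rho_h = Inf, t_ch = Inf) {
  tibble::new_tibble(list(t2_h = t2_h, t2_c = t2_c, t1rho_h = t1rho_h,
                          t_ch = t_ch),
                     nrow = 1L, class = "relaxation_set")
}

test_that("CP kinetics reproduce direct formula evaluation in the three regimes", {
  st <- default_settings
  g <- st$gamma_ratio
  # rigid slow limit: fast build-up, negligible rotating-frame loss
  rx <- fake_relax(t_ch = 50e-6, t1rho_h = 1)
  direct <- g / (1 - 50e-6 / 1) * (exp(-1e-3 / 1) - exp(-1e-3 / 50e-6))
  expect_equal(cp_intensity(rx, st), direct, tolerance = 1e-12)
  expect_gte(cp_intensity(rx, st), 0.9 * g)
  # isotropic fast limit: no dipolar build-up at all
  expect_identical(cp_intensity(fake_relax(t_ch = Inf, t1rho_h = 1), st), 0)
  # intermediate: rotating-frame relaxation kills the transfer
  rx2 <- fake_relax(t_ch = 50e-6, t1rho_h = 50e-6)
  expect_lt(cp_intensity(rx2, st), 0.1 * g)
  # degenerate rates use the analytic limit
  expect_equal(cp_intensity(rx2, st),
               g * (1e-3 / 50e-6) * exp(-1e-3 / 50e-6), tolerance = 1e-6)
})

test_that("INEPT amplitude matches the refocusing product formula", {
  st <- default_settings
  g <- st$gamma_ratio
  # lossless transfer at optimal delays for a CH with J = 1/(4 tau)
  j_opt <- 1 / (4 * st$inept_tau)
  st_match <- experiment_settings(inept_tau_prime = st$inept_tau)
  seg1 <- spin_segment(1, j_ch = j_opt)
  expect_equal(inept_intensity(fake_relax(), seg1, st_match), g,
               tolerance = 1e-12)
  # scalar oracle for the CH2 refocusing factor at the reference delays
  th <- pi * 139 * 2 * st$inept_tau
  thp <- pi * 139 * 2 * st$inept_tau_prime
  expect_equal(inept_intensity(fake_relax(), ch2, st),
               g * sin(th) * sin(thp) * cos(thp), tolerance = 1e-12)
  # exponential damping: short T2H annihilates the signal
  expect_lt(inept_intensity(fake_relax(t2_h = 10e-6), ch2, st), 1e-3)
})

test_that("DP is the unit reference, with optional visibility attenuation", {
  expect_identical(dp_intensity(fake_relax(t2_c = 1)), 1.0)
  expect_identical(dp_intensity(fake_relax(t2_c = 1e-6)), 1.0)
  expect_lt(dp_intensity(fake_relax(t2_c = 5e-6), visibility = TRUE), 1.0)
})

test_that("efficiency triplets land in the regimes expected at fast correlation times", {
  st <- default_settings
  g <- st$gamma_ratio
  iso <- efficiency_triplet(motion_model(0.005, 1e-9), ch2, st)
  expect_gt(iso$i_inept, 0.9 * efficiency_triplet(motion_model(0.001, 1e-9), ch2, st)$i_inept)
  expect_lt(iso$i_cp, 0.01 * g)

  ordered <- efficiency_triplet(motion_model(0.7, 1e-9), ch2, st)
  expect_gt(ordered$i_cp, 0.9 * efficiency_triplet(motion_model(1, 1e-9), ch2, st)$i_cp)
  expect_lt(ordered$i_inept, 0.01 * g)

  inter <- efficiency_triplet(motion_model(0.9, 2e-6), ch2, st)
  expect_lt(inter$i_cp, 0.15 * g)
  expect_lt(inter$i_inept, 0.15 * g)
  expect_equal(inter$i_dp, 1.0)
})

test_that("INEPT decreases and CP increases with order at fast correlation time", {
  sgrid <- 10^seq(-3, 0, length.out = 40)
  trips <- purrr::map_dfr(sgrid, function(S) {
    efficiency_triplet(motion_model(S, 1e-9, 1), ch2, default_settings)
  })
  expect_true(all(diff(trips$i_inept) <= 1e-12))
  expect_true(all(diff(trips$i_cp) >= -1e-12))
  # no super-physical enhancement anywhere
  expect_true(all(trips$i_cp <= default_settings$gamma_ratio + 1e-9))
  expect_true(all(trips$i_inept <= default_settings$gamma_ratio + 1e-9))
})

test_that("efficiency map covers the grid, validates input, and shows the equality contour near S = 0.1", {
  tau <- 10^seq(-12, 0, length.out = 9)
  s <- 10^seq(-3, 0, length.out = 7)
  map <- efficiency_map(tau, s)
  expect_s3_class(map, "efficiency_map")
  expect_equal(nrow(map), length(tau) * length(s))
  expect_true(all(c("order_parameter", "tau_c", "i_dp", "i_cp", "i_inept") %in%
                  names(map)))

  expect_error(efficiency_map(numeric(0), s), class = "ptnmr_usage_error")
  expect_error(efficiency_map(c(1e-13, 1e-9), s), class = "ptnmr_usage_error")
  expect_error(efficiency_map(tau, 2), class = "ptnmr_usage_error")

  # CP = INEPT equality crossing at tau_c = 1 ns sits near S ~ 0.1
  sfine <- 10^seq(-3, 0, length.out = 61)
  m1 <- efficiency_map(1e-9, sfine)
  diffsign <- sign(m1$i_cp - m1$i_inept)
  cross <- sfine[which(diff(diffsign) > 0)[1] + 1]
  expect_gt(cross, 0.05)
  expect_lt(cross, 0.2)
})

test_that("a 50 x 50 map computes quickly", {
  t0 <- Sys.time()
  map <- efficiency_map(10^seq(-12, 0, length.out = 50),
                        10^seq(-3, 0, length.out = 50))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 10)
  expect_equal(nrow(map), 2500)
})

test_that("regime classification follows the thresholded-ratio rules", {
  expect_identical(classify_regime(1, 0, 3.5), "mobile_isotropic")
  expect_identical(classify_regime(1, 1.8, 1.7), "mobile_anisotropic")
  expect_identical(classify_regime(1, 3.6, 0), "rigid_slow")
  expect_identical(classify_regime(1, 0.1, 0.05), "intermediate")
  expect_identical(classify_regime(0, 0, 0), "ambiguous")
  # CP-dominated mixtures with a trace of INEPT stay rigid_slow
  expect_identical(classify_regime(1, 3.6, 0.3), "rigid_slow")
  # vectorised
  expect_identical(classify_regime(c(1, 1), c(0, 3.6), c(3.5, 0)),
                   c("mobile_isotropic", "rigid_slow"))
})
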