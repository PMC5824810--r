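test_that("2D autocorrelation model: amplitude, half-decay and monotonicity", {
  expect_equal(fcs_model_2d(0, 10, 1e-3), 0.1)            # G(0) = 1/N
  expect_equal(fcs_model_2d(1e-3, 10, 1e-3), 0.05)        # G(tauD) = 1/(2N)
  expect_equal(fcs_model_2d(3e-3, 10, 1e-3), 0.025)
  lags <- 10^seq(-5, 0, length.out = 50)
  g <- fcs_model_2d(lags, 12, 0.02)
  expect_true(all(diff(g) < 0))
  expect_true(all(fcs_model_2d(lags, 24, 0.02) < g))      # decreasing in N
})

test_that("noise-free curves are recovered essentially exactly", {
  curve <- gen_fcs_curve(simulation_config(
    fcs = list(true_n = 12, true_tau_d_s = 0.02, n_lags = 80,
               lag_decades = 5, lag_min_s = 1e-5, noise_sd = 0)))
  fit <- fit_fcs(curve)
  expect_equal(fit$n_particles, 12, tolerance = 1e-6)
  expect_equal(fit$tau_d_s, 0.02, tolerance = 1e-6)
})

test_that("degenerate curves are rejected", {
  lags <- 10^seq(-5, 0, length.out = 30)
  expect_error(fit_fcs(list(lag_s = lags, g = rep(0.1, 30))), "flat curve")
  expect_error(fit_fcs(list(lag_s = lags, g = -fcs_model_2d(lags, 10, 0.01))),
               "amplitude")
  expect_error(fit_fcs(list(lag_s = lags[1:5], g = rep(1, 5))), "at least")
  expect_error(fit_fcs(list(lag_s = rev(lags), g = fcs_model_2d(rev(lags), 10, 0.01))),
               "increasing")
})

test_that("waist calibration inverts tauD = r0^2 / (4D)", {
  tau <- (0.207^2) / (4 * 414)               # r0 = 207 nm, D = 414 um^2/s
  expect_equal(waist_from_reference(tau, 414), 207, tolerance = 1e-9)
  expect_equal(waist_from_reference(1, 1), 2000)   # 2 um
  expect_equal(waist_from_reference(tau, 2 * 414),
               sqrt(2) * 207, tolerance = 1e-9)
})

test_that("temperature correction follows Stokes-Einstein with water viscosity", {
  expect_equal(temperature_correct_d(414, 298.15, 298.15), 414)
  d27 <- temperature_correct_d(414, 298.15, 300.65)
  expect_equal(d27, 441.5, tolerance = 1e-3)
  expect_gt(temperature_correct_d(414, 298.15, 301.65), d27)
  expect_equal(water_viscosity(293.15), 1.002, tolerance = 1e-3)
  expect_equal(water_viscosity(298.15), 0.890, tolerance = 1e-3)
  expect_error(water_viscosity(350), "range")
})

test_that("surface density and crowding flag follow sigma = N/(pi r0^2), rho = sigma L^2", {
  d <- surface_density(12.12, 207, 110)
  expect_equal(d$sigma_per_um2, 90.035, tolerance = 1e-4)
  expect_equal(d$rho, d$sigma_per_um2 * 0.11^2, tolerance = 1e-12)
  expect_false(d$valid)                       # rho ~ 1.09 > 0.2
  low <- surface_density(1, 207, 110)
  expect_true(low$valid)
  zero <- surface_density(0, 207, 110)
  expect_equal(zero$sigma_per_um2, 0)
  expect_true(zero$valid)
  # boundary: rho exactly 0.2 is still valid
  sigma_b <- 0.2 / 0.11^2
  expect_true(density_estimate(sigma_b, 110)$valid)
  expect_false(density_estimate(sigma_b * (1 + 1e-9), 110)$valid)
  # linear in N
  expect_equal(surface_density(24.24, 207)$sigma_per_um2,
               2 * d$sigma_per_um2, tolerance = 1e-12)
})

test_that("intensity calibration fits, filters crowded pairs and inverts", {
  # exact line sigma = 2 I through valid-regime points
  I <- seq(0.5, 4, length.out = 10)
  dens <- lapply(2 * I, density_estimate)
  cal <- build_intensity_calibration(I, dens)
  expect_equal(cal$slope, 2, tolerance = 1e-9)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1)
  est <- density_from_intensity(45, cal)
  expect_equal(est$sigma_per_um2, 90, tolerance = 1e-9)
  expect_equal(est$source, "intensity_calibration")
  expect_false(est$valid)                     # 90 um^-2 is crowded at L = 110

  # crowded pairs excluded and counted
  I2 <- c(I, 100, 200)
  dens2 <- lapply(2 * I2, density_estimate)   # last two have rho > 0.2
  expect_message(cal2 <- build_intensity_calibration(I2, dens2), "excluded")
  expect_equal(cal2$n_guvs, 10L)
  expect_equal(cal2$n_excluded, 2L)

  expect_error(build_intensity_calibration(1:2, lapply(c(2, 4), density_estimate)),
               ">= 3 valid")
  # negative prediction clips to zero with a warning
  cal3 <- build_intensity_calibration(I, lapply(2 * I + 5, density_estimate))
  expect_warning(clipped <- density_from_intensity(-10, cal3), "clipping")
  expect_equal(clipped$sigma_per_um2, 0)
})

test_that("noisy calibration recovers the generating slope", {
  set.seed(99)
  slope <- 1.5
  I <- seq(0.5, 6, length.out = 45)
  sigma <- slope * I * rlnorm(45, -0.005, 0.1)   # ~10% noise
  cal <- build_intensity_calibration(I, lapply(sigma, density_estimate))
  expect_equal(cal$slope, slope, tolerance = 0.15)
})
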