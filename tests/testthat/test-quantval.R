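test_that("calibration fits recover exact lines and expose intercept bias", {
  conc <- c(1, 2, 4, 8, 16)
  cal <- calibration_fit(conc, 2 * conc)
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$r2, 1, tolerance = 1e-12)
  expect_equal(inverse_predict(cal, 8), 4, tolerance = 1e-9)

  # forcing a zero intercept on data with a true offset biases the slope up
  y <- 5 + 2 * conc
  free <- calibration_fit(conc, y)
  forced <- calibration_fit(conc, y, zero_intercept = TRUE)
  slope_oracle <- sum(conc * y) / sum(conc^2)  # closed-form zero-intercept OLS
  expect_equal(forced$slope, slope_oracle, tolerance = 1e-12)
  expect_gt(forced$slope, free$slope)
  expect_equal(free$slope, 2, tolerance = 1e-12)

  expect_error(calibration_fit(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_error(calibration_fit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("encapsulation efficiency is a scale-free percent ratio", {
  expect_equal(encapsulation_efficiency(5, 5), 100)
  expect_equal(encapsulation_efficiency(0, 5), 0)
  expect_equal(encapsulation_efficiency(5, 5),
               encapsulation_efficiency(5000, 5000))
  expect_error(encapsulation_efficiency(1, 0), "positive")
})

test_that("encapsulated drug quantified through the chromatographic route
           recovers the loaded amount", {
  # calibration from noiseless injections at five known concentrations
  peaks <- stp_hi443_peaks()["stp"]
  area_of <- function(conc) {
    pk <- peaks$stp; pk$conc <- conc
    ch <- simulate_chromatogram(c(flow = 0.6, volume = 18,
                                  organic_init = 92, wavelength = 270),
                                peaks = list(stp = pk),
                                noise_sd = 0, inj_cv = 0)
    pp <- ch$peaks_used$stp
    peak_area(ch, c(pp$ret - 6 * pp$sigma - pp$tau,
                    pp$ret + 6 * pp$sigma + 7 * pp$tau))
  }
  levels <- c(2, 5, 10, 15, 20)
  cal <- calibration_fit(levels, vapply(levels, area_of, numeric(1)))

  # an extract of "measured" concentration 7.3 from a 10 ug/mL theoretical load
  measured_conc <- inverse_predict(cal, area_of(7.3))
  ee <- encapsulation_efficiency(measured_conc, 10)
  expect_equal(ee, 73, tolerance = 0.02 * 73)
})

test_that("extinction coefficient round-trips through the peak-area route", {
  pk <- stp_hi443_peaks()$hi443
  pk$lambda_max <- 270        # measure at the response maximum
  flow <- 0.6; vol <- 18
  ch <- simulate_chromatogram(c(flow = flow, volume = vol,
                                organic_init = 92, wavelength = 270),
                              peaks = list(hi443 = pk),
                              noise_sd = 0, inj_cv = 0)
  pp <- ch$peaks_used$hi443
  area <- peak_area(ch, c(pp$ret - 6 * pp$sigma - pp$tau,
                          pp$ret + 6 * pp$sigma + 7 * pp$tau))
  moles <- pk$conc * vol / 1000 * 1e-6 / pk$molar_mass
  eps <- epsilon_from_peak_area(area, flow, path = 1, moles = moles)
  expect_equal(eps, 17823.67, tolerance = 0.001)

  # doubling the injected amount doubles area but leaves epsilon unchanged
  pk2 <- pk; pk2$conc <- 2 * pk$conc
  ch2 <- simulate_chromatogram(c(flow = flow, volume = vol,
                                 organic_init = 92, wavelength = 270),
                               peaks = list(hi443 = pk2),
                               noise_sd = 0, inj_cv = 0)
  pp2 <- ch2$peaks_used$hi443
  area2 <- peak_area(ch2, c(pp2$ret - 6 * pp2$sigma - pp2$tau,
                            pp2$ret + 6 * pp2$sigma + 7 * pp2$tau))
  expect_equal(area2 / area, 2, tolerance = 1e-3)
  eps2 <- epsilon_from_peak_area(area2, flow, path = 1, moles = 2 * moles)
  expect_equal(eps2, eps, tolerance = 1e-3)
  expect_error(epsilon_from_peak_area(-1, 1, 1, 1), "positive")
})

test_that("per-level epsilon estimates are mutually consistent", {
  pk <- stp_hi443_peaks()$stp
  pk$lambda_max <- 270
  flow <- 0.6
  eps_at <- function(conc) {
    p <- pk; p$conc <- conc
    ch <- simulate_chromatogram(c(flow = flow, volume = 15,
                                  organic_init = 92, wavelength = 270),
                                peaks = list(stp = p),
                                noise_sd = 0, inj_cv = 0)
    pp <- ch$peaks_used$stp
    area <- peak_area(ch, c(pp$ret - 6 * pp$sigma - pp$tau,
                            pp$ret + 6 * pp$sigma + 7 * pp$tau))
    moles <- conc * 15 / 1000 * 1e-6 / p$molar_mass
    epsilon_from_peak_area(area, flow, 1, moles)
  }
  eps_series <- vapply(c(1, 2.5, 5, 10, 20), eps_at, numeric(1))
  expect_lt(rsd(eps_series), 1)
})

test_that("the spectrophotometric route recovers epsilon from Beer-Lambert
           data and agrees with the chromatographic route", {
  conc <- seq(1e-5, 5e-5, length.out = 5)
  expect_equal(epsilon_from_uv(conc, 7569.03 * conc), 7569.03,
               tolerance = 1e-6)
  # half path length halves absorbance at fixed epsilon
  expect_equal(epsilon_from_uv(conc, 7569.03 * 0.5 * conc, path = 0.5),
               7569.03, tolerance = 1e-6)

  # noisy absorbances stay unbiased
  set.seed(31)
  est <- replicate(200, {
    ab <- 7569.03 * conc * (1 + rnorm(5, sd = 0.01))
    epsilon_from_uv(conc, ab)
  })
  expect_lt(abs(mean(est) - 7569.03) / 7569.03, 0.005)

  # both routes from one Beer-Lambert truth agree within 1%
  pk <- stp_hi443_peaks()$stp
  pk$lambda_max <- 270
  ch <- simulate_chromatogram(c(flow = 0.6, volume = 15,
                                organic_init = 92, wavelength = 270),
                              peaks = list(stp = pk),
                              noise_sd = 0, inj_cv = 0)
  pp <- ch$peaks_used$stp
  area <- peak_area(ch, c(pp$ret - 6 * pp$sigma - pp$tau,
                          pp$ret + 6 * pp$sigma + 7 * pp$tau))
  moles <- pk$conc * 15 / 1000 * 1e-6 / pk$molar_mass
  eps_hplc <- epsilon_from_peak_area(area, 0.6, 1, moles)
  eps_uv <- epsilon_from_uv(conc, pk$epsilon * conc)
  expect_lt(abs(eps_hplc - eps_uv) / eps_uv, 0.01)
})
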