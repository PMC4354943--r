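# Dense-grid brute-force width measurement used as the oracle for the
# interpolated peak metrics.
oracle_tailing <- function(mu, sigma, tau, level = 0.05) {
  t <- seq(mu - 8 * sigma, mu + 8 * sigma + 12 * tau, length.out = 400001)
  s <- chromdoe:::emg_density(t, mu, sigma, tau)
  apex <- which.max(s)
  thr <- level * s[apex]
  left <- t[min(which(s >= thr))]
  right <- t[max(which(s >= thr))]
  (right - left) / (2 * (t[apex] - left))
}

test_that("peak area follows the mass-over-flow law of a UV detector", {
  f1 <- c(flow = 0.6, volume = 15, organic_init = 70)
  f2 <- c(flow = 1.2, volume = 15, organic_init = 70)
  a <- function(f) {
    ch <- simulate_chromatogram(f, noise_sd = 0, inj_cv = 0)
    pp <- ch$peaks_used$stp
    peak_area(ch, c(pp$ret - 6 * pp$sigma - pp$tau,
                    pp$ret + 6 * pp$sigma + 7 * pp$tau))
  }
  expect_equal(a(f2) / a(f1), 0.5, tolerance = 0.01)

  # area * flow / mass constant across a factor grid (noiseless)
  ratios <- c()
  for (flow in c(0.6, 0.8, 1.0)) for (vol in c(10, 20)) {
    ch <- simulate_chromatogram(c(flow = flow, volume = vol,
                                  organic_init = 70),
                                noise_sd = 0, inj_cv = 0)
    pp <- ch$peaks_used$stp
    ar <- peak_area(ch, c(pp$ret - 6 * pp$sigma - pp$tau,
                          pp$ret + 6 * pp$sigma + 7 * pp$tau))
    ratios <- c(ratios, ar * flow / vol)
  }
  expect_lt(diff(range(ratios)) / mean(ratios), 0.01)
})

test_that("generator determinism and input validation", {
  f <- c(flow = 0.8, volume = 15, organic_init = 70)
  c1 <- simulate_chromatogram(f, seed = 5)
  c2 <- simulate_chromatogram(f, seed = 5)
  expect_identical(c1$signal, c2$signal)
  expect_error(simulate_chromatogram(c(flow = 0, volume = 10,
                                       organic_init = 70)), "flow")
  expect_error(simulate_chromatogram(c(flow = 1, volume = -1,
                                       organic_init = 70)), "volume")
})

test_that("Gaussian closed forms: area, plates, tailing", {
  ch <- gaussian_chromatogram(amplitude = 2, center = 3.2, sigma = 0.02,
                              t_max = 6.4, dt = 0.0005)
  win <- c(3.2 - 0.2, 3.2 + 0.2)
  expect_equal(peak_area(ch, win), 2 * 0.02 * sqrt(2 * pi),
               tolerance = 1e-3)
  expect_equal(theoretical_plates(ch, win),
               5.54 * (3.2 / (2.3548 * 0.02))^2, tolerance = 0.01)
  expect_equal(usp_tailing(ch, win), 1.00, tolerance = 0.01)

  # plates invariant under joint scaling, smaller for wider peaks
  ch2 <- gaussian_chromatogram(amplitude = 2, center = 6.4, sigma = 0.04,
                               t_max = 12.8, dt = 0.001)
  expect_equal(theoretical_plates(ch2, c(6, 6.8)),
               theoretical_plates(ch, win), tolerance = 0.01)
  chw <- gaussian_chromatogram(amplitude = 2, center = 3.2, sigma = 0.04)
  expect_lt(theoretical_plates(chw, c(2.9, 3.5)),
            theoretical_plates(ch, win))

  # zero signal integrates to zero; areas add over disjoint windows
  flat <- gaussian_chromatogram(amplitude = 0)
  expect_equal(peak_area(flat, c(1, 2)), 0)
  two <- gaussian_chromatogram(amplitude = 1, center = 2, sigma = 0.05)
  two$signal <- two$signal +
    gaussian_chromatogram(amplitude = 1, center = 4, sigma = 0.05)$signal
  expect_equal(peak_area(two, c(1.5, 2.5)) + peak_area(two, c(3.5, 4.5)),
               peak_area(two, c(1.5, 4.5)), tolerance = 1e-6)
})

test_that("tailing of exponentially modified peaks matches a dense-grid
           oracle and mirrors for fronting peaks", {
  sigma <- 0.05; tau <- 0.05; mu <- 3
  t <- seq(0, 6, by = 0.001)
  s <- chromdoe:::emg_density(t, mu, sigma, tau)
  ch <- structure(list(time = t, signal = s, sampling_interval = 0.001),
                  class = "chromatogram")
  T_pkg <- usp_tailing(ch, c(2.5, 4))
  expect_gt(T_pkg, 1)
  expect_equal(T_pkg, oracle_tailing(mu, sigma, tau), tolerance = 1e-2)

  front <- structure(list(time = t, signal = rev(s),
                          sampling_interval = 0.001),
                     class = "chromatogram")
  expect_lt(usp_tailing(front, c(2, 3.5)), 1)
})

test_that("generated tailing is symmetric without a tail term and grows with
           volume and organic fraction", {
  sym <- list(peak_model("sym", ret_ref = 3.2, k_organic = 0.8,
                         sigma_rel = 0.015, tau0 = 0, tau_volume = 0,
                         tau_organic = 0, conc = 10, molar_mass = 507.4,
                         epsilon = 7569.03))
  ch <- simulate_chromatogram(c(flow = 0.6, volume = 15,
                                organic_init = 92),
                              peaks = sym, noise_sd = 0, inj_cv = 0)
  pp <- ch$peaks_used$sym
  expect_equal(usp_tailing(ch, c(pp$ret - 6 * pp$sigma,
                                 pp$ret + 6 * pp$sigma)),
               1.00, tolerance = 0.01)

  tail_at <- function(vol, org, drug = "stp") {
    ch <- simulate_chromatogram(c(flow = 0.8, volume = vol,
                                  organic_init = org),
                                noise_sd = 0, inj_cv = 0)
    pp <- ch$peaks_used[[drug]]
    usp_tailing(ch, c(pp$ret - 6 * pp$sigma - pp$tau,
                      pp$ret + 6 * pp$sigma + 7 * pp$tau))
  }
  expect_true(all(diff(sapply(c(10, 15, 20), tail_at, org = 70)) > 0))
  expect_true(all(diff(sapply(c(60, 70, 80), function(o)
    tail_at(15, o))) >= 0))
  # organic coefficient is at least as strong for the lipophilic analyte
  pk <- stp_hi443_peaks()
  expect_gte(pk$hi443$tau_organic, pk$stp$tau_organic)
})

test_that("metrics are invariant to baseline offset and time translation", {
  ch <- gaussian_chromatogram(amplitude = 1, center = 3, sigma = 0.05,
                              t_max = 6)
  off <- ch; off$signal <- off$signal + 0.3
  shf <- ch; shf$time <- shf$time + 1
  win <- c(2.5, 3.5)
  expect_equal(peak_area(off, win), peak_area(ch, win), tolerance = 1e-9)
  expect_equal(usp_tailing(off, win), usp_tailing(ch, win),
               tolerance = 1e-9)
  expect_equal(peak_area(shf, win + 1), peak_area(ch, win),
               tolerance = 1e-9)
})

test_that("two-drug fixture at the optimized conditions is well resolved", {
  ch <- simulate_chromatogram(c(flow = 0.6, volume = 18,
                                organic_init = 92), seed = 3)
  w <- lapply(ch$peaks_used, function(p)
    c(p$ret - 6 * p$sigma - p$tau, p$ret + 6 * p$sigma + 7 * p$tau))
  expect_gt(resolution(ch, w$stp, w$hi443), 2)
  # identical windows: co-eluting peak, zero resolution
  expect_equal(resolution(ch, w$stp, w$stp), 0)
})

test_that("signal-to-noise conventions and the derived detection limit", {
  # clean peak, noise confined to the baseline window: height / (2 sd) exactly
  ch <- gaussian_chromatogram(amplitude = 30, center = 3, sigma = 0.05,
                              t_max = 6)
  set.seed(1)
  noise_idx <- ch$time >= 4.5
  ch$signal[noise_idx] <- ch$signal[noise_idx] +
    rnorm(sum(noise_idx), 0, 5)
  sn <- sn_ratio(ch, c(2.5, 3.5), c(4.5, 6))
  expect_equal(sn, 3, tolerance = 0.1)

  half <- ch
  half$signal[!noise_idx] <- half$signal[!noise_idx] / 2
  expect_equal(sn_ratio(half, c(2.5, 3.5), c(4.5, 6)) / sn, 0.5,
               tolerance = 1e-6)

  clean <- gaussian_chromatogram(amplitude = 1)
  expect_error(sn_ratio(clean, c(2.9, 3.5), c(5, 6)), "degenerate")

  expect_equal(lod_from_calibration(2, 0.5), 1.5)
  expect_error(lod_from_calibration(0, 1), "slope")
})

test_that("replicate precision and recovery behave like the validated assay", {
  expect_equal(rsd(c(10, 10, 10)), 0)
  expect_error(rsd(c(5)), "at least 2")
  expect_equal(recovery(100, 100), 100)

  set.seed(4)
  areas <- replicate(30, {
    ch <- simulate_chromatogram(c(flow = 0.6, volume = 18,
                                  organic_init = 92),
                                noise_sd = 0, inj_cv = 0.01)
    pp <- ch$peaks_used$stp
    peak_area(ch, c(pp$ret - 6 * pp$sigma - pp$tau,
                    pp$ret + 6 * pp$sigma + 7 * pp$tau))
  })
  expect_gt(rsd(areas), 0.4)
  expect_lt(rsd(areas), 2)
})

test_that("batch response measurement feeds the screening stage", {
  pb <- generate_pb(5, 12, 0)
  actual <- coded_to_actual(pb, hplc_factors())
  resp <- simulate_responses(actual, seed = 2)
  expect_equal(dim(resp), c(12, 4))
  expect_true(all(resp$area_stp > 0))
  expect_true(all(resp$tailing_stp > 1))
  # Eq.2 structure: areas rise with volume, fall with flow
  expect_gt(cor(resp$area_stp, actual[, "volume"]), 0.5)
  expect_lt(cor(resp$area_stp, actual[, "flow"]), -0.5)
})
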