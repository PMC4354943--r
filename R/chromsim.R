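#' Exponentially modified Gaussian peak shape
#'
#' Unit-area EMG density evaluated on a numerically stable log scale; a
#' Gaussian when `tau` is negligible relative to `sigma`.
#'
#' @param t Time grid (minutes).
#' @param mu Gaussian center (minutes).
#' @param sigma Gaussian width (minutes, > 0).
#' @param tau Exponential tail constant (minutes, >= 0).
#' @return Density values; multiply by a peak area to get a signal.
#' @keywords internal
emg_density <- function(t, mu, sigma, tau) {
  stopifnot(sigma > 0, tau >= 0)
  if (tau < 1e-8 * sigma) return(stats::dnorm(t, mu, sigma))
  u <- sigma / tau - (t - mu) / sigma
  logf <- -log(tau) + sigma^2 / (2 * tau^2) - (t - mu) / tau +
    stats::pnorm(-u, log.p = TRUE)
  exp(logf)
}

#' Describe a chromatographic peak template
#'
#' A template captures how one analyte's peak responds to the assay factors:
#' its retention at the reference condition (flow 0.6 mL/min, initial
#' organic 92 % v/v), the retention sensitivity to the organic fraction, the
#' relative Gaussian width, the affine tail model
#' `tau = tau0 + tau_volume * (volume - 10) + tau_organic * (organic - 60)`,
#' the sample concentration, and the Beer-Lambert quantities (molar
#' extinction coefficient, molar mass, absorption maximum) that set the
#' detector response. Peak area follows `area = response * mass / flow`.
#'
#' @param name Analyte identifier.
#' @param ret_ref Retention time (min) at the reference condition.
#' @param k_organic Dimensionless retention sensitivity to the organic
#'   fraction (retention decreases as organic increases).
#' @param sigma_rel Gaussian width as a fraction of retention time.
#' @param tau0,tau_volume,tau_organic Affine tail model (min, min/uL,
#'   min per % v/v).
#' @param conc Sample concentration (ug/mL).
#' @param molar_mass g/mol.
#' @param epsilon Molar extinction coefficient (L mol^-1 cm^-1) at
#'   `lambda_max`.
#' @param lambda_max Absorption maximum (nm).
#' @param lambda_width Width (nm) of the shallow quadratic wavelength
#'   response.
#' @param path Detector path length (cm).
#' @return An object of class `peak_model`.
#' @export
peak_model <- function(name, ret_ref, k_organic, sigma_rel,
                       tau0, tau_volume, tau_organic,
                       conc, molar_mass, epsilon,
                       lambda_max = 270, lambda_width = 60, path = 1) {
  stopifnot(ret_ref > 0, sigma_rel > 0, tau0 >= 0, conc > 0,
            molar_mass > 0, epsilon > 0, path > 0)
  structure(
    list(name = name, ret_ref = ret_ref, k_organic = k_organic,
         sigma_rel = sigma_rel, tau0 = tau0, tau_volume = tau_volume,
         tau_organic = tau_organic, conc = conc, molar_mass = molar_mass,
         epsilon = epsilon, lambda_max = lambda_max,
         lambda_width = lambda_width, path = path),
    class = "peak_model"
  )
}

#' Peak templates for the two synthetic microbicide analytes
#'
#' Two resolved peaks emulating a nucleoside (early-eluting, moderately
#' lipophilic, "stp") and a strongly lipophilic non-nucleoside
#' ("hi443") analyte: the lipophilic analyte elutes later, has the larger
#' extinction coefficient, and its tailing responds more strongly to the
#' organic fraction. Extinction coefficients 7,569.03 and 17,823.67
#' L mol^-1 cm^-1 at 270 nm.
#'
#' @return Named list of two [peak_model()] objects (`stp`, `hi443`).
#' @export
stp_hi443_peaks <- function() {
  list(
    stp = peak_model("stp", ret_ref = 3.20, k_organic = 0.8,
                     sigma_rel = 0.015, tau0 = 0.065,
                     tau_volume = 0.0020, tau_organic = 0.0003,
                     conc = 10, molar_mass = 507.4, epsilon = 7569.03,
                     lambda_max = 267),
    hi443 = peak_model("hi443", ret_ref = 4.60, k_organic = 1.2,
                       sigma_rel = 0.015, tau0 = 0.060,
                       tau_volume = 0.0020, tau_organic = 0.0009,
                       conc = 5, molar_mass = 342.2, epsilon = 17823.67,
                       lambda_max = 273)
  )
}

# Deterministic peak parameters at one factor setting.
.peak_params <- function(factors, pk) {
  flow <- factors[["flow"]]
  volume <- factors[["volume"]]
  wl <- if (!is.null(factors[["wavelength"]])) factors[["wavelength"]] else 270
  org <- factors[["organic_init"]]
  org4 <- if (!is.null(factors[["organic_4min"]])) factors[["organic_4min"]] else 95
  ret <- pk$ret_ref * (0.6 / flow) * exp(-pk$k_organic * (org - 92) / 100) *
    exp(-0.1 * (org4 - 95) / 100)
  sigma <- pk$sigma_rel * ret
  tau <- pk$tau0 + pk$tau_volume * (volume - 10) + pk$tau_organic * (org - 60)
  wfac <- pmax(0.2, 1 - ((wl - pk$lambda_max) / pk$lambda_width)^2)
  mass_ug <- pk$conc * volume / 1000
  moles <- mass_ug * 1e-6 / pk$molar_mass
  # Beer-Lambert: area(AU min) = eps * path * moles / (flow in L/min)
  area <- pk$epsilon * pk$path * wfac * moles / (flow / 1000)
  list(ret = ret, sigma = sigma, tau = max(tau, 0), area = area,
       moles = moles)
}

#' Simulate a detector trace
#'
#' Sums exponentially modified Gaussian peaks, one per analyte template,
#' whose area, retention, width and tail respond to the chromatographic
#' factors: area is proportional to injected mass over flow, retention
#' shortens with flow and organic fraction, and the tail constant grows
#' affinely with injection volume and organic fraction (more steeply for
#' the lipophilic template). Additive white baseline noise and a
#' multiplicative injection-repeatability error complete the trace.
#'
#' @param factors Named vector or list in actual units: `flow` (mL/min),
#'   `volume` (uL), optionally `wavelength` (nm), `organic_init` (% v/v),
#'   `organic_4min` (% v/v).
#' @param peaks List of [peak_model()] templates (default
#'   [stp_hi443_peaks()]).
#' @param noise_sd Baseline white-noise standard deviation (AU).
#' @param inj_cv Relative standard deviation of the injected mass
#'   (default 0.01).
#' @param t_max End of the time grid (min).
#' @param dt Sampling interval (min, default 0.002).
#' @param seed Optional integer seed; the same seed gives a bit-identical
#'   trace.
#' @return Object of class `chromatogram` with `time`, `signal`,
#'   `sampling_interval` and the per-peak parameters used (`peaks_used`).
#' @examples
#' ch <- simulate_chromatogram(c(flow = 0.6, volume = 18,
#'                               organic_init = 92), seed = 3)
#' ch
#' @export
simulate_chromatogram <- function(factors, peaks = stp_hi443_peaks(),
                                  noise_sd = 1e-4, inj_cv = 0.01,
                                  t_max = 9, dt = 0.002, seed = NULL) {
  factors <- as.list(factors)
  if (is.null(factors$flow) || factors$flow <= 0)
    stop("flow must be positive", call. = FALSE)
  if (is.null(factors$volume) || factors$volume <= 0)
    stop("injection volume must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  time <- seq(0, t_max, by = dt)
  signal <- numeric(length(time))
  used <- list()
  for (pk in peaks) {
    pp <- .peak_params(factors, pk)
    area <- pp$area
    if (inj_cv > 0) area <- area * (1 + stats::rnorm(1, 0, inj_cv))
    signal <- signal + area * emg_density(time, pp$ret, pp$sigma, pp$tau)
    used[[pk$name]] <- pp
  }
  if (noise_sd > 0) signal <- signal + stats::rnorm(length(time), 0, noise_sd)
  structure(
    list(time = time, signal = signal, sampling_interval = dt,
         peaks_used = used),
    class = "chromatogram"
  )
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("Chromatogram: %d points, 0-%.3g min (dt %.4g min)\n",
              length(x$time), max(x$time), x$sampling_interval))
  if (!is.null(x$peaks_used))
    for (nm in names(x$peaks_used))
      cat(sprintf("  %s: retention %.3f min, area %.4g AU min\n",
                  nm, x$peaks_used[[nm]]$ret, x$peaks_used[[nm]]$area))
  invisible(x)
}

#' @export
plot.chromatogram <- function(x, ...) {
  plot(x$time, x$signal, type = "l", xlab = "time (min)",
       ylab = "signal (AU)", ...)
  invisible(x)
}

.window_idx <- function(chrom, window) {
  idx <- which(chrom$time >= window[1] & chrom$time <= window[2])
  if (length(idx) < 3) stop("window contains too few points", call. = FALSE)
  idx
}

# Linear baseline through the edge levels of the window; edge levels are
# averaged over ~5% of the window so baseline noise barely enters the area.
.baseline_corrected <- function(chrom, idx, edge = NULL) {
  t <- chrom$time[idx]; s <- chrom$signal[idx]
  n <- length(idx)
  if (is.null(edge)) edge <- max(5, round(0.05 * n))
  e <- min(edge, floor(n / 4))
  left <- mean(s[seq_len(max(e, 1))])
  right <- mean(s[seq(n - max(e, 1) + 1, n)])
  base <- left + (right - left) * (t - t[1]) / (t[n] - t[1])
  list(time = t, signal = s - base)
}

#' Peak area by trapezoidal integration
#'
#' Integrates the baseline-corrected signal over a time window; the
#' baseline is the straight line through the window's edge levels.
#'
#' @param chrom A `chromatogram`.
#' @param window Length-2 numeric `c(from, to)` in minutes.
#' @return Area in AU min.
#' @export
peak_area <- function(chrom, window) {
  if (window[2] <= window[1]) stop("empty window", call. = FALSE)
  bc <- .baseline_corrected(chrom, .window_idx(chrom, window))
  sum(diff(bc$time) * (utils::head(bc$signal, -1) + utils::tail(bc$signal, -1)) / 2)
}

# Interpolated left/right crossings of `level` around the apex.
.width_at <- function(t, s, apex_i, level) {
  li <- apex_i
  while (li > 1 && s[li] > level) li <- li - 1
  if (s[li] > level) return(NULL)
  ri <- apex_i
  n <- length(s)
  while (ri < n && s[ri] > level) ri <- ri + 1
  if (s[ri] > level) return(NULL)
  tl <- t[li] + (level - s[li]) / (s[li + 1] - s[li]) * (t[li + 1] - t[li])
  tr <- t[ri - 1] + (level - s[ri - 1]) / (s[ri] - s[ri - 1]) *
    (t[ri] - t[ri - 1])
  c(left = tl, right = tr)
}

.peak_geometry <- function(chrom, window) {
  bc <- .baseline_corrected(chrom, .window_idx(chrom, window))
  apex_i <- which.max(bc$signal)
  height <- bc$signal[apex_i]
  if (height <= 0) stop("no peak found in window", call. = FALSE)
  list(time = bc$time, signal = bc$signal, apex_i = apex_i,
       apex_t = bc$time[apex_i], height = height)
}

#' USP tailing factor
#'
#' `T = W / (2 f)` where `W` is the full peak width at 5% of the peak
#' height and `f` the front (apex-to-leading-edge) half-width, both by
#' linear interpolation on the sampled trace. `T = 1` for a symmetric peak.
#'
#' @inheritParams peak_area
#' @return The tailing factor.
#' @export
usp_tailing <- function(chrom, window) {
  g <- .peak_geometry(chrom, window)
  w <- .width_at(g$time, g$signal, g$apex_i, 0.05 * g$height)
  if (is.null(w))
    stop("peak truncated by window: 5% level not reached", call. = FALSE)
  unname((w["right"] - w["left"]) / (2 * (g$apex_t - w["left"])))
}

#' Theoretical plate count
#'
#' Half-height formula `N = 5.54 (t_R / W_0.5)^2`.
#'
#' @inheritParams peak_area
#' @return Plate count `N`.
#' @export
theoretical_plates <- function(chrom, window) {
  g <- .peak_geometry(chrom, window)
  w <- .width_at(g$time, g$signal, g$apex_i, 0.5 * g$height)
  if (is.null(w))
    stop("peak truncated by window: half height not reached", call. = FALSE)
  unname(5.54 * (g$apex_t / (w["right"] - w["left"]))^2)
}

#' Resolution between two peaks
#'
#' `Rs = 2 (t_R2 - t_R1) / (W_b1 + W_b2)` with base widths estimated from
#' half-height widths times 1.699 (the Gaussian tangent relation).
#'
#' @param chrom A `chromatogram`.
#' @param window1,window2 Time windows of the earlier and later peak.
#' @return Resolution `Rs`.
#' @export
resolution <- function(chrom, window1, window2) {
  g1 <- .peak_geometry(chrom, window1)
  g2 <- .peak_geometry(chrom, window2)
  if (g2$apex_t < g1$apex_t)
    stop("window2 must contain the later-eluting peak", call. = FALSE)
  if (g2$apex_t == g1$apex_t) return(0)
  w1 <- .width_at(g1$time, g1$signal, g1$apex_i, 0.5 * g1$height)
  w2 <- .width_at(g2$time, g2$signal, g2$apex_i, 0.5 * g2$height)
  if (is.null(w1) || is.null(w2))
    stop("peak truncated by window", call. = FALSE)
  wb1 <- 1.699 * (w1["right"] - w1["left"])
  wb2 <- 1.699 * (w2["right"] - w2["left"])
  unname(2 * (g2$apex_t - g1$apex_t) / (wb1 + wb2))
}

#' Signal-to-noise ratio
#'
#' Peak height over twice the baseline noise standard deviation estimated
#' from a peak-free window (the 2-SD convention).
#'
#' @param chrom A `chromatogram`.
#' @param peak_window Window containing the peak.
#' @param noise_window Peak-free window used for the noise estimate.
#' @return The S/N ratio.
#' @export
sn_ratio <- function(chrom, peak_window, noise_window) {
  noise <- chrom$signal[.window_idx(chrom, noise_window)]
  nsd <- stats::sd(noise)
  if (nsd == 0) stop("noise estimate is zero: S/N is degenerate",
                     call. = FALSE)
  g <- .peak_geometry(chrom, peak_window)
  g$height / (2 * nsd)
}

#' Limit of detection from calibration slope and baseline noise
#'
#' The concentration whose peak height reaches a 3:1 signal-to-noise ratio
#' under the 2-SD noise convention: `LOD = 3 * 2 * noise_sd / slope`.
#'
#' @param slope Calibration slope (signal height per concentration unit).
#' @param noise_sd Baseline noise standard deviation (signal units).
#' @return Concentration at S/N = 3.
#' @export
lod_from_calibration <- function(slope, noise_sd) {
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  3 * 2 * noise_sd / slope
}

#' Percent relative standard deviation
#'
#' @param values At least two numeric values with non-zero mean.
#' @return `100 * sd / mean`.
#' @export
rsd <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Percent recovery
#'
#' @param measured Measured amount or concentration.
#' @param nominal Nominal (true) amount, > 0.
#' @return `100 * measured / nominal`.
#' @export
recovery <- function(measured, nominal) {
  if (any(nominal <= 0)) stop("nominal must be positive", call. = FALSE)
  100 * measured / nominal
}

#' Measure the four assay responses over a design
#'
#' For each run of a design (in actual units) a chromatogram is simulated
#' and the peak areas and USP tailing factors of both analytes are
#' measured, yielding the response table that feeds the response-surface
#' fits. Areas are reported in mAU s.
#'
#' @param design_actual Run-by-factor matrix in actual units; columns must
#'   include `flow`, `volume` and `organic_init`, and may include
#'   `wavelength` and `organic_4min`.
#' @param fixed Named vector of factor levels to hold constant for columns
#'   absent from `design_actual` (default wavelength 270 nm, final organic
#'   95 % v/v).
#' @param peaks,noise_sd,inj_cv,dt Passed to [simulate_chromatogram()].
#' @param seed Optional integer seed for the whole batch.
#' @return Data frame with columns `area_stp`, `area_hi443`, `tailing_stp`,
#'   `tailing_hi443`, one row per run.
#' @export
simulate_responses <- function(design_actual,
                               fixed = c(wavelength = 270, organic_4min = 95),
                               peaks = stp_hi443_peaks(),
                               noise_sd = 1e-4, inj_cv = 0.01, dt = 0.002,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design_actual <- as.matrix(design_actual)
  n <- nrow(design_actual)
  out <- matrix(NA_real_, n, 4)
  colnames(out) <- c("area_stp", "area_hi443", "tailing_stp", "tailing_hi443")
  for (i in seq_len(n)) {
    f <- as.list(design_actual[i, ])
    for (nm in names(fixed)) if (is.null(f[[nm]])) f[[nm]] <- fixed[[nm]]
    ch <- simulate_chromatogram(f, peaks = peaks, noise_sd = noise_sd,
                                inj_cv = inj_cv, dt = dt)
    win <- lapply(ch$peaks_used, function(pp)
      c(pp$ret - 6 * pp$sigma - pp$tau,
        pp$ret + 6 * pp$sigma + 7 * pp$tau))
    out[i, "area_stp"] <- peak_area(ch, win$stp) * 60000   # AU min -> mAU s
    out[i, "area_hi443"] <- peak_area(ch, win$hi443) * 60000
    out[i, "tailing_stp"] <- usp_tailing(ch, win$stp)
    out[i, "tailing_hi443"] <- usp_tailing(ch, win$hi443)
  }
  as.data.frame(out)
}
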