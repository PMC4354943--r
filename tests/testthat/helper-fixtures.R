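# Shared fixtures for the test suite. Everything is generated in code.

# Factor specs of the synthetic HPLC study, subset used by the BB stage.
bb_specs <- function() hplc_factors()[c("flow", "volume", "organic_init")]

# A hand-built rsm_fit whose predictions are exactly `mu` with residual
# RMSE `sigma`: an intercept-only main-effects model over k factors. Used
# as a harness so Monte Carlo defect rates can be checked against
# closed-form normal exceedance probabilities.
constant_model <- function(mu, sigma, k = 3) {
  terms <- c("(Intercept)", paste0("x", seq_len(k)))
  p <- length(terms)
  structure(
    list(form = "main_effects", terms = terms,
         coefficients = stats::setNames(c(mu, rep(0, k)), terms),
         standard_errors = stats::setNames(rep(1, p), terms),
         t_ratios = stats::setNames(rep(0, p), terms),
         residual_df = 5L, rmse = sigma, r2 = 0,
         fitted = NULL, residuals = NULL,
         n_factors = k, factor_names = paste0("x", seq_len(k)),
         XtXinv = diag(p)),
    class = "rsm_fit")
}

# Unit-variance coded factor specs: sim_sd chosen so the coded draw has
# standard deviation `sd_coded` per factor.
coded_specs <- function(k, sd_coded) {
  lapply(seq_len(k), function(j)
    factor_spec(paste0("x", j), "", -1, 0, 1, sim_sd = sd_coded))
}

# Exact combinatorial check of Latin-hypercube stratification: sorted into
# n equal bins, each bin holds exactly one point, per column.
strata_ok <- function(X, lower, upper) {
  n <- nrow(X)
  all(vapply(seq_len(ncol(X)), function(j) {
    u <- (X[, j] - lower) / (upper - lower)
    all(sort(floor(u * n)) == 0:(n - 1))
  }, logical(1)))
}

# A noiseless Gaussian peak chromatogram built directly on a fine grid.
gaussian_chromatogram <- function(amplitude = 1, center = 3.2, sigma = 0.05,
                                  t_max = 6.4, dt = 0.001) {
  t <- seq(0, t_max, by = dt)
  structure(list(time = t,
                 signal = amplitude * exp(-(t - center)^2 / (2 * sigma^2)),
                 sampling_interval = dt),
            class = "chromatogram")
}

# One reduced-size pipeline run shared by the pipeline and acceptance
# tests (computed once per test session).
.pipeline_cache <- new.env(parent = emptyenv())
cached_pipeline <- function(seed = 7) {
  key <- paste0("seed", seed)
  if (is.null(.pipeline_cache[[key]])) {
    cf <- default_pipeline_config()
    cf$simulation$n_runs <- 4000
    cf$simulation$n_points <- 25
    cf$simulation$runs_per_point <- 800
    .pipeline_cache[[key]] <- run_pipeline(cf, seed = seed)
  }
  .pipeline_cache[[key]]
}
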