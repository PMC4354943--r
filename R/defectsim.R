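#' Specify a Monte Carlo defect-rate simulation
#'
#' Bundles everything the simulator needs apart from the fitted response
#' models: the factor specifications (whose `sim_sd` fields give the random
#' variation of each factor in actual units), the operating setpoint in
#' coded units, the specification limits per response, the number of runs
#' and the noise/seed settings.
#'
#' @param factors List of [factor_spec()], order-matched to the models'
#'   factor space.
#' @param setpoint Coded setpoint vector (length = number of factors).
#' @param spec_limits Named list; each element is a list with optional `lsl`
#'   and/or `usl` members. At least one response must carry a limit.
#' @param n_runs Number of Monte Carlo runs (default 15000).
#' @param response_noise If `TRUE` (default) each predicted response gets
#'   additive normal noise with the model's residual RMSE, representing the
#'   assay's inherent variability.
#' @param truncate If `TRUE` (default) factor draws are rejected outside the
#'   coded design range `[-1, 1]`, i.e. factors vary randomly within their
#'   specification range.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(factors, setpoint, spec_limits, n_runs = 15000,
                        response_noise = TRUE, truncate = TRUE, seed = NULL) {
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  if (length(setpoint) != length(factors))
    stop("setpoint length must match the number of factors", call. = FALSE)
  has_limit <- vapply(spec_limits, function(l)
    !is.null(l$lsl) || !is.null(l$usl), logical(1))
  if (length(spec_limits) == 0 || !any(has_limit))
    stop("at least one response must have a specification limit",
         call. = FALSE)
  sds <- vapply(factors, `[[`, numeric(1), "sim_sd")
  if (any(sds < 0)) stop("sim_sd must be non-negative", call. = FALSE)
  structure(
    list(factors = factors, setpoint = as.numeric(setpoint),
         spec_limits = spec_limits, n_runs = as.integer(n_runs),
         response_noise = isTRUE(response_noise),
         truncate = isTRUE(truncate), seed = seed),
    class = "defect_spec"
  )
}

# Draw n coded factor vectors around a coded setpoint; sd is converted from
# actual units per factor; optional rejection keeps draws inside [-1, 1].
.draw_factors <- function(spec, n, setpoint = spec$setpoint) {
  k <- length(spec$factors)
  half <- vapply(spec$factors, function(s) (s$high - s$low) / 2, numeric(1))
  sd_coded <- vapply(spec$factors, `[[`, numeric(1), "sim_sd") / half
  X <- matrix(rep(setpoint, each = n), nrow = n)
  for (j in seq_len(k)) {
    if (sd_coded[j] == 0) next
    x <- stats::rnorm(n, setpoint[j], sd_coded[j])
    if (spec$truncate) {
      bad <- which(x < -1 | x > 1)
      while (length(bad) > 0) {
        x[bad] <- stats::rnorm(length(bad), setpoint[j], sd_coded[j])
        bad <- bad[x[bad] < -1 | x[bad] > 1]
      }
    }
    X[, j] <- x
  }
  X
}

# Run-by-response matrix of defect indicators for drawn factor settings.
.defect_indicators <- function(models, spec, X) {
  n <- nrow(X)
  resp <- names(spec$spec_limits)
  viol <- matrix(FALSE, nrow = n, ncol = length(resp),
                 dimnames = list(NULL, resp))
  for (r in resp) {
    m <- models[[r]]
    if (is.null(m)) stop(sprintf("no model named '%s'", r), call. = FALSE)
    y <- predict(m, X)
    if (spec$response_noise && m$rmse > 0)
      y <- y + stats::rnorm(n, 0, m$rmse)
    lim <- spec$spec_limits[[r]]
    bad <- rep(FALSE, n)
    if (!is.null(lim$lsl)) bad <- bad | (y < lim$lsl)
    if (!is.null(lim$usl)) bad <- bad | (y > lim$usl)
    viol[, r] <- bad
  }
  viol
}

#' Monte Carlo defect-rate estimation
#'
#' Draws `n_runs` random factor settings around the setpoint (normal per
#' factor, standard deviation from `sim_sd`, optionally truncated to the
#' coded design range), predicts every response with its fitted model (plus
#' optional RMSE noise), and counts a run as defective when any response
#' falls outside its specification limits. The defect rate is the defective
#' fraction m/n.
#'
#' @param models Named list of `rsm_fit` objects covering every response in
#'   the spec limits.
#' @param spec A [defect_spec()].
#' @return An object of class `defect_report`: `overall_dr`, `per_response_dr`
#'   (named vector), `m`, `n`, `ci` (exact binomial 95% interval on the
#'   overall rate) and `dpm` (defects per million).
#' @examples
#' bb <- generate_bb(3, 3)
#' y <- 1.1 + 0.2 * bb$coded[, 1]
#' fit <- fit_rsm(bb, y + rnorm(15, sd = 0.01), "full_quadratic")
#' fs <- hplc_factors()[c("flow", "volume", "organic_init")]
#' sp <- defect_spec(fs, c(0, 0, 0), list(tailing = list(usl = 1.5)),
#'                   n_runs = 2000, seed = 1)
#' simulate_defect_rate(list(tailing = fit), sp)
#' @export
simulate_defect_rate <- function(models, spec) {
  stopifnot(inherits(spec, "defect_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  X <- .draw_factors(spec, spec$n_runs)
  viol <- .defect_indicators(models, spec, X)
  any_bad <- rowSums(viol) > 0
  m <- sum(any_bad)
  n <- spec$n_runs
  ci <- stats::binom.test(m, n)$conf.int
  structure(
    list(overall_dr = m / n,
         per_response_dr = colMeans(viol),
         m = m, n = n, ci = as.numeric(ci),
         dpm = defects_per_million(m / n)),
    class = "defect_report"
  )
}

#' @export
print.defect_report <- function(x, ...) {
  cat(sprintf("Defect rate: %.4g (%d / %d runs; %.0f dpm)\n",
              x$overall_dr, x$m, x$n, x$dpm))
  cat(sprintf("95%% CI [%.4g, %.4g]\n", x$ci[1], x$ci[2]))
  if (length(x$per_response_dr)) {
    cat("Per-response defect rates:\n")
    for (r in names(x$per_response_dr))
      cat(sprintf("  %s: %.4g\n", r, x$per_response_dr[[r]]))
  }
  invisible(x)
}

#' Convert a defect rate to defects per million
#'
#' @param dr Defect rate in `[0, 1]`.
#' @return `dr * 1e6`.
#' @examples
#' defects_per_million(0.00077) # 770
#' @export
defects_per_million <- function(dr) {
  if (any(dr < 0 | dr > 1)) stop("dr must lie in [0, 1]", call. = FALSE)
  dr * 1e6
}

#' Share of the overall defect rate attributable to one response
#'
#' @param component_dr Defect rate of a single response.
#' @param overall_dr Overall defect rate (> 0, >= `component_dr`).
#' @return Percent share `100 * component_dr / overall_dr`.
#' @examples
#' defect_share(0.0189, 0.0196) # 96.43
#' @export
defect_share <- function(component_dr, overall_dr) {
  if (overall_dr <= 0)
    stop("share is undefined for overall_dr = 0", call. = FALSE)
  if (component_dr < 0 || component_dr > overall_dr)
    stop("component_dr must lie in [0, overall_dr]", call. = FALSE)
  100 * component_dr / overall_dr
}

#' Defect-rate profile along one factor
#'
#' The defect profiler: for each grid value, the chosen factor is held fixed
#' while all other factors vary randomly around the setpoint, and the defect
#' rate is re-estimated. The resulting curve shows how sensitive the defect
#' rate is to that factor's setting.
#'
#' @param models Named list of `rsm_fit` objects.
#' @param spec A [defect_spec()]; `spec$n_runs` runs are used per grid value.
#' @param factor Name of the factor to sweep (must match a
#'   `factor_spec$name`).
#' @param grid Coded values at which to fix the factor.
#' @return A data frame with columns `value` (coded grid) and `dr`.
#' @export
defect_profile <- function(models, spec, factor, grid) {
  stopifnot(inherits(spec, "defect_spec"))
  fnames <- vapply(spec$factors, `[[`, character(1), "name")
  j <- match(factor, fnames)
  if (is.na(j)) stop(sprintf("unknown factor '%s'", factor), call. = FALSE)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  fixed <- spec
  fixed$factors[[j]]$sim_sd <- 0
  dr <- vapply(grid, function(g) {
    sp <- fixed$setpoint
    sp[j] <- g
    X <- .draw_factors(fixed, fixed$n_runs, setpoint = sp)
    viol <- .defect_indicators(models, fixed, X)
    mean(rowSums(viol) > 0)
  }, numeric(1))
  data.frame(value = grid, dr = dr)
}
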