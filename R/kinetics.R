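#' Construct an in vitro release profile
#'
#' @param time Sampling times (minutes), strictly increasing, first >= 0.
#' @param cumulative Cumulative fraction released, non-decreasing; in
#'   `[0, 1]` on the fractional scale.
#' @param scale `"fraction"` (default) or `"amount"`.
#' @param monotone_tol Largest decrease between consecutive points to
#'   tolerate (default 0). Measured profiles carry sampling noise, so small
#'   dips can be allowed without accepting a genuinely decreasing profile.
#' @return Object of class `release_profile`.
#' @examples
#' release_profile(c(0, 15, 30, 60, 150, 300),
#'                 c(0, 0.14, 0.17, 0.20, 0.26, 0.31))
#' @export
release_profile <- function(time, cumulative,
                            scale = c("fraction", "amount"),
                            monotone_tol = 0) {
  scale <- match.arg(scale)
  if (length(time) != length(cumulative))
    stop("time and cumulative must have equal length", call. = FALSE)
  if (any(diff(time) <= 0) || time[1] < 0)
    stop("time must be strictly increasing and start at >= 0", call. = FALSE)
  if (any(diff(cumulative) < -monotone_tol))
    stop("cumulative release must be non-decreasing", call. = FALSE)
  if (scale == "fraction" && any(cumulative < 0 | cumulative > 1))
    stop("fractional release must lie in [0, 1]", call. = FALSE)
  structure(list(time = time, cumulative = cumulative, scale = scale),
            class = "release_profile")
}

#' Fit one release-kinetics model
#'
#' Linearized least-squares fits of the four classic models:
#' zero order (`Q` vs `t`, constant `K0` = slope), first order
#' (`ln(1 - Q)` vs `t`, `K1` = -slope), Higuchi (`Q` vs `sqrt(t)`,
#' `KH` = slope), and Korsmeyer-Peppas (`log10 Q` vs `log10 t` restricted
#' to `Q <= 0.6`, exponent `n` = slope, `k = 10^intercept`). Time-zero
#' points are dropped from the log-based fits; r2 is reported on the
#' fitted linearization.
#'
#' @param profile A [release_profile()] (fractional scale required for the
#'   first-order and Peppas models).
#' @param model One of `"zero"`, `"first"`, `"higuchi"`, `"peppas"`.
#' @return Object of class `kinetic_fit` with `model`, `parameters`
#'   (named list), and `r2`.
#' @examples
#' t <- c(0, 15, 30, 60, 150, 300)
#' q <- 0.07 * t^0.26
#' fit_release(release_profile(t, pmin(q, 1)), "peppas")
#' @export
fit_release <- function(profile,
                        model = c("zero", "first", "higuchi", "peppas")) {
  model <- match.arg(model)
  stopifnot(inherits(profile, "release_profile"))
  t <- profile$time
  q <- profile$cumulative

  if (model %in% c("first", "peppas")) {
    if (profile$scale != "fraction")
      stop("log-based models need the fractional release scale",
           call. = FALSE)
    keep <- t > 0
    if (model == "peppas") keep <- keep & q > 0 & q <= 0.6
    if (model == "first") keep <- keep & q < 1
    t <- t[keep]; q <- q[keep]
  }
  if (length(t) < 3)
    stop("fewer than 3 usable points after filtering", call. = FALSE)

  xy <- switch(model,
    zero = list(x = t, y = q),
    first = list(x = t, y = log(1 - q)),
    higuchi = list(x = sqrt(t), y = q),
    peppas = list(x = log10(t), y = log10(q))
  )
  fit <- stats::lm(y ~ x, data = xy)
  sl <- unname(stats::coef(fit)[2])
  ic <- unname(stats::coef(fit)[1])
  tss <- sum((xy$y - mean(xy$y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  parameters <- switch(model,
    zero = list(K0 = sl, intercept = ic),
    first = list(K1 = -sl, intercept = ic),
    higuchi = list(KH = sl, intercept = ic),
    peppas = list(k = 10^ic, n = sl)
  )
  structure(list(model = model, parameters = parameters, r2 = r2,
                 n_points = length(t)),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  pars <- paste(names(x$parameters),
                signif(unlist(x$parameters), 4), sep = " = ",
                collapse = ", ")
  cat(sprintf("Release kinetics (%s): %s; r2 = %.4f (%d points)\n",
              x$model, pars, x$r2, x$n_points))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) unlist(object$parameters)

#' Select the best-fitting release model
#'
#' Picks the fit with the highest r2; ties are broken in favour of the
#' model with fewer estimated parameters (zero/first/Higuchi before
#' Peppas).
#'
#' @param fits List of `kinetic_fit` objects (>= 2), or a named numeric
#'   vector of r2 values with names among the model names.
#' @return The winning model name.
#' @examples
#' select_best_model(c(zero = 0.52, first = 0.83, higuchi = 0.46,
#'                     peppas = 0.65)) # "first"
#' @export
select_best_model <- function(fits) {
  n_par <- c(zero = 1, first = 1, higuchi = 1, peppas = 2)
  if (is.numeric(fits)) {
    r2 <- fits
    models <- names(fits)
  } else {
    if (length(fits) < 2) stop("need at least 2 fits", call. = FALSE)
    r2 <- vapply(fits, `[[`, numeric(1), "r2")
    models <- vapply(fits, `[[`, character(1), "model")
  }
  if (length(r2) < 2) stop("need at least 2 fits", call. = FALSE)
  ord <- order(-r2, n_par[models])
  models[ord[1]]
}

#' Classify the drug-release mechanism from the Peppas exponent
#'
#' Fickian diffusion for `n <= 0.5`, anomalous transport for
#' `0.5 < n < 1`, case-II transport at `n = 1` (within 1e-9), and super
#' case-II transport for `n > 1`.
#'
#' @param n Release exponent (> 0).
#' @return One of `"fickian"`, `"anomalous"`, `"case_II"`,
#'   `"super_case_II"`.
#' @examples
#' classify_mechanism(0.26) # "fickian"
#' @export
classify_mechanism <- function(n) {
  if (n <= 0) stop("the release exponent must be positive", call. = FALSE)
  if (abs(n - 1) <= 1e-9) return("case_II")
  if (n <= 0.5) return("fickian")
  if (n < 1) return("anomalous")
  "super_case_II"
}
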