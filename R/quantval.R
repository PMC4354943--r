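#' Fit a calibration curve
#'
#' Ordinary least squares of detector response on concentration, with or
#' without a free intercept. The zero-intercept form is the convention for
#' Beer-Lambert extinction-coefficient estimation.
#'
#' @param conc Concentrations (>= 3 distinct non-negative values).
#' @param response Measured responses, same length.
#' @param zero_intercept Constrain the intercept to zero (default `FALSE`).
#' @return Object of class `calibration_curve` with `slope`, `intercept`,
#'   `r2` and `range`.
#' @examples
#' cal <- calibration_fit(1:5, 2 * (1:5))
#' cal$slope # 2
#' @export
calibration_fit <- function(conc, response, zero_intercept = FALSE) {
  if (length(conc) < 3) stop("need at least 3 calibration points",
                             call. = FALSE)
  if (length(conc) != length(response))
    stop("conc and response must have equal length", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be non-negative",
                          call. = FALSE)
  if (length(unique(conc)) < 2)
    stop("calibration needs at least two distinct concentrations",
         call. = FALSE)
  fit <- if (zero_intercept) stats::lm(response ~ conc + 0)
         else stats::lm(response ~ conc)
  cf <- stats::coef(fit)
  slope <- unname(cf[["conc"]])
  intercept <- if (zero_intercept) 0 else unname(cf[[1]])
  # r2 about the mean in both cases, so the two forms are comparable
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((response - mean(response))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  structure(
    list(slope = slope, intercept = intercept, r2 = r2,
         range = range(conc), zero_intercept = zero_intercept),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: response = %.6g * conc %s %.6g (r2 %.5f)\n",
              x$slope, if (x$intercept < 0) "-" else "+", abs(x$intercept),
              x$r2))
  cat(sprintf("Range: %.4g to %.4g\n", x$range[1], x$range[2]))
  invisible(x)
}

#' Inverse prediction from a calibration curve
#'
#' @param cal A `calibration_curve`.
#' @param response Measured response value(s).
#' @return Estimated concentration(s).
#' @export
inverse_predict <- function(cal, response) {
  stopifnot(inherits(cal, "calibration_curve"))
  if (cal$slope == 0) stop("zero slope: inverse prediction undefined",
                           call. = FALSE)
  (response - cal$intercept) / cal$slope
}

#' Percent encapsulation efficiency
#'
#' @param measured_drug Drug amount recovered from the carrier.
#' @param theoretical_drug Drug amount loaded (> 0, same units).
#' @return `100 * measured / theoretical` (% w/w).
#' @examples
#' encapsulation_efficiency(4.7, 5) # 94
#' @export
encapsulation_efficiency <- function(measured_drug, theoretical_drug) {
  if (any(theoretical_drug <= 0))
    stop("theoretical amount must be positive", call. = FALSE)
  if (any(measured_drug < 0))
    stop("measured amount must be non-negative", call. = FALSE)
  100 * measured_drug / theoretical_drug
}

#' Molar extinction coefficient from a chromatographic peak area
#'
#' With a UV detector, `Ab(t) = epsilon * l * c(t)`, and the injected moles
#' equal the concentration integral times the volumetric flow:
#' `moles = integral(c) * flow`. Eliminating the integral gives
#' `epsilon = area * flow / (path * moles)` once units are made consistent:
#' area is AU min and flow mL/min, so their product is AU mL = AU * 1e-3 L,
#' hence the division by 1000 to return L mol^-1 cm^-1.
#'
#' @param area Peak area (AU min).
#' @param flow Flow rate (mL/min).
#' @param path Detector path length (cm).
#' @param moles Injected amount (mol).
#' @return Extinction coefficient (L mol^-1 cm^-1).
#' @export
epsilon_from_peak_area <- function(area, flow, path, moles) {
  if (any(c(area, flow, path, moles) <= 0))
    stop("all arguments must be positive", call. = FALSE)
  area * (flow / 1000) / (path * moles)
}

#' Molar extinction coefficient from a UV calibration curve
#'
#' Zero-intercept regression of absorbance on molar concentration; the
#' slope divided by the path length is the extinction coefficient.
#'
#' @param conc Molar concentrations (mol/L), >= 3 points.
#' @param Ab Absorbances (AU).
#' @param path Path length (cm, default 1).
#' @return Extinction coefficient (L mol^-1 cm^-1).
#' @examples
#' conc <- seq(1e-5, 5e-5, length.out = 5)
#' epsilon_from_uv(conc, 7569.03 * conc) # 7569.03
#' @export
epsilon_from_uv <- function(conc, Ab, path = 1) {
  if (path <= 0) stop("path must be positive", call. = FALSE)
  cal <- calibration_fit(conc, Ab, zero_intercept = TRUE)
  cal$slope / path
}
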