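#' Define a factor for an experimental design
#'
#' A factor specification ties a coded design axis to its actual scale:
#' coded -1 maps to `low`, 0 to `mid` and +1 to `high`. `sim_sd` is the
#' standard deviation (in actual units) used when the factor is varied
#' randomly in Monte Carlo defect-rate simulations.
#'
#' @param name Factor identifier.
#' @param unit Unit string (free text, e.g. `"mL/min"`).
#' @param low,mid,high Actual-scale levels; must satisfy `low < mid < high`.
#' @param sim_sd Non-negative simulation standard deviation in actual units.
#'
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("flow", "mL/min", 0.6, 0.8, 1.0, sim_sd = 0.1 / 3)
#' @export
factor_spec <- function(name, unit, low, mid, high, sim_sd = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!(is.numeric(low) && is.numeric(mid) && is.numeric(high)))
    stop("factor levels must be numeric", call. = FALSE)
  if (!(low < mid && mid < high))
    stop(sprintf("factor '%s': levels must satisfy low < mid < high", name),
         call. = FALSE)
  if (sim_sd < 0) stop("sim_sd must be non-negative", call. = FALSE)
  structure(
    list(name = name, unit = unit, low = low, mid = mid, high = high,
         sim_sd = sim_sd),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor %s [%s]: low %g, mid %g, high %g (sim sd %g)\n",
              x$name, x$unit, x$low, x$mid, x$high, x$sim_sd))
  invisible(x)
}

#' Factor specifications for the two-microbicide HPLC study
#'
#' The five chromatographic factors used throughout the examples and the
#' synthetic pipeline: mobile-phase flow rate, injection volume, detection
#' wavelength, and the acetonitrile volume fraction at the start and at four
#' minutes of the gradient. Simulation standard deviations default to the
#' method-robustness perturbations (flow +/- 0.1 mL/min, wavelength +/- 2 nm,
#' initial organic +/- 2 % v/v) read as three-sigma excursions; the injection
#' volume uses +/- 0.5 uL, a typical autosampler precision.
#'
#' @return A named list of [factor_spec()] objects
#'   (`flow`, `volume`, `wavelength`, `organic_init`, `organic_4min`).
#' @examples
#' specs <- hplc_factors()
#' specs$flow
#' @export
hplc_factors <- function() {
  list(
    flow         = factor_spec("flow", "mL/min", 0.6, 0.8, 1.0,
                               sim_sd = 0.1 / 3),
    volume       = factor_spec("volume", "uL", 10, 15, 20, sim_sd = 0.5 / 3),
    wavelength   = factor_spec("wavelength", "nm", 265, 270, 275,
                               sim_sd = 2 / 3),
    organic_init = factor_spec("organic_init", "% v/v", 60, 70, 80,
                               sim_sd = 2 / 3),
    organic_4min = factor_spec("organic_4min", "% v/v", 85, 90, 95,
                               sim_sd = 2 / 3)
  )
}

new_design_matrix <- function(coded, family, n_center, factor_names) {
  coded <- as.matrix(coded)
  dimnames(coded) <- list(NULL, factor_names)
  structure(
    list(family = family, coded = coded, n_center = n_center,
         factor_names = factor_names),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("%s design: %d runs x %d factors (%d center point%s)\n",
              x$family, nrow(x$coded), ncol(x$coded), x$n_center,
              if (x$n_center == 1L) "" else "s"))
  print(x$coded)
  invisible(x)
}

# Canonical 12-run Plackett-Burman cyclic generator row.
.pb12_generator <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)

#' Generate a Plackett-Burman screening design
#'
#' Builds the canonical two-level Plackett-Burman design by cyclic shifts of
#' the generator row plus a final all-low run, takes the first `n_factors`
#' columns, and appends `n_center` all-mid (coded zero) runs. Over the base
#' runs every column sums to zero and any two columns are orthogonal, so up
#' to `base_runs - 1` main effects can be screened.
#'
#' @param n_factors Number of factors (at most `base_runs - 1`).
#' @param base_runs Number of two-level runs; must be a multiple of 4
#'   (only the 12-run construction is built in).
#' @param n_center Number of center points appended after the base runs.
#' @param shuffle_seed Optional integer; if given, the run order is shuffled
#'   reproducibly (the design itself is unchanged).
#'
#' @return A `design_matrix` with `family = "PB"`.
#' @examples
#' pb <- generate_pb(5, 12, 3)
#' crossprod(pb$coded[1:12, ]) # 12 * diag(5)
#' @export
generate_pb <- function(n_factors, base_runs = 12, n_center = 0,
                        shuffle_seed = NULL) {
  if (base_runs %% 4 != 0)
    stop("base_runs must be a multiple of 4", call. = FALSE)
  if (base_runs != 12)
    stop("only the canonical 12-run Plackett-Burman construction is built in",
         call. = FALSE)
  if (n_factors > base_runs - 1)
    stop(sprintf("a %d-run Plackett-Burman design holds at most %d factors",
                 base_runs, base_runs - 1), call. = FALSE)
  stopifnot(n_factors >= 1, n_center >= 0)

  g <- .pb12_generator
  full <- matrix(0, nrow = 12, ncol = 11)
  for (i in 1:11) full[i, ] <- g[((seq_len(11) - i) %% 11) + 1]
  full[12, ] <- -1
  coded <- full[, seq_len(n_factors), drop = FALSE]
  if (!is.null(shuffle_seed)) {
    ord <- local({ set.seed(shuffle_seed); sample.int(nrow(coded)) })
    coded <- coded[ord, , drop = FALSE]
  }
  if (n_center > 0)
    coded <- rbind(coded, matrix(0, nrow = n_center, ncol = n_factors))
  new_design_matrix(coded, "PB", n_center, paste0("x", seq_len(n_factors)))
}

#' Generate a Box-Behnken response-surface design
#'
#' For three factors this is the 12 edge midpoints of the coded cube,
#' `(+/-1, +/-1, 0)` and permutations, plus `n_center` center runs: 15 runs
#' with three centers, as used to fit a full quadratic model. For more than
#' three factors the same edge-midpoint construction is applied to every
#' factor pair.
#'
#' @param n_factors Number of factors (>= 3).
#' @param n_center Number of center points appended after the edge midpoints.
#'
#' @return A `design_matrix` with `family = "BB"`.
#' @examples
#' bb <- generate_bb(3, 3)
#' nrow(bb$coded) # 15
#' @export
generate_bb <- function(n_factors, n_center = 0) {
  if (n_factors < 3)
    stop("a Box-Behnken design needs at least 3 factors", call. = FALSE)
  stopifnot(n_center >= 0)
  pairs <- utils::combn(n_factors, 2)
  blocks <- lapply(seq_len(ncol(pairs)), function(j) {
    m <- matrix(0, nrow = 4, ncol = n_factors)
    m[, pairs[1, j]] <- c(-1, -1, 1, 1)
    m[, pairs[2, j]] <- c(-1, 1, -1, 1)
    m
  })
  coded <- do.call(rbind, blocks)
  if (n_center > 0)
    coded <- rbind(coded, matrix(0, nrow = n_center, ncol = n_factors))
  new_design_matrix(coded, "BB", n_center, paste0("x", seq_len(n_factors)))
}

.check_specs <- function(design, specs) {
  k <- ncol(design$coded)
  if (length(specs) != k)
    stop(sprintf("design has %d factors but %d factor specs were given",
                 k, length(specs)), call. = FALSE)
  if (!all(vapply(specs, inherits, logical(1), "factor_spec")))
    stop("specs must be a list of factor_spec objects", call. = FALSE)
  invisible(specs)
}

#' Map a coded design to actual factor units
#'
#' Applies the affine map `actual = mid + coded * (high - low) / 2` per
#' factor; [actual_to_coded()] is its exact inverse.
#'
#' @param design A `design_matrix`.
#' @param specs List of [factor_spec()], one per design column, in order.
#'
#' @return A run-by-factor numeric matrix in actual units, with columns named
#'   after the specs.
#' @examples
#' bb <- generate_bb(3, 3)
#' specs <- hplc_factors()[c("flow", "volume", "organic_init")]
#' head(coded_to_actual(bb, specs))
#' @export
coded_to_actual <- function(design, specs) {
  .check_specs(design, specs)
  mid <- vapply(specs, `[[`, numeric(1), "mid")
  half <- vapply(specs, function(s) (s$high - s$low) / 2, numeric(1))
  actual <- sweep(sweep(design$coded, 2, half, `*`), 2, mid, `+`)
  colnames(actual) <- unname(vapply(specs, `[[`, character(1), "name"))
  actual
}

#' Map actual factor levels back to coded units
#'
#' @param actual A run-by-factor matrix (or vector for one run) in actual
#'   units.
#' @param specs List of [factor_spec()], order-matched to the columns.
#' @return A numeric matrix in coded units.
#' @seealso [coded_to_actual()]
#' @export
actual_to_coded <- function(actual, specs) {
  if (is.null(dim(actual))) actual <- matrix(actual, nrow = 1)
  if (ncol(actual) != length(specs))
    stop("column count does not match the number of factor specs",
         call. = FALSE)
  mid <- vapply(specs, `[[`, numeric(1), "mid")
  half <- vapply(specs, function(s) (s$high - s$low) / 2, numeric(1))
  coded <- sweep(sweep(actual, 2, mid, `-`), 2, half, `/`)
  colnames(coded) <- paste0("x", seq_along(specs))
  coded
}
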