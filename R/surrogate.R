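#' Latin hypercube sample of factor setpoints
#'
#' Space-filling design: per factor, exactly one point falls in each of
#' `n_points` equal-width strata, and all levels are distinct.
#'
#' @param n_points Number of design points (>= 2).
#' @param n_factors Number of factors.
#' @param lower,upper Per-factor bounds (scalars are recycled).
#' @param seed Optional integer seed.
#' @return An `n_points` by `n_factors` matrix.
#' @examples
#' X <- latin_hypercube(80, 3, -1, 1, seed = 11)
#' @export
latin_hypercube <- function(n_points, n_factors, lower = 0, upper = 1,
                            seed = NULL) {
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  lower <- rep_len(lower, n_factors)
  upper <- rep_len(upper, n_factors)
  if (any(upper <= lower))
    stop("degenerate bounds: upper must exceed lower", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  U <- lhs::randomLHS(n_points, n_factors)
  X <- sweep(sweep(U, 2, upper - lower, `*`), 2, lower, `+`)
  colnames(X) <- paste0("x", seq_len(n_factors))
  X
}

# Anisotropic squared-exponential correlation matrix.
.gp_corr <- function(X1, X2, ell) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  K <- matrix(0, n1, n2)
  for (d in seq_len(ncol(X1))) {
    D <- outer(X1[, d], X2[, d], `-`) / ell[d]
    K <- K + D * D
  }
  exp(-0.5 * K)
}

# Profile negative log likelihood of constant-mean kriging at
# log length-scales lt and log10 nugget lg (on standardized data).
.gp_nll <- function(par, X, y) {
  k <- ncol(X)
  ell <- exp(par[seq_len(k)])
  g <- 10^par[k + 1]
  n <- length(y)
  A <- .gp_corr(X, X, ell) + diag(g, n)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  Ainv_y <- backsolve(ch, forwardsolve(t(ch), y))
  Ainv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Ainv_y) / sum(Ainv_1)
  r <- y - mu
  Ainv_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Ainv_r) / n
  if (s2 <= 0) return(1e10)
  n / 2 * log(s2) + sum(log(diag(ch)))
}

#' Fit a Gaussian-process (kriging) surrogate
#'
#' Constant-mean kriging with an anisotropic squared-exponential kernel and
#' a small nugget. Length-scales and nugget are chosen by maximum likelihood
#' with multiple restarts; inputs and outputs are standardized internally.
#'
#' @param X Point-by-factor matrix of training inputs (>= 5 rows, no
#'   duplicated rows unless the nugget absorbs them).
#' @param y Numeric response vector (finite).
#' @param nugget_range Log10 bounds of the nugget (default `c(-8, -4)`).
#' @param n_restarts Number of likelihood restarts (default 3).
#' @param ell,nugget Optional fixed hyperparameters (length-scales on the
#'   unit cube and nugget); when both are supplied the likelihood
#'   optimization is skipped.
#' @return An object of class `gp_fit` supporting `predict()` with standard
#'   errors. Predictions at points that coincide with training inputs
#'   reproduce the training values (the nugget is treated as part of the
#'   deterministic surface, as appropriate for simulator output).
#' @examples
#' X <- latin_hypercube(40, 2, seed = 2)
#' y <- 3 + 2 * X[, 1]
#' gp <- fit_gp(X, y)
#' predict(gp, cbind(0.5, 0.5))
#' @export
fit_gp <- function(X, y, nugget_range = c(-8, -4), n_restarts = 3,
                   ell = NULL, nugget = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 5) stop("at least 5 training points are required",
                        call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)",
                                 call. = FALSE)
  if (!all(is.finite(y))) stop("y must be finite", call. = FALSE)
  k <- ncol(X)

  x_lo <- apply(X, 2, min); x_hi <- apply(X, 2, max)
  x_rng <- pmax(x_hi - x_lo, .Machine$double.eps)
  Xs <- sweep(sweep(X, 2, x_lo, `-`), 2, x_rng, `/`)
  y_mu <- mean(y); y_sd <- stats::sd(y)
  constant <- !(y_sd > 0)
  ys <- if (constant) y - y_mu else (y - y_mu) / y_sd

  if (!is.null(ell) && !is.null(nugget)) {
    ell <- rep_len(ell, k); lg <- log10(nugget)
  } else if (constant) {
    ell <- rep(1, k); lg <- mean(nugget_range)
  } else {
    starts <- rbind(rep(log(0.5), k),
                    rep(log(0.2), k),
                    rep(log(1.5), k))
    starts <- starts[seq_len(min(n_restarts, nrow(starts))), , drop = FALSE]
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      par0 <- c(starts[s, ], mean(nugget_range))
      res <- tryCatch(
        stats::optim(par0, .gp_nll, X = Xs, y = ys, method = "L-BFGS-B",
                     lower = c(rep(log(0.01), k), nugget_range[1]),
                     upper = c(rep(log(10), k), nugget_range[2])),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value))
        best <- res
    }
    if (is.null(best)) stop("likelihood optimization failed", call. = FALSE)
    ell <- exp(best$par[seq_len(k)])
    lg <- best$par[k + 1]
  }

  g <- 10^lg
  n <- nrow(Xs)
  A <- .gp_corr(Xs, Xs, ell) + diag(g, n)
  ch <- chol(A)
  Ainv_y <- backsolve(ch, forwardsolve(t(ch), ys))
  Ainv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Ainv_y) / sum(Ainv_1)
  r <- ys - mu
  alpha <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * alpha) / n

  structure(
    list(Xs = Xs, x_lo = x_lo, x_rng = x_rng, y_mu = y_mu,
         y_sd = if (constant) 1 else y_sd, constant = constant,
         ell = ell, nugget = g, mu = mu, sigma2 = s2,
         chol = ch, alpha = alpha, n = n, k = k),
    class = "gp_fit"
  )
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("Gaussian-process surrogate: %d points, %d factors\n",
              x$n, x$k))
  cat("Length-scales (unit-cube):", signif(x$ell, 4), "\n")
  cat(sprintf("Nugget %.3g, process variance %.4g (standardized)\n",
              x$nugget, x$sigma2))
  invisible(x)
}

#' Predict from a Gaussian-process surrogate
#'
#' @param object A `gp_fit`.
#' @param newdata Matrix (or vector for one point) on the original input
#'   scale.
#' @param se.fit If `TRUE`, return predictive standard errors too.
#' @param ... Unused.
#' @return Predictions, or a list `fit`/`se.fit`.
#' @export
predict.gp_fit <- function(object, newdata, se.fit = FALSE, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$k)
    stop("prediction points have the wrong number of columns", call. = FALSE)
  Zs <- sweep(sweep(newdata, 2, object$x_lo, `-`), 2, object$x_rng, `/`)
  Kx <- .gp_corr(Zs, object$Xs, object$ell)
  # simulator output is deterministic: at an exact training input the
  # nugget belongs to the surface, so the surrogate re-interpolates there
  exact <- which(Kx > 1 - 1e-12, arr.ind = TRUE)
  if (nrow(exact) > 0) {
    d2 <- rowSums((Zs[exact[, 1], , drop = FALSE] -
                     object$Xs[exact[, 2], , drop = FALSE])^2)
    hit <- exact[d2 == 0, , drop = FALSE]
    Kx[hit] <- Kx[hit] + object$nugget
  }
  mu <- object$y_mu + object$y_sd * (object$mu + drop(Kx %*% object$alpha))
  if (!se.fit) return(mu)
  V <- backsolve(object$chol, forwardsolve(t(object$chol), t(Kx)))
  var_s <- pmax(0, object$sigma2 * (1 + object$nugget - colSums(V * V)))
  list(fit = mu, se.fit = object$y_sd * sqrt(var_s))
}

#' Leave-one-out (jackknife) predictions of a kriging surrogate
#'
#' For each training point the prediction the surrogate would make without
#' that point, obtained by algebraic downdating of the fitted kernel matrix
#' (hyperparameters held fixed). Plotting actual against jackknife-predicted
#' values is the standard goodness-of-fit diagnostic for the surrogate.
#'
#' @param X Training inputs (>= 6 rows).
#' @param y Training responses.
#' @param ... Passed to [fit_gp()].
#' @return A data frame with columns `actual` and `predicted`.
#' @export
jackknife_predictions <- function(X, y, ...) {
  X <- as.matrix(X)
  if (nrow(X) < 6)
    stop("jackknife needs at least 6 points", call. = FALSE)
  gp <- fit_gp(X, y, ...)
  n <- gp$n
  Ainv <- chol2inv(gp$chol)
  ys <- (y - gp$y_mu) / gp$y_sd
  r <- ys - gp$mu
  Ainv_r <- drop(Ainv %*% r)
  loo_resid <- Ainv_r / diag(Ainv)
  pred_s <- ys - loo_resid
  data.frame(actual = y, predicted = gp$y_mu + gp$y_sd * pred_s)
}

#' Minimize the surrogate-predicted defect rate
#'
#' Multi-start bound-constrained minimization of the surrogate mean
#' prediction. When the surrogate was fitted to log10 defect rates the
#' predicted minimum is back-transformed to a defect rate.
#'
#' @param gp A `gp_fit`.
#' @param lower,upper Bounds per factor on the original input scale.
#' @param log10_scale If `TRUE` (default) the surrogate response is log10 DR
#'   and the returned `predicted_dr` is `10^fit`.
#' @param n_starts Grid starts per dimension (default 4).
#' @return List with `setpoint`, `predicted` (surrogate scale) and
#'   `predicted_dr`.
#' @export
minimize_dr <- function(gp, lower, upper, log10_scale = TRUE, n_starts = 4) {
  stopifnot(inherits(gp, "gp_fit"))
  k <- gp$k
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  if (any(upper <= lower)) stop("degenerate bounds", call. = FALSE)
  obj <- function(x) predict(gp, matrix(x, nrow = 1))
  grid1 <- lapply(seq_len(k), function(i)
    seq(lower[i], upper[i], length.out = n_starts))
  starts <- as.matrix(expand.grid(grid1))
  best <- list(value = Inf, par = starts[1, ])
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(res) && res$value < best$value) best <- res
  }
  pt <- pmin(upper, pmax(lower, best$par))
  list(setpoint = unname(pt), predicted = best$value,
       predicted_dr = if (log10_scale) 10^best$value else best$value)
}

#' Latin-hypercube simulation experiment over factor setpoints
#'
#' Sweeps candidate operating setpoints over the coded factor cube with a
#' Latin hypercube design, estimates the Monte Carlo defect rate at each
#' setpoint, fits a Gaussian-process surrogate to log10 DR, and attaches
#' jackknife goodness-of-fit predictions. Zero-defect points are floored at
#' half a count (`0.5 / runs_per_point`) so the log stays finite.
#'
#' @param models Named list of `rsm_fit` objects.
#' @param spec A [defect_spec()] providing factors, limits and noise
#'   settings; its setpoint is ignored (the LHS provides setpoints).
#' @param n_points Number of LHS setpoints (default 80).
#' @param runs_per_point Monte Carlo runs per setpoint (default 15000).
#' @param factor_space Half-width of the coded sweep region (default 1,
#'   i.e. the full coded design cube).
#' @param seed Optional integer seed.
#' @return An object of class `sim_experiment`: `points`, `dr`, `log10_dr`,
#'   `gp`, `jackknife` (data frame), `floored` (logical vector),
#'   `all_floored` flag, and the `optimum` from [minimize_dr()].
#' @export
run_simulation_experiment <- function(models, spec, n_points = 80,
                                      runs_per_point = 15000,
                                      factor_space = 1, seed = NULL) {
  stopifnot(inherits(spec, "defect_spec"))
  if (!is.null(seed)) set.seed(seed)
  k <- length(spec$factors)
  bound <- rep(factor_space, k)
  pts <- latin_hypercube(n_points, k, lower = -bound, upper = bound)
  sub <- spec
  sub$n_runs <- as.integer(runs_per_point)
  sub$seed <- NULL
  dr <- vapply(seq_len(n_points), function(i) {
    sub$setpoint <- pts[i, ]
    simulate_defect_rate(models, sub)$overall_dr
  }, numeric(1))
  floor_dr <- 0.5 / runs_per_point
  floored <- dr < floor_dr
  log10_dr <- log10(pmax(dr, floor_dr))
  gp <- fit_gp(pts, log10_dr)
  jk <- jackknife_predictions(pts, log10_dr)
  opt <- minimize_dr(gp, lower = -bound, upper = bound)
  structure(
    list(points = pts, dr = dr, log10_dr = log10_dr, gp = gp,
         jackknife = jk, floored = floored, all_floored = all(floored),
         optimum = opt),
    class = "sim_experiment"
  )
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("Simulation experiment: %d setpoints, DR range [%.3g, %.3g]\n",
              nrow(x$points), min(x$dr), max(x$dr)))
  if (x$all_floored)
    cat("note: every setpoint was defect-free; log10 DR is at the floor\n")
  cat(sprintf("Surrogate optimum: DR %.4g at (%s)\n", x$optimum$predicted_dr,
              paste(signif(x$optimum$setpoint, 4), collapse = ", ")))
  invisible(x)
}
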