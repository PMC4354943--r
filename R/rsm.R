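#' Build the model matrix for a response-surface form
#'
#' @param coded Run-by-factor matrix in coded units.
#' @param form `"main_effects"` (intercept + linear terms) or
#'   `"full_quadratic"` (plus all two-way interactions and pure quadratics).
#' @return Numeric model matrix with term labels as column names.
#' @keywords internal
rsm_model_matrix <- function(coded, form = c("main_effects", "full_quadratic")) {
  form <- match.arg(form)
  coded <- as.matrix(coded)
  k <- ncol(coded)
  nm <- colnames(coded)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  X <- cbind(`(Intercept)` = 1, coded)
  colnames(X) <- c("(Intercept)", nm)
  if (form == "full_quadratic") {
    if (k >= 2) {
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        X <- cbind(X, coded[, i] * coded[, j])
        colnames(X)[ncol(X)] <- paste0(nm[i], ":", nm[j])
      }
    }
    for (i in seq_len(k)) {
      X <- cbind(X, coded[, i]^2)
      colnames(X)[ncol(X)] <- paste0(nm[i], "^2")
    }
  }
  X
}

#' Fit a response-surface model on coded units
#'
#' Ordinary least squares of a measured response on the coded design, either
#' a main-effects (screening) model or a full quadratic model with all
#' two-way interactions and pure quadratic terms. Fitting is always done in
#' coded units so that coefficients are directly comparable standardized
#' effects; center points contribute only to the residual degrees of freedom.
#'
#' @param design A `design_matrix` (see [generate_pb()], [generate_bb()]).
#' @param response Numeric vector, one value per run.
#' @param form `"main_effects"` or `"full_quadratic"`.
#'
#' @return An object of class `rsm_fit` with components `terms`,
#'   `coefficients`, `standard_errors`, `t_ratios`, `residual_df`, `rmse`,
#'   `r2`, `fitted`, `residuals`, plus the design metadata needed by
#'   [predict.rsm_fit()].
#' @examples
#' bb <- generate_bb(3, 3)
#' y <- 2 + 3 * bb$coded[, 1] - bb$coded[, 2] + bb$coded[, 1]^2
#' fit <- fit_rsm(bb, y, "full_quadratic")
#' coef(fit)[c("(Intercept)", "x1", "x1^2")]
#' @export
fit_rsm <- function(design, response,
                    form = c("main_effects", "full_quadratic")) {
  form <- match.arg(form)
  coded <- design$coded
  n <- nrow(coded)
  if (length(response) != n)
    stop(sprintf("response has %d values but the design has %d runs",
                 length(response), n), call. = FALSE)
  X <- rsm_model_matrix(coded, form)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop(sprintf(
      "singular fit: term(s) %s are aliased with earlier terms in this design",
      paste(aliased, collapse = ", ")), call. = FALSE)
  }
  if (n - p < 1)
    stop("saturated model: no residual degrees of freedom", call. = FALSE)

  fit <- stats::lm.fit(X, response)
  beta <- fit$coefficients
  res <- fit$residuals
  df <- n - p
  rss <- sum(res^2)
  rmse <- sqrt(rss / df)
  XtXinv <- chol2inv(qr.R(qx))
  se <- rmse * sqrt(diag(XtXinv))
  names(se) <- colnames(X)
  tss <- sum((response - mean(response))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1

  # exact fits give se = 0; a zero effect then has t = 0, not NaN
  t_ratios <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))

  structure(
    list(form = form, terms = colnames(X), coefficients = beta,
         standard_errors = se, t_ratios = t_ratios,
         residual_df = df, rmse = rmse, r2 = r2,
         fitted = fit$fitted.values, residuals = res,
         n_factors = ncol(coded),
         factor_names = colnames(coded) %||% paste0("x", seq_len(ncol(coded))),
         XtXinv = XtXinv),
    class = "rsm_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("Response-surface fit (%s), %d terms, residual df %d\n",
              x$form, length(x$terms), x$residual_df))
  cat(sprintf("RMSE %.4g, r2 %.4f\n", x$rmse, x$r2))
  invisible(x)
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
summary.rsm_fit <- function(object, ...) {
  tab <- data.frame(
    term = object$terms,
    estimate = unname(object$coefficients),
    std_error = unname(object$standard_errors),
    t_ratio = unname(object$t_ratios),
    p_value = 2 * stats::pt(abs(unname(object$t_ratios)),
                            object$residual_df, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  structure(list(coefficients = tab, residual_df = object$residual_df,
                 rmse = object$rmse, r2 = object$r2, form = object$form),
            class = "summary.rsm_fit")
}

#' @export
print.summary.rsm_fit <- function(x, ...) {
  cat(sprintf("Response-surface fit (%s)\n", x$form))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("Residual df %d, RMSE %.4g, r2 %.4f\n",
              x$residual_df, x$rmse, x$r2))
  invisible(x)
}

#' Predict from a response-surface fit
#'
#' @param object An `rsm_fit`.
#' @param newdata Coded point(s): a vector of length `n_factors` or a matrix
#'   with one row per point.
#' @param se.fit If `TRUE`, also return the standard error of the predicted
#'   mean.
#' @param ... Unused.
#' @return Numeric vector of predictions, or a list with elements `fit` and
#'   `se.fit`.
#' @export
predict.rsm_fit <- function(object, newdata, se.fit = FALSE, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_factors)
    stop(sprintf("prediction points have %d columns; the model has %d factors",
                 ncol(newdata), object$n_factors), call. = FALSE)
  colnames(newdata) <- object$factor_names
  X <- rsm_model_matrix(newdata, object$form)
  mu <- unname(drop(X %*% object$coefficients))
  if (!se.fit) return(mu)
  se <- object$rmse * sqrt(rowSums((X %*% object$XtXinv) * X))
  list(fit = mu, se.fit = se)
}

#' @export
residuals.rsm_fit <- function(object, ...) object$residuals

#' Two-sided Student-t critical value
#'
#' The critical value against which standardized effects are judged on a
#' Pareto chart: with `alpha = 0.05` and the 5 residual degrees of freedom of
#' a 15-run Box-Behnken full quadratic fit this is 2.57.
#'
#' @param alpha Two-sided significance level in (0, 1).
#' @param df Residual degrees of freedom (>= 1).
#' @return The positive critical value `qt(1 - alpha/2, df)`.
#' @examples
#' t_critical(0.05, 5) # 2.57
#' @export
t_critical <- function(alpha, df) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  stats::qt(1 - alpha / 2, df)
}

#' Standardized-effect (Pareto) ranking of model terms
#'
#' Ranks the non-intercept terms of a fitted response-surface model by the
#' magnitude of their t-ratio and flags those strictly exceeding the
#' two-sided critical t value. An effect exactly at the critical value is
#' reported as non-significant.
#'
#' @param model An `rsm_fit`.
#' @param alpha Significance level (default 0.05).
#' @return A data frame with columns `term`, `t_ratio`, `abs_t`, `sign`,
#'   `significant`, sorted by `abs_t` descending.
#' @examples
#' bb <- generate_bb(3, 3)
#' set.seed(1)
#' y <- 5 - 2 * bb$coded[, 1] + rnorm(15, sd = 0.1)
#' pareto_effects(fit_rsm(bb, y, "full_quadratic"))
#' @export
pareto_effects <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "rsm_fit"))
  keep <- model$terms != "(Intercept)"
  t <- model$t_ratios[keep]
  crit <- t_critical(alpha, model$residual_df)
  out <- data.frame(
    term = model$terms[keep],
    t_ratio = unname(t),
    abs_t = abs(unname(t)),
    sign = ifelse(t > 0, "+", ifelse(t < 0, "-", "0")),
    significant = abs(unname(t)) > crit,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$abs_t), ]
  rownames(out) <- NULL
  attr(out, "t_critical") <- crit
  out
}
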