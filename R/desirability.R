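#' Define a response goal for desirability profiling
#'
#' Goals follow the Derringer convention: `maximize` ramps linearly from 0 at
#' `lower` to 1 at `upper`; `minimize` is the mirror image (1 at `lower`, 0
#' at `upper`); `target` is a triangular ramp peaking at `target`.
#'
#' @param name Response identifier.
#' @param goal `"maximize"`, `"minimize"` or `"target"`.
#' @param lower,upper Anchor values; required, with `lower < upper`.
#' @param target Target value (only for `goal = "target"`), strictly between
#'   the anchors.
#' @param importance Positive weight in the overall desirability (default 1).
#' @return An object of class `response_goal`.
#' @examples
#' response_goal("tailing_stp", "minimize", lower = 1.0, upper = 1.5)
#' @export
response_goal <- function(name, goal = c("maximize", "minimize", "target"),
                          lower = NULL, upper = NULL, target = NULL,
                          importance = 1) {
  goal <- match.arg(goal)
  if (is.null(lower) || is.null(upper) || !(lower < upper))
    stop(sprintf("goal '%s': anchors must satisfy lower < upper", name),
         call. = FALSE)
  if (goal == "target") {
    if (is.null(target) || !(lower < target && target < upper))
      stop(sprintf("goal '%s': target must lie strictly between the anchors",
                   name), call. = FALSE)
  }
  if (!(importance > 0)) stop("importance must be positive", call. = FALSE)
  structure(
    list(name = name, goal = goal, lower = lower, upper = upper,
         target = target, importance = importance),
    class = "response_goal"
  )
}

#' Individual desirability of a response value
#'
#' @param value Observed or predicted response value (vectorized).
#' @param goal A [response_goal()].
#' @return Desirability in `[0, 1]`.
#' @examples
#' g <- response_goal("area", "maximize", lower = 100, upper = 200)
#' d_individual(c(100, 150, 250), g) # 0, 0.5, 1
#' @export
d_individual <- function(value, goal) {
  stopifnot(inherits(goal, "response_goal"))
  lo <- goal$lower; hi <- goal$upper
  d <- switch(goal$goal,
    maximize = (value - lo) / (hi - lo),
    minimize = (hi - value) / (hi - lo),
    target = {
      tg <- goal$target
      ifelse(value <= tg, (value - lo) / (tg - lo), (hi - value) / (hi - tg))
    }
  )
  pmin(1, pmax(0, d))
}

#' Overall desirability
#'
#' Importance-weighted geometric mean of individual desirabilities; zero as
#' soon as any component is zero, so one fully undesirable response vetoes
#' the whole profile.
#'
#' @param ds Vector of individual desirabilities in `[0, 1]`.
#' @param importances Positive weights, same length as `ds` (default all 1).
#' @return Overall desirability in `[0, 1]`.
#' @examples
#' d_overall(c(0.25, 1)) # 0.5
#' @export
d_overall <- function(ds, importances = rep(1, length(ds))) {
  if (length(ds) == 0) stop("at least one desirability is required",
                            call. = FALSE)
  if (length(importances) != length(ds))
    stop("ds and importances must have equal length", call. = FALSE)
  if (any(importances <= 0)) stop("importances must be positive",
                                  call. = FALSE)
  if (any(ds < 0 | ds > 1)) stop("desirabilities must lie in [0, 1]",
                                 call. = FALSE)
  if (any(ds == 0)) return(0)
  exp(sum(importances * log(ds)) / sum(importances))
}

#' Maximize overall desirability over the coded factor cube
#'
#' Evaluates each fitted response model at a coded point, maps predictions
#' through their goals, and maximizes the overall desirability by
#' multi-start local search: a seeded coded grid of starting points refined
#' with bound-constrained quasi-Newton steps.
#'
#' @param models Named list of `rsm_fit` objects sharing one factor space;
#'   names must match the goal names.
#' @param goals List of [response_goal()] objects.
#' @param lower,upper Coded bounds per factor (defaults -1 and +1).
#' @param n_starts Number of grid starts per dimension (default 5).
#'
#' @return A list with `point` (optimal coded vector), `predicted` (named
#'   predicted responses there), and `desirability`. A `degenerate` flag is
#'   set when the desirability is zero everywhere explored.
#' @export
optimize_profile <- function(models, goals, lower = NULL, upper = NULL,
                             n_starts = 5) {
  stopifnot(length(goals) >= 1)
  gnames <- vapply(goals, `[[`, character(1), "name")
  if (!all(gnames %in% names(models)))
    stop("every goal needs a model of the same name", call. = FALSE)
  models <- models[gnames]
  k <- models[[1]]$n_factors
  if (!all(vapply(models, `[[`, integer(1), "n_factors") == k))
    stop("all models must share one factor space", call. = FALSE)
  if (is.null(lower)) lower <- rep(-1, k)
  if (is.null(upper)) upper <- rep(1, k)
  imp <- vapply(goals, `[[`, numeric(1), "importance")

  objective <- function(x) {
    pred <- vapply(models, function(m) predict(m, x), numeric(1))
    ds <- mapply(function(p, g) d_individual(p, g), pred, goals)
    -d_overall(ds, imp)
  }

  grid1 <- lapply(seq_len(k), function(i)
    seq(lower[i], upper[i], length.out = n_starts))
  starts <- as.matrix(expand.grid(grid1))

  best <- list(value = Inf, par = starts[1, ])
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[s, ], objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && res$value < best$value) best <- res
  }

  point <- pmin(upper, pmax(lower, best$par))
  pred <- vapply(models, function(m) predict(m, point), numeric(1))
  names(pred) <- gnames
  dopt <- -best$value
  list(point = unname(point), predicted = pred, desirability = dopt,
       degenerate = dopt <= 0)
}

#' Percent error between a model prediction and a checkpoint observation
#'
#' @param predicted Model-predicted response value.
#' @param observed Measured response value (non-zero).
#' @return `100 * |observed - predicted| / |observed|`.
#' @examples
#' checkpoint_error(95, 100) # 5
#' @export
checkpoint_error <- function(predicted, observed) {
  if (any(observed == 0))
    stop("percent error is undefined for observed = 0", call. = FALSE)
  100 * abs(observed - predicted) / abs(observed)
}
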