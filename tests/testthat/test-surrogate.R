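test_that("Latin hypercube places one point per stratum for every seed", {
  for (s in c(1, 2, 17, 101)) {
    X <- latin_hypercube(80, 3, -1, 1, seed = s)
    expect_true(strata_ok(X, -1, 1))
    expect_true(all(apply(X, 2, function(v) !anyDuplicated(v))))
  }
  X2 <- latin_hypercube(2, 1, seed = 5)
  expect_true(xor(X2[1] < 0.5, X2[2] < 0.5))
  expect_identical(latin_hypercube(10, 2, seed = 3),
                   latin_hypercube(10, 2, seed = 3))
  expect_false(identical(latin_hypercube(10, 2, seed = 3),
                         latin_hypercube(10, 2, seed = 4)))
  expect_error(latin_hypercube(1, 2), "n_points")
  expect_error(latin_hypercube(10, 2, lower = 1, upper = 1), "degenerate")
})

test_that("kriging interpolates its training data and recovers a linear
           function on held-out points", {
  X <- latin_hypercube(40, 2, seed = 2)
  y <- 3 + 2 * X[, 1]
  gp <- fit_gp(X, y)
  expect_equal(predict(gp, X), y, tolerance = 1e-6)
  Xtest <- as.matrix(expand.grid(seq(0.1, 0.9, 0.2), seq(0.1, 0.9, 0.2)))
  expect_equal(predict(gp, Xtest), 3 + 2 * Xtest[, 1], tolerance = 1e-3)

  # predictive variance: at most nugget-sized at training points,
  # strictly positive away from them
  pv <- predict(gp, X, se.fit = TRUE)$se.fit
  far <- predict(gp, matrix(c(0.512345, 0.4987), 1), se.fit = TRUE)$se.fit
  expect_lt(max(pv), 10 * sqrt(gp$nugget) * stats::sd(y))
  expect_gt(far, max(pv))
})

test_that("kriging predictions are invariant to training-row permutation", {
  set.seed(8)
  X <- latin_hypercube(30, 2, seed = 8)
  y <- sin(3 * X[, 1]) + X[, 2]^2
  # fixed hyperparameters: permutation must not move predictions at all
  gp1 <- fit_gp(X, y, ell = c(0.4, 0.4), nugget = 1e-6)
  perm <- sample(nrow(X))
  gp2 <- fit_gp(X[perm, ], y[perm], ell = c(0.4, 0.4), nugget = 1e-6)
  Z <- matrix(runif(20), 10, 2)
  expect_equal(predict(gp1, Z), predict(gp2, Z), tolerance = 1e-10)
  # with estimated hyperparameters the optimizer sees the same likelihood
  gp3 <- fit_gp(X, y)
  gp4 <- fit_gp(X[perm, ], y[perm])
  expect_equal(predict(gp3, Z), predict(gp4, Z), tolerance = 1e-6)
})

test_that("constant response collapses to the constant mean and bad input
           errors", {
  X <- latin_hypercube(10, 2, seed = 1)
  gp <- fit_gp(X, rep(4.2, 10))
  expect_equal(predict(gp, matrix(c(0.3, 0.9), 1)), 4.2, tolerance = 1e-8)
  expect_error(fit_gp(X[1:4, ], rep(1, 4)), "at least 5")
  expect_error(fit_gp(X, c(rep(1, 9), NaN)), "finite")
})

test_that("jackknife predictions diagnose good and vacuous fits", {
  X <- latin_hypercube(40, 2, seed = 12)
  y <- 1 + X[, 1] + 0.5 * X[, 2]^2
  jk <- jackknife_predictions(X, y)
  expect_equal(nrow(jk), 40)
  sl <- coef(lm(predicted ~ actual, data = jk))[2]
  expect_gt(sl, 0.8); expect_lt(sl, 1.2)
  expect_gt(summary(lm(predicted ~ actual, data = jk))$r.squared, 0.95)

  set.seed(13)
  ynoise <- rnorm(40)
  jkn <- jackknife_predictions(X, ynoise)
  sln <- coef(lm(predicted ~ actual, data = jkn))[2]
  expect_lt(abs(sln), 0.5)

  expect_silent(jackknife_predictions(X[1:6, ], y[1:6]))
  expect_error(jackknife_predictions(X[1:5, ], y[1:5]), "at least 6")
})

test_that("surrogate minimization recovers a known minimum and boundary
           optima", {
  X <- latin_hypercube(60, 2, seed = 14)
  y <- (X[, 1] - 0.3)^2 + (X[, 2] - 0.7)^2 + 0.01
  gp <- fit_gp(X, y)
  opt <- minimize_dr(gp, lower = 0, upper = 1, log10_scale = FALSE)
  expect_lt(max(abs(opt$setpoint - c(0.3, 0.7))), 0.05)

  ymono <- 2 + X[, 1] + X[, 2]
  gpm <- fit_gp(X, ymono)
  optm <- minimize_dr(gpm, lower = 0, upper = 1, log10_scale = FALSE)
  expect_lt(max(abs(optm$setpoint - c(0, 0))), 0.05)
})

test_that("a smooth defect surface is recovered through the full simulation
           experiment and zero-defect regions hit the log floor", {
  # smooth surface oracle, fitted directly
  X <- latin_hypercube(50, 2, seed = 15)
  y <- log10(pnorm(2 * X[, 1] - 1) + 1e-4)
  jk <- jackknife_predictions(X, y)
  expect_gt(summary(lm(predicted ~ actual, data = jk))$r.squared, 0.95)

  # linear model crossing its USL across the sweep: DR varies smoothly
  lin <- constant_model(0, 0.2, k = 2)
  lin$coefficients["x1"] <- 1
  specs <- coded_specs(2, 0.1)
  sp <- defect_spec(specs, c(0, 0), list(y = list(usl = 0.5)),
                    n_runs = 400, seed = 1)
  ex <- run_simulation_experiment(list(y = lin), sp, n_points = 25,
                                  runs_per_point = 400, seed = 16)
  expect_length(ex$dr, 25)
  expect_false(ex$all_floored)
  expect_equal(nrow(ex$jackknife), 25)
  # the surrogate optimum sits where the true exceedance is negligible
  # (the low-x1 plateau); the closed-form oracle bounds the true DR there
  sd_tot <- sqrt(0.1^2 + 0.2^2)
  expect_lt(ex$optimum$setpoint[1], 0)
  expect_lt(pnorm((ex$optimum$setpoint[1] - 0.5) / sd_tot), 0.01)
  expect_lte(ex$optimum$predicted_dr, max(ex$dr))

  # a never-violating model floors every point and flags it
  safe <- constant_model(0, 0, k = 2)
  sp2 <- defect_spec(specs, c(0, 0), list(y = list(usl = 5)),
                     n_runs = 200, seed = 2)
  ex2 <- run_simulation_experiment(list(y = safe), sp2, n_points = 12,
                                   runs_per_point = 200, seed = 17)
  expect_true(ex2$all_floored)
  expect_true(all(ex2$log10_dr == log10(0.5 / 200)))
})
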