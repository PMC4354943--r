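#' Default configuration of the assay-development pipeline
#'
#' Returns the configuration under which the synthetic study runs: the five
#' chromatographic factors, a 12-run two-level screening design with three
#' center points, a three-factor Box-Behnken optimization design with three
#' center points, maximize goals on both peak areas and minimize goals on
#' both tailing factors, lower specification limits on the areas plus the
#' 1.5 upper limit on tailing, a 15,000-run Monte Carlo budget, and an
#' 80-point Latin hypercube simulation experiment.
#'
#' @return A nested list; override elements before passing to
#'   [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    factors = hplc_factors(),
    screening = list(base_runs = 12, n_center = 3, alpha = 0.05),
    optimization = list(n_center = 3, n_carry = 3,
                        fixed_levels = c(wavelength = 270,
                                         organic_4min = 95)),
    goals = list(
      area_stp = list(goal = "maximize"),
      area_hi443 = list(goal = "maximize"),
      tailing_stp = list(goal = "minimize", lower = 1.0, upper = 1.5),
      tailing_hi443 = list(goal = "minimize", lower = 1.0, upper = 1.5)
    ),
    spec_limits = list(
      area_stp = list(lsl = 100),
      area_hi443 = list(lsl = 180),
      tailing_stp = list(usl = 1.5),
      tailing_hi443 = list(usl = 1.5)
    ),
    simulation = list(n_runs = 15000, response_noise = TRUE,
                      n_points = 80, runs_per_point = 15000),
    rounding = list(increments = c(flow = 0.1, volume = 1,
                                   wavelength = 1, organic_init = 1,
                                   organic_4min = 1)),
    generator = list(noise_sd = 1e-4, inj_cv = 0.01, dt = 0.002)
  )
}

#' Round an operating point to practically settable factor levels
#'
#' Instrument panels only accept coarse factor settings, so the
#' continuous optimum is snapped to each factor's practical increment
#' using round-half-away-from-zero.
#'
#' @param setpoint Numeric vector in actual units.
#' @param increments Positive step per factor (recycled).
#' @return The rounded setpoint.
#' @examples
#' round_to_practical(c(0.60, 18.29, 91.81), c(0.1, 1, 1)) # 0.6 18 92
#' @export
round_to_practical <- function(setpoint, increments) {
  increments <- rep_len(increments, length(setpoint))
  if (any(increments <= 0)) stop("increments must be positive",
                                 call. = FALSE)
  sign(setpoint) * floor(abs(setpoint) / increments + 0.5 + 1e-9) *
    increments
}

# Build response_goal objects, filling unanchored area goals with the
# min/max of the model predictions over the coded design cube.
.build_goals <- function(goal_cfg, models) {
  goals <- list()
  for (nm in names(goal_cfg)) {
    g <- goal_cfg[[nm]]
    lower <- g$lower; upper <- g$upper
    if (is.null(lower) || is.null(upper)) {
      m <- models[[nm]]
      k <- m$n_factors
      grid <- as.matrix(expand.grid(rep(list(seq(-1, 1, length.out = 7)), k)))
      pr <- predict(m, grid)
      if (is.null(lower)) lower <- min(pr)
      if (is.null(upper)) upper <- max(pr)
      if (upper <= lower) upper <- lower + max(abs(lower), 1) * 1e-6
    }
    goals[[nm]] <- response_goal(nm, g$goal, lower = lower, upper = upper,
                                 target = g$target,
                                 importance = g$importance %||% 1)
  }
  goals
}

#' Run the full assay-development pipeline
#'
#' Executes the study stages in order on synthetic chromatographic data:
#' two-level screening with main-effects fits and Pareto selection, a
#' Box-Behnken response-surface stage on the carried-over factors with
#' full quadratic fits, desirability optimization, Monte Carlo defect-rate
#' estimation at the desirability optimum, a Latin-hypercube simulation
#' experiment with a Gaussian-process surrogate minimized to find the
#' low-defect operating point, rounding of that point to practical factor
#' settings, and a confirmatory defect-rate run. Factors whose screening
#' |t| never exceeds the critical value are held at configured levels.
#'
#' @param config Configuration list (see [default_pipeline_config()]), or a
#'   path to a YAML file with the same structure.
#' @param seed Integer seed; the whole bundle is a pure function of
#'   (config, seed).
#' @param out_dir Optional directory; when given, designs and responses are
#'   written as CSV, models/optima/defect reports as JSON, and a Markdown
#'   summary is produced.
#' @return A `pipeline_result` list with elements `screening`,
#'   `optimization`, `desirability`, `dr_initial`, `sim_experiment`,
#'   `dr_optimized`, `practical` and `config`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1,
                         out_dir = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    config <- utils::modifyList(default_pipeline_config(),
                                yaml::read_yaml(config))
  }
  cf <- config
  factors <- cf$factors
  fnames <- vapply(factors, `[[`, character(1), "name")
  gen <- cf$generator

  ## Stage 1: screening ----------------------------------------------------
  pb <- generate_pb(length(factors), cf$screening$base_runs,
                    cf$screening$n_center)
  pb_actual <- coded_to_actual(pb, factors)
  resp_pb <- simulate_responses(pb_actual, noise_sd = gen$noise_sd,
                                inj_cv = gen$inj_cv, dt = gen$dt,
                                seed = seed)
  screen_fits <- lapply(resp_pb, function(y) fit_rsm(pb, y, "main_effects"))
  screen_pareto <- lapply(screen_fits, pareto_effects,
                          alpha = cf$screening$alpha)
  sig_by_factor <- vapply(seq_along(factors), function(j) {
    term <- paste0("x", j)
    any(vapply(screen_pareto, function(p)
      p$significant[p$term == term], logical(1)))
  }, logical(1))
  max_abs_t <- vapply(seq_along(factors), function(j) {
    term <- paste0("x", j)
    max(vapply(screen_pareto, function(p) p$abs_t[p$term == term],
               numeric(1)))
  }, numeric(1))
  carry <- which(sig_by_factor)
  n_carry <- cf$optimization$n_carry
  if (length(carry) < n_carry) {
    extra <- setdiff(order(-max_abs_t), carry)
    carry <- sort(c(carry, extra[seq_len(n_carry - length(carry))]))
  }
  carry_names <- fnames[carry]

  ## Stage 2: response-surface optimization --------------------------------
  bb <- generate_bb(length(carry), cf$optimization$n_center)
  bb_factors <- factors[carry]
  bb_actual <- coded_to_actual(bb, bb_factors)
  fixed <- cf$optimization$fixed_levels
  fixed_used <- fixed[setdiff(names(fixed), carry_names)]
  resp_bb <- simulate_responses(bb_actual, fixed = fixed_used,
                                noise_sd = gen$noise_sd, inj_cv = gen$inj_cv,
                                dt = gen$dt, seed = seed + 1L)
  bb_fits <- lapply(resp_bb, function(y) fit_rsm(bb, y, "full_quadratic"))
  bb_pareto <- lapply(bb_fits, pareto_effects, alpha = cf$screening$alpha)

  ## Stage 3: desirability optimum ------------------------------------------
  goals <- .build_goals(cf$goals, bb_fits)
  des <- optimize_profile(bb_fits, goals)

  ## Stage 4: Monte Carlo defect rate at the desirability optimum -----------
  spec0 <- defect_spec(bb_factors, des$point, cf$spec_limits,
                       n_runs = cf$simulation$n_runs,
                       response_noise = cf$simulation$response_noise,
                       seed = seed + 2L)
  dr_initial <- simulate_defect_rate(bb_fits, spec0)

  ## Stage 5: simulation experiment + surrogate minimization ----------------
  simexp <- run_simulation_experiment(
    bb_fits, spec0, n_points = cf$simulation$n_points,
    runs_per_point = cf$simulation$runs_per_point, seed = seed + 3L)
  spec_opt <- spec0
  spec_opt$setpoint <- simexp$optimum$setpoint
  spec_opt$seed <- seed + 4L
  dr_optimized <- simulate_defect_rate(bb_fits, spec_opt)

  ## Stage 6: practical rounding + confirmation ------------------------------
  opt_actual <- drop(coded_to_actual(
    new_design_matrix(matrix(simexp$optimum$setpoint, nrow = 1), "custom",
                      0, carry_names), bb_factors))
  inc <- cf$rounding$increments[carry_names]
  practical_actual <- round_to_practical(opt_actual, inc)
  practical_coded <- drop(actual_to_coded(matrix(practical_actual, nrow = 1),
                                          bb_factors))
  spec_prac <- spec0
  spec_prac$setpoint <- practical_coded
  spec_prac$seed <- seed + 5L
  dr_practical <- simulate_defect_rate(bb_fits, spec_prac)

  result <- structure(list(
    screening = list(design = pb, design_actual = pb_actual,
                     responses = resp_pb, fits = screen_fits,
                     pareto = screen_pareto,
                     significant = fnames[sig_by_factor],
                     carried = carry_names),
    optimization = list(design = bb, design_actual = bb_actual,
                        responses = resp_bb, fits = bb_fits,
                        pareto = bb_pareto, factors = bb_factors),
    desirability = des,
    dr_initial = dr_initial,
    sim_experiment = simexp,
    dr_optimized = dr_optimized,
    practical = list(setpoint_actual = practical_actual,
                     setpoint_coded = practical_coded,
                     dr = dr_practical),
    config = cf, seed = seed
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Assay-development pipeline result\n")
  cat(sprintf("  screening: significant factors: %s (carried: %s)\n",
              paste(x$screening$significant, collapse = ", "),
              paste(x$screening$carried, collapse = ", ")))
  cat(sprintf("  desirability optimum d = %.3f at coded (%s)\n",
              x$desirability$desirability,
              paste(signif(x$desirability$point, 3), collapse = ", ")))
  cat(sprintf("  defect rate at desirability optimum: %.4g (%.0f dpm)\n",
              x$dr_initial$overall_dr, x$dr_initial$dpm))
  cat(sprintf("  defect rate at surrogate optimum:    %.4g (%.0f dpm)\n",
              x$dr_optimized$overall_dr, x$dr_optimized$dpm))
  cat(sprintf("  practical setpoint: %s -> DR %.4g (%.0f dpm)\n",
              paste(names(x$practical$setpoint_actual),
                    signif(x$practical$setpoint_actual, 4),
                    sep = "=", collapse = ", "),
              x$practical$dr$overall_dr, x$practical$dr$dpm))
  invisible(x)
}

.model_report <- function(fit) {
  list(form = fit$form, terms = fit$terms,
       coefficients = unname(fit$coefficients),
       standard_errors = unname(fit$standard_errors),
       t_ratios = unname(fit$t_ratios),
       residual_df = fit$residual_df, rmse = fit$rmse, r2 = fit$r2)
}

#' Write the machine-readable report bundle of a pipeline run
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  utils::write.csv(cbind(as.data.frame(result$screening$design$coded),
                         result$screening$responses),
                   p("screening_design_responses.csv"), row.names = FALSE)
  utils::write.csv(cbind(as.data.frame(result$optimization$design$coded),
                         result$optimization$responses),
                   p("bb_design_responses.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(result$optimization$fits, .model_report),
                       p("models.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(desirability_optimum = result$desirability,
         dr_initial = unclass(result$dr_initial),
         surrogate_optimum = result$sim_experiment$optimum,
         dr_optimized = unclass(result$dr_optimized),
         practical_setpoint = as.list(result$practical$setpoint_actual),
         dr_practical = unclass(result$practical$dr)),
    p("optimization_report.json"), auto_unbox = TRUE, digits = NA)
  simx <- result$sim_experiment
  utils::write.csv(
    data.frame(simx$points, dr = simx$dr, log10_dr = simx$log10_dr,
               jackknife_pred = simx$jackknife$predicted),
    p("simulation_experiment.csv"), row.names = FALSE)
  lines <- c(
    "# Pipeline summary", "",
    sprintf("- Seed: %d", result$seed),
    sprintf("- Screening significant factors: %s",
            paste(result$screening$significant, collapse = ", ")),
    sprintf("- Carried to optimization: %s",
            paste(result$screening$carried, collapse = ", ")),
    sprintf("- Desirability optimum (coded): %s, d = %.3f",
            paste(signif(result$desirability$point, 4), collapse = ", "),
            result$desirability$desirability),
    sprintf("- Defect rate at desirability optimum: %.5g (%.0f dpm)",
            result$dr_initial$overall_dr, result$dr_initial$dpm),
    sprintf("- Defect rate at surrogate optimum: %.5g (%.0f dpm)",
            result$dr_optimized$overall_dr, result$dr_optimized$dpm),
    sprintf("- Practical setpoint: %s",
            paste(names(result$practical$setpoint_actual),
                  signif(result$practical$setpoint_actual, 4),
                  sep = " = ", collapse = ", ")),
    sprintf("- Defect rate at practical setpoint: %.5g (%.0f dpm)",
            result$practical$dr$overall_dr, result$practical$dr$dpm)
  )
  writeLines(lines, p("summary.md"))
  invisible(out_dir)
}
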