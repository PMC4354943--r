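---
title: "Methods: DOE and Monte Carlo defect-rate optimization of an HPLC assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DOE and Monte Carlo defect-rate optimization of an HPLC assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdoe)
```

## The problem

Developing a liquid-chromatography assay means choosing operating factors —
mobile-phase flow rate, injection volume, detection wavelength, organic
fraction of the gradient — so that the measured responses (peak areas and
USP tailing factors of the analytes) are simultaneously acceptable, and stay
acceptable under the day-to-day random variation of those factors. chromdoe
implements that workflow as computation: a screening design identifies the
factors that matter, a response-surface design models their joint effects, a
desirability profile proposes an operating point, and a Monte Carlo
simulation quantifies the *defect rate* — the probability that a run
violates a specification limit — which a surrogate model then minimizes over
candidate setpoints.

The worked system is a two-analyte assay: an early-eluting, moderately
lipophilic nucleoside analogue (template `stp`, 10 ug/mL) and a late-eluting,
strongly lipophilic non-nucleoside compound (template `hi443`, 5 ug/mL),
carried in solid lipid nanoparticles. No instrument data are shipped; a
synthetic chromatogram generator stands in for the detector, so the entire
analysis is reproducible from a seed.

## Experimental designs

`generate_pb()` builds the canonical 12-run two-level Plackett-Burman design
from the cyclic generator row `+ + - + + + - - - + -` plus a final all-low
run. Any 12-run PB design is orthogonal over its base rows
(`X'X = 12 I`); the cyclic construction is the standard one and its
orthogonality is tested exactly. Three all-mid center points are appended by
default; they contribute residual degrees of freedom (process stability and
pure error) but, being orthogonal to every coded column, do not move the
effect estimates. Run order randomization is available as a seeded shuffle
but off by default so designs are reproducible.

`generate_bb()` builds the three-factor Box-Behnken design: the 12 edge
midpoints of the coded cube plus center points — 15 runs with three centers,
enough to fit a full quadratic model (10 terms) with 5 residual degrees of
freedom. Center points are placed last; their position is irrelevant to the
fit.

Coded and actual units are linked by the affine map
`actual = mid + coded * (high - low) / 2` per factor (`coded_to_actual()` /
`actual_to_coded()`), with levels declared in `factor_spec()` objects. The
built-in `hplc_factors()` set is: flow 0.6/0.8/1.0 mL/min, injection volume
10/15/20 uL, wavelength 265/270/275 nm, initial organic 60/70/80 % v/v, and
organic at four minutes 85/90/95 % v/v.

## Response-surface models

`fit_rsm()` fits ordinary least squares in coded units — main effects for
screening (PB designs cannot resolve interactions, and pure quadratics are
aliased with the intercept there, which the fit reports as a singular-fit
error naming the aliased terms), or the full quadratic for the Box-Behnken
stage. Coded-unit fitting keeps the model matrix well conditioned and makes
coefficients directly comparable standardized effects. No stepwise term
removal is done: the declared model is always fitted in full, matching how
Pareto charts of standardized effects are normally read.

`pareto_effects()` ranks non-intercept terms by `|t| = |coef| / se` against
the two-sided critical value `t_critical(alpha, residual_df)`; for the
15-run Box-Behnken quadratic that critical value is
`t_critical(0.05, 5) = 2.57`. An effect exactly at the critical value is
reported non-significant (strict inequality) so the decision is
deterministic. Center-point replicate error is not pooled separately from
residual error; plain OLS residual error is used throughout.

## Desirability profiling

Goals are linear Derringer ramps (`d_individual()`): maximize rises 0 to 1
between its anchors, minimize mirrors it, target is triangular. The overall
desirability (`d_overall()`) is the importance-weighted geometric mean, so a
single fully undesirable response vetoes a candidate point. Anchors for the
peak areas default to the (min, max) of the fitted predictions over the
coded cube — the goals are "maximize" without natural anchors — while the
tailing goals use (1.0, 1.5): 1.0 is a symmetric peak and 1.5 is the upper
specification limit used in the defect simulation. `optimize_profile()`
maximizes overall desirability by a 5-per-dimension seeded grid of starts
refined with bound-constrained quasi-Newton steps (tolerance 1e-6 in coded
units); a property test checks it never loses to a 21^3 brute-force grid.

`checkpoint_error()` supports confirmation runs: percent error
`100 |obs - pred| / |obs|` between model predictions and observations at
off-optimum settings.

## Monte Carlo defect rate

`simulate_defect_rate()` draws `n_runs` (default 15,000) factor settings
around a setpoint — per factor an independent normal with the standard
deviation given by `factor_spec$sim_sd`, rejected outside the coded design
range so factors "vary within their specification range" — predicts every
response from its fitted model, optionally adds N(0, rmse) response noise
(on by default, representing the assay's inherent variability), and counts a
run defective when any response violates its limits. The defect rate is
`DR = m/n`; `defects_per_million()` is `DR * 1e6`, and `defect_share()`
attributes the overall rate to individual responses. An exact binomial 95%
interval accompanies every estimate.

The `sim_sd` defaults come from the method-robustness perturbations (flow
+/- 0.1 mL/min, wavelength +/- 2 nm, initial organic +/- 2 % v/v) read as
three-sigma excursions — the only variation magnitudes the validation
protocol states. The injection volume has no stated perturbation; +/- 0.5 uL
(a typical autosampler precision) is used, and the final organic ratio
mirrors the initial one. The numeric lower specification limits on the peak
areas are likewise not dictated by theory; the defaults (100 and 180 mAU s)
were chosen once for the synthetic generator so that area defects are
possible at aggressive settings but tailing dominates, as in the motivating
assay. `defect_profile()` sweeps one factor over a grid while the others
vary randomly, tracing the defect-rate sensitivity curve.

## Latin hypercube + Gaussian-process surrogate

`run_simulation_experiment()` sweeps candidate setpoints over the coded cube
("factor space of one", read as the full +/- 1 coded region) with an
80-point Latin hypercube (`lhs::randomLHS`; exactly one point per
equal-width stratum per factor), estimates the defect rate at each point,
and fits a kriging surrogate to log10 DR. Zero-defect points are floored at
half a count, `0.5 / runs_per_point`, the standard continuity correction
that keeps the log finite; an `all_floored` flag marks the degenerate case.
The default budget is 15,000 Monte Carlo runs per setpoint; tests use
reduced presets (hundreds per point), and the sizes used are stated below.

`fit_gp()` is constant-mean kriging with an anisotropic squared-exponential
kernel and a nugget bounded in [1e-8, 1e-4], hyperparameters by maximum
likelihood from three restarts (inputs scaled to the unit cube, response
standardized). Because the defect-rate surface is deterministic simulator
output, predictions at exact training inputs re-interpolate the training
values: the nugget is treated as part of the surface covariance there.
`jackknife_predictions()` gives leave-one-out predictions by algebraic
downdating of the fitted kernel matrix (hyperparameters held fixed), the
standard goodness-of-fit diagnostic plotted as actual vs predicted.
`minimize_dr()` minimizes the surrogate mean by multi-start bound-constrained
search and back-transforms to a defect rate.

## The synthetic chromatogram generator

`simulate_chromatogram()` sums one exponentially modified Gaussian (EMG) per
analyte — the minimal standard peak shape with a controllable tailing factor
— over a uniform time grid (default 0.002 min, fine enough that
interpolation errors in area and width are below 0.1%). The factor physics
encoded, per `peak_model()` template:

* **Area** follows the Beer-Lambert detector law `area = eps * l * moles /
  flow`: proportional to injected mass (concentration x volume) and
  inversely proportional to flow. This is the quantitative core the
  screening stage must rediscover (negative flow effect, positive volume
  effect on both areas).
* **Retention** decreases with flow (`t_R ~ 1/f`) and with the organic
  fraction (exponentially, more steeply for the lipophilic analyte); the
  templates put the two peaks at 3.2 and 4.6 min at the reference condition
  (0.6 mL/min, 92% organic).
* **Width** is proportional to retention (`sigma_rel = 0.015`).
* **Tail constant** grows affinely with injection volume (mass overload)
  and organic fraction (silanol interactions), with the organic coefficient
  at least as large for the lipophilic template. Higher flow also raises
  the tailing factor indirectly by narrowing sigma. The tail coefficients
  were set so USP tailing spans roughly 1.1-2.0 over the design region and
  sits near the 1.5 limit at desirable operating points — a system where
  defect-rate analysis has something to find, with tailing of the early
  peak the dominant defect source.
* **Wavelength** multiplies the response through a shallow quadratic
  peaking near each analyte's absorption maximum (267 / 273 nm, width 60
  nm), so the wavelength factor is real but non-significant at +/- 5 nm,
  preserving the screening outcome.
* **Noise**: additive white baseline noise (default 1e-4 AU) plus a 1%
  injection-repeatability error on the injected mass, which puts replicate
  peak-area %RSD near 1%, inside the 2% precision criterion.

What the generator does **not** emulate: the mechanistic shape of gradient
elution (the organic program enters only through monotone empirical maps),
column aging and carryover, co-eluting impurities, detector saturation, and
vendor file formats. Tests passing on this generator therefore demonstrate
that the statistical machinery recovers known structure from
chromatography-like data, not that the specific fitted constants transfer
to any real instrument.

Peak metrics follow the compendial conventions: `usp_tailing()` uses widths
at 5% height, `T = W / (2 f)`; `theoretical_plates()` uses the half-height
formula `N = 5.54 (t_R / W_0.5)^2`; `resolution()` uses base widths of
1.699 x the half-height width; `sn_ratio()` uses peak height over twice the
baseline-noise standard deviation, and `lod_from_calibration()` inverts it
at S/N = 3. All metrics operate on a baseline-corrected window (straight
line through the window's edge levels, averaged over ~5% of the window) and
are invariant to constant offsets and time translation.

## Release kinetics and quantification

`fit_release()` fits the four classic in-vitro release models by linearized
least squares — the convention of the kinetics literature, whose r2 values
refer to the linearization: zero order (Q vs t), first order (ln(1-Q) vs t),
Higuchi (Q vs sqrt t), Korsmeyer-Peppas (log10 Q vs log10 t). Zero-order and
Higuchi fits include a free intercept, with the slope reported as the rate
constant. The Peppas fit uses only points with Q <= 0.6 (its standard
validity bound) and all log-based fits drop t = 0. Rate-constant units
follow the declared scale of the input profile; literature tables that mix
amount-based constants with percent-based profiles cannot be reproduced
numerically and are not attempted. `select_best_model()` takes the highest
r2 with ties broken toward fewer parameters; `classify_mechanism()` applies
the exponent thresholds (Fickian n <= 0.5, anomalous 0.5 < n < 1, case-II
n = 1 within 1e-9, super case-II n > 1). Measured profiles may dip slightly
between time points; `release_profile(monotone_tol=)` admits such noise
without accepting a genuinely decreasing curve.

`epsilon_from_peak_area()` rearranges Beer-Lambert for chromatography: with
`Ab(t) = eps * l * c(t)` and `moles = integral(c) * flow`, the concentration
integral cancels to give `eps = area * flow / (l * moles)`; area in AU min
times flow in mL/min is AU mL, hence a division by 1000 yields
L mol^-1 cm^-1. This is the only dimensionally consistent reading of "peak
area is the time integral of absorbance". The spectrophotometric route
(`epsilon_from_uv()`) is the zero-intercept calibration slope over the path
length. Both a regression slope and per-level estimates are available for
the chromatographic route; the slope is the default and the two routes agree
within 1% on common Beer-Lambert truth. `encapsulation_efficiency()` is
`100 * measured / theoretical` (% w/w).

## The pipeline

`run_pipeline()` executes: PB screening -> Pareto carryover -> Box-Behnken
quadratics -> desirability optimum -> Monte Carlo defect rate there ->
Latin-hypercube simulation experiment with surrogate minimization ->
rounding to practical increments (round-half-away-from-zero; flow 0.1
mL/min, volume 1 uL, organic 1 % v/v) -> confirmatory defect rate. The
carryover rule advances factors whose screening |t| exceeds the critical
value anywhere; if fewer than three qualify, the largest remaining |t|
values fill the Box-Behnken trio, and non-carried factors are held at
configured levels (wavelength 270 nm, final organic 95 % v/v by default —
config, not hard-coded). All randomness is seeded; a bundle is a pure
function of (config, seed), and `write_pipeline_outputs()` emits CSV/JSON
reports plus a Markdown summary.

## Numerical choices and problem sizes

* Desirability and surrogate optimizers: L-BFGS-B multistart; ties and
  plateaus resolve to the best start deterministically.
* Defect draws are truncated by rejection; a zero `sim_sd` fixes the factor.
* GP nugget bounds 1e-8..1e-4 (log10-uniform search), three restarts;
  constant responses shortcut to the constant mean.
* The test suite runs the pipeline at reduced sizes (4,000-run Monte Carlo,
  25 LHS points x 800 runs) and the Monte Carlo oracle checks at n =
  20,000; the acceptance script uses the full defaults (15,000 runs, 80
  points x 15,000). These sizes were chosen to keep binomial error well
  inside every asserted tolerance.

## Limitations

Absolute defect rates depend on the generator's noise levels and the chosen
area specification limits; only their qualitative structure (tailing-driven
defects, improvement under surrogate optimization, low-flow optimum) is a
stable property. The GP surrogate assumes a smooth log10 DR surface; heavily
floored (defect-free) regions flatten it, which the `all_floored` flag
surfaces. The desirability anchors for the areas are data-dependent by
design, so re-running with a different seed moves the absolute desirability
values slightly. None of the reported constants of the motivating assay that
depend on unavailable raw instrument data are claimed as reproduced; the
package reproduces the method, and its arithmetic identities, exactly.
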