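---
title: "Calibration curves, inverse prediction, and why the parameterization matters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration curves, inverse prediction, and why the parameterization matters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elisacal)
```

## The problem

An ELISA plate reader reports optical densities (OD); what the analyst
needs is concentrations. The link is the standard curve: a four-parameter
logistic (4PL) fit to wells of known concentration, inverted at each
unknown well's OD. Statistically, every reported concentration is an
*inverse prediction* from a regression, and it inherits the uncertainty of
the fitted curve. `elisacal` makes that uncertainty explicit and asks a
design question with practical consequences: of the two standard ways to
parameterize the 4PL — on the concentration scale or on the log-concentration
scale — which one yields tighter, more stable inverse predictions from a
realistic calibration set?

## Model and assumptions

Both parameterizations describe the same sigmoid (see the README for the
formulas), mapped onto each other by `A = α₄`, `B = α₁`, `xmid = ln α₃`,
`scal = −1/α₂`. The regression model is ordinary nonlinear least squares:
ODs are the curve value plus i.i.d. homoscedastic Gaussian noise. Those two
assumptions — constant residual variance and approximate normality — are
exactly what `residual_diagnostics()` scores, because the Monte-Carlo
uncertainty propagation relies on them.

Orientation is deliberately unconstrained. A competitive assay has high OD
at low concentration, but the code imposes no ordering on the asymptote
pair (`A`,`B`) or (`α₁`,`α₄`): orientation is carried by the sign of
`scal` (or `α₂`), and the pair (`A`,`B`,`scal`) and its swapped/negated
twin describe the identical curve. Fits may therefore return either
labelling; all downstream code is agnostic to it.

Natural logarithms are used throughout: the customary substituted low
standard of 0.05 µg/L sits at `ln 0.05 ≈ −3.0`, just left of the lowest
nonzero standard (`ln 0.15 ≈ −1.9`), which is the placement that motivates
that choice of concentration.

## Fitting

`fit_standard_curve()` minimizes the residual sum of squares by
Levenberg–Marquardt (`minpack.lm::nlsLM`), with convergence declared at a
relative RSS change below 1e−10 and at most 500 iterations. Starting
values come from in-package self-starters: asymptotes from the mean OD of
the two smallest- and two largest-predictor points, midpoint from the
point whose OD is nearest the asymptote midpoint, and shape from the slope
of a logit-linearization of the scaled response. The "two extreme points
per asymptote" constant is a documented fixed choice. If the optimizer
cannot take a step from an exactly-placed start (which can happen on
noise-free, symmetric data), the start is retried with a small
deterministic relative jitter (1e−3, then 3e−2).

Three deliberate choices:

- **No parameter bounds.** Bounded optimization would mask the very
  instability the comparison is designed to expose.
- **Replicates are individual rows** — no pre-averaging.
- **Failures are data, not crashes.** A fit that exhausts its iteration
  budget is returned with `converged = FALSE`; a singular Jacobian yields
  a fit without covariance, which downstream draws refuse with a specific
  error class.

The coefficient covariance is the standard large-sample
`σ̂² (JᵀJ)⁻¹`; residual degrees of freedom are `n − 4`.

## Zero-concentration wells and the log form

The log form cannot take `x = 0`. `prepare_curve_data()` offers two
policies: `"drop"` removes blanks (84 rows under the default design), and
`"substitute"` (the default) relabels them at `c0 = 0.05` µg/L, keeping
their measured ODs (90 rows, six at predictor −3.0). Relabelling is
defensible here because the curve value at 0.05 µg/L is within a few
thousandths of an OD unit of its zero-concentration limit — far below
measurement noise — and it keeps the training set at exactly 12 wells in
the comparison experiment. When a plate genuinely contains wells at the
substitution concentration (the default design does: 0.15/3 = 0.05), they
participate as ordinary standards.

## Monte-Carlo inverse prediction

`draw_posterior()` implements the classical normal-theory simulation for
nonlinear-regression prediction: per draw, `σⱼ = σ̂ √(df/χ²_df)` and
`θⱼ ~ N(θ̂, (σⱼ/σ̂)² cov)`. Each draw is a plausible standard curve;
inverting all of them at an observed OD (closed form, no iteration) gives
the sample whose median and central 50%/95% quantile intervals
(`quantile()` type 7, linear interpolation) summarize the predicted
concentration. Defaults follow common practice: 10,000 draws, levels
0.5 and 0.95.

Only coefficient uncertainty is propagated by default — the observed OD is
taken as given. `add_od_noise = TRUE` additionally perturbs the OD by
`N(0, σⱼ²)` per draw for full predictive uncertainty; it is off by default
because the curve-uncertainty-only quantity is what the comparison
experiment is about. Coverage checks of the default intervals therefore
use a *noise-free* OD (the curve value at the true concentration); against
noisy ODs the default intervals are intentionally narrower than full
predictive intervals.

Draws at which an OD cannot be inverted (it falls at or outside the drawn
curve's open asymptote interval, or the drawn coefficients admit no real
solution) are counted and reported per prediction (`n_out_of_range`),
excluded from quantiles, and never clipped: an OD equal to the
zero-concentration asymptote of the *concentration-scale* curve maps to 0
(that value is attained at `x = 0`), but everything else out of range is
`NA` by design. If every draw fails for an OD, prediction raises a classed
error; the comparison harness catches it and drops that well from both
models' metrics (reported as `n_dropped_wells`).

## The comparison experiment

`compare_models()` runs two steps. Step 1, goodness of fit: both forms on
all 90 known wells. Step 2, predictive uncertainty: train on the 12
undiluted calibration wells (10 standards + 2 blanks, the set a routine
assay would use), predict all 78 remaining known wells, and reduce to

- the ratio of mean 95% interval widths (log / conc), overall and
  restricted to wells with true concentration in [0.1, 2] µg/L (closed
  band; a regulatory range of concern),
- the per-draw predictive sum of squares `SSⱼ = Σ(x̂ⱼ − x_true)²` with its
  mean and 95% interval — per-draw, because the instability lives in the
  draw-level tail: a handful of astronomical draws inflate the mean far
  beyond the central interval, which is precisely the diagnostic signature
  of the unstable parameterization. Non-invertible draws contribute the
  well's largest finite inversion, so no draw is dropped; squares of
  astronomical draws may overflow to `Inf`, in which case the mean honestly
  reports `Inf` while the interval summarizes the finite draws,
- 50%/95% interval coverage of the known concentrations.

Each model gets its own seeded draw stream (offsets of the experiment
seed), so results are deterministic given the seed and independent of
test-well ordering.

## The synthetic plate generator

`plate_design()`/`simulate_plate()` emulate a 96-well dilution-series
calibration experiment: 5 standard stocks and a QC stock diluted by
{1, 1.5, 2, 2.5, 3, 3.5, 4} in duplicate, 6 blanks, 6 unknown wells.
ODs are the generating log-scale curve plus i.i.d. Gaussian noise;
blanks sit at the curve's zero-concentration limit, so one truth serves
both model forms consistently. The generator requires the unknown sample's
true concentration explicitly — there is no hidden default truth for it.

Defaults, chosen once and documented:

- `noise_sd = 0.10` OD units, the scale of residual SEs seen on real
  microcystin plates;
- generating curve `A = 0.15, B = 1.8, xmid = ln 0.75, scal = −0.35`: an
  arbitrary but realistic competitive curve, placed so the mid-response is
  near 1 µg/L and both asymptotes are expressed within the design's
  effective range (0.0375–5 µg/L). The placement matters: a flatter curve
  leaves an asymptote outside the data and that coefficient weakly
  identified, which is a property of assay design, not of the fitting
  code.

What the generator does *not* emulate: plate-position and edge effects,
drift, inter-plate variation, or concentration-dependent noise (a
CV-proportional option exists in spirit via `noise_sd` scaling but
operational error sources are out of scope). Tests passing on synthetic
plates therefore validate the statistical machinery under the stated
model, not the behaviour of any particular physical kit.

## Numerical notes

- `eval_fpl_log()` is computed through `plogis`, so it saturates cleanly
  at the asymptotes for arguments of any magnitude (including ±∞) instead
  of overflowing.
- Closed-form inversion is ill-conditioned near the asymptotes: for
  shape magnitudes around 1.5 the round trip `invert(eval(x))` holds to
  1e−8 relative across x ∈ [1e−4, 1e4], but much steeper curves push ODs
  within ~1e−12 OD of an asymptote at the range edges and double precision
  then surrenders several digits. This is intrinsic to the arithmetic, not
  to the implementation; property tests randomize shapes in the
  well-conditioned regime that real immunoassay curves occupy.
- Posterior draws use an eigendecomposition square root of the covariance,
  tolerating the tiny negative eigenvalues a near-singular `JᵀJ` can
  produce.
- Monte-Carlo study sizes in the test suite (200 recovery plates, 500
  coverage replicates, 50 comparison plates; 2,000–4,000 draws where full
  10,000-draw precision is not needed) were sized to estimate each rate
  comfortably within the tolerance being checked.

## Known limitations

- The posterior is the large-sample normal approximation, not MCMC; for
  severely ill-conditioned fits (exactly the concentration-scale regime
  this package is designed to expose) the approximation is itself part of
  the phenomenon being measured, not a calibrated posterior.
- Weighted least squares, robust losses, bootstrap and profile-likelihood
  intervals, and five-parameter logistic curves are out of scope.
- Goodness-of-fit degrees of freedom are always `n − 4`; published
  analyses occasionally report other conventions, and no attempt is made
  to match them.
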