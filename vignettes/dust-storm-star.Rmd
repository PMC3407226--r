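---
title: "Modelling clinic-visit counts around dust storm events with structured additive regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clinic-visit counts around dust storm events with structured additive regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adstar)
```

## The scientific problem

Asian dust storms (ADS) carry mineral dust from the Mongolian and Chinese
deserts over East Asia in late winter and spring, sharply raising coarse
particulate levels for a day or a few days at a time.  Health effects on
children's respiratory systems are expected to appear not only on the storm
days themselves but over the week that follows, and to differ across the
districts of a city because clinic accessibility and population composition
differ.  `adstar` implements a complete, testable pipeline for this kind of
analysis: it turns a published storm-day list into an exposure-lag calendar,
joins daily district-level visit counts with a citywide temperature series
and census populations, fits an overdispersed Poisson structured additive
regression (STAR) model, and reports effects in the conventions of the
environmental-epidemiology literature (percent change in relative rate;
posterior-probability maps of district effects).

Because the claims data such analyses use are confidential, the package
also ships a synthetic-data generator that draws district-day panels from
the model's own data-generating process with known parameters.  Every
statistical claim the package makes about itself is backed by a computation
on such panels.

## The model

For visit count $y_{ts}$ on day $t$ in district $s$, with district
population $P_s$,

$$y_{ts} \sim \text{Poisson-type}(\mu_{ts}), \qquad
\operatorname{Var}(y_{ts}) = \varphi\,\mu_{ts},$$

$$\log \mu_{ts} = \log P_s + \beta_0 + \mathbf{dow}_t\gamma +
\mathbf{dsli}_t\delta + f_{\text{time}}(t) + f_{\text{temp}}(T_t) +
f_{\text{spat}}(s).$$

* **DOW** is a block of six Monday–Saturday indicators (Sunday is the
  reference).  In a first-come-first-serve outpatient system the weekly
  service schedule dominates short-term variation, so these are fixed
  effects, not a smooth.
* **DSLI**, the dust-storm lag index, is a block of eight indicators:
  `lag0` marks days inside a storm event and `lag1`–`lag7` mark the seven
  days after an event ends; all remaining days are the reference.  When a
  day is within seven days of two events, the most recent event (minimum
  lag) wins; a storm day is always `lag0` even if it trails an earlier
  event.  This most-recent-exposure tie-break is the standard
  distributed-lag convention; it matters because real storm calendars
  contain closely spaced events.
* $f_{\text{time}}$ and $f_{\text{temp}}$ are cubic B-spline smooths on
  equidistant knots whose coefficients carry a second-order random-walk
  (RW2) prior, i.e. a squared-second-difference penalty.  The RW2 null
  space (constant and linear sequences) is unpenalized, so the smooths
  shrink toward linear trends, not toward zero.
* $f_{\text{spat}}$ is a Markov-random-field district effect with an
  intrinsic conditional autoregressive (CAR) prior: each district's effect
  is conditionally normal around the mean of its neighbours with variance
  $\tau^2_{\text{spat}}/n_s$.  Its joint precision is the graph Laplacian
  of the district adjacency graph (degree on the diagonal, $-1$ for
  neighbours), which the package builds from a plain edge list.
* Each smoothing variance $\tau^2_j$ carries an inverse-gamma
  IG(0.001, 0.001) hyperprior; $\varphi$ absorbs extra-Poisson variation.

Identifiability: each smooth is reparameterized to a sum-to-zero block so
the intercept keeps its interpretation as the overall log rate.  For the
RW2 smooths only the constant direction is removed — the linear trend stays
inside the block as its remaining unpenalized direction; for the MRF the
constant is the whole null space on a connected graph, so the constrained
spatial penalty has full rank.  Centering uses plain column sums by
default; a variant that re-centers with the converged working weights is
available (`constraint = "weighted"`) and changes only the intercept/smooth
split, not the fitted model, which the test suite asserts.

## Estimation

Estimation is penalized-likelihood empirical Bayes, not MCMC.  The fitting
loop alternates:

1. **Inner loop** — penalized iteratively reweighted least squares for the
   coefficients at fixed smoothing weights $\lambda_j = \varphi/\tau^2_j$:
   working response $z = \eta + (y-\mu)/\mu$, weights $\mu$, ridge term
   $\lambda_j K_j$, with step-halving on the penalized deviance so the
   objective never increases.
2. **Outer loop** — empirical-Bayes REML fixed-point updates
   $$\tau^2_j \leftarrow \frac{b_j^\top K_j b_j + 2b}{\text{edf}_j -
   \text{null}_j + 2(a+1)},$$
   where $\text{edf}_j$ is the trace of the term's block of the influence
   operator and $(a, b)$ is the IG hyperprior (a `prior = "flat"` option
   drops it).  The fixed point of the flat update coincides with the
   stationary point of the Gaussian restricted likelihood of the working
   model, which the tests verify against a brute-force grid search.
   $\varphi$ is updated as the Pearson statistic over $n$ minus the total
   effective degrees of freedom.

The reported covariance is $\varphi\,(X^\top W X + \sum_j \lambda_j
K_j)^{-1}$ at convergence; all intervals, p-values and posterior
probabilities derive from it.  Wald 95% intervals use the 1.96 multiplier
on the log scale and are transformed to the percent-change scale
($100(e^\beta - 1)$), and district classifications use each district's
marginal normal posterior: significantly positive (negative) when at least
80% of the posterior mass for the relative rate lies above (below) 1.

### Numerical choices

* Convergence: relative change of all coefficients and all $\tau^2_j$
  below `tol = 1e-6`; inner cap 50, outer cap 200.  Non-convergence is an
  error carrying the objective trace.
* $\tau^2$ floor `1e-8` (with a warning), initialization $\tau^2 = 0.1$,
  $\varphi = 1$, $\beta_0$ at its intercept-only closed form, all other
  coefficients zero.
* Zero-eigenvalue tolerance for penalty null spaces: $10^{-9}$ times the
  largest eigenvalue.
* Degenerate inputs: all-zero counts, constant covariates, disconnected
  adjacency graphs, missing panel cells and malformed calendar entries are
  all errors with context; missing temperature days are linearly
  interpolated with a message.  A single-district panel is fitted without
  a spatial term.

### Basis dimensions

The temperature smoother uses 10 interior knots (cubic).  The
calendar-time smoother defaults to **about 8 interior knots per year** of
study window (floor 7).  A fixed small basis cannot track annual
respiratory seasonality over a decade-long window, and the resulting
seasonal residual masquerades as overdispersion and biases the indicator
effects; roughly 7–8 degrees of freedom per year is the established choice
in daily time-series studies of air pollution and health.  Both knot
counts, the degree and the constraint mode are configuration
(`star_spec()`), since district-day data cannot pin them down sharply.

## The synthetic generator

`generate_scenario()` draws panels from exactly the model above.  Defaults
define the reference ("paper-like") study conditions:

* 12 districts over 1997–2007 (4017 days), storm calendar from the shipped
  storm-day list (76 events, 172 storm days), a hand-built adjacency edge
  list resembling the Taipei City district layout, and synthetic district
  populations of plausible 2000-census magnitude (the files are labelled
  synthetic; they assert no geography).
* Indicator-effect presets per age group taken from the published
  percent-change table (e.g. Monday $+37.64\%$, storm-day lag0 $-6.28\%$
  for school children), stored exactly as $\log(1 + \text{pct}/100)$.
* Per-child daily visit rates of 0.045 (preschool), 0.032 (school) and
  0.022 (all children), chosen once so that per-district mean daily counts
  land in the several-hundred-to-~1500 range reported for citywide
  pediatric respiratory visits.
* A seasonal time trend (annual + semiannual sinusoids plus a slow
  quadratic, amplitude 0.12 on the log scale), a centered quadratic
  (U-shaped) temperature effect ($0.0015\,(T-23)^2$, a common shape for
  temperature–respiratory relations), and a citywide temperature series
  built as a seasonal sinusoid around 23 °C with AR(1) noise.
* District effects drawn from the intrinsic CAR prior with
  $\tau^2_{\text{spat}} = 0.0225$ (spatial SD 0.15, between the ranges
  reported for preschool and school children) and centered.
* Overdispersion $\varphi = 2$ via gamma–Poisson mixing, so
  $\operatorname{Var} = \varphi\mu$ exactly; the published analysis states
  only the first two moments, and the quasi-likelihood fitter matches
  moments, not the full law.  Age groups are generated independently, each
  from its own preset, so "all children" is its own draw rather than the
  sum of the two subgroups.

The generator and the fitter implement the linear predictor independently
(indicator lookups versus design matrices), so recovery experiments are
non-circular.  All randomness flows from one integer seed through R's
default Mersenne–Twister stream, making panels reproducible across
platforms.

### What the tests show — and what they cannot

`recovery_experiment()` refits replicate panels and tabulates bias, RMSE,
95% CI coverage and sign recovery.  The shipped validation uses a scaled
replicate study (3 districts × 730 days, 20 replicates — sizes chosen to
keep the default check fast at desk scale) plus a single full-scale
12 × 4017 fit, and a 100-replicate null-exposure calibration of the Wald
tests (4 districts × 365 days).  Passing these shows the estimator is
correct and calibrated *for data generated by its own model*.  It cannot
show that real claims data satisfy that model: true visit series carry
holiday effects, epidemics, policy changes and cross-infection dynamics
that the generator deliberately omits, and the published pollutant
contrasts (PM10, O3) have no counterpart here because exposure is binary
event membership.

## Known limitations

* The model is additive: no space–time interactions and no
  district-specific lag effects.
* Empirical-Bayes Gaussian approximation throughout; no MCMC, so
  posterior probabilities are approximate, and numerical equality with
  MCMC-based or other REML software for the same model class is not
  claimed.
* Whether the population offset should be the total district population
  or the modeled age band's own population is ambiguous in practice; the
  fitter defaults to the group's own population
  (`offset_population = "group"`) and exposes the alternative.
* Whether published intervals scale with the overdispersion is similarly
  unstated in the conventions this follows; here the covariance is scaled
  by $\hat\varphi$.

## A short worked example

```{r example, eval = FALSE}
scen <- generate_scenario(scenario_config(
  n_districts = 3, study_start = "2001-01-01", study_end = "2002-12-31",
  calendar = "random", events_per_year = 7, age_groups = "all", seed = 42))
fit <- fit_star(scen$panel, "all")
effect_report(fit)       # percent change in rate per DOW / lag dummy
classify_spatial(fit)    # 80% posterior-probability district classes
```
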