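# adstar

Spatiotemporal structured additive regression (STAR) for daily clinic-visit
counts around Asian dust storm (ADS) events.

## What this package is for

Environmental epidemiologists studying dust storms face a recurring
analysis shape: a list of storm events, daily disease counts aggregated to
city districts, and the need to separate a lagged exposure signal from
day-of-week scheduling effects, seasonal and long-term trends, weather,
and stable geographic differences in clinic use.  `adstar` implements that
pipeline end to end:

1. **Exposure-lag calendar** — parse a published storm-day list
   (`M/D` / `M/D–M/D` entries per year), merge consecutive days into
   events, and classify every study day as `lag0` (storm day), `lag1`–`lag7`
   (days after an event ends; the most recent event wins), or reference.
2. **Panel assembly** — join counts, a citywide temperature series,
   district populations (log-population offsets) and a district adjacency
   edge list into a validated district-day panel, with day-of-week and
   dust-storm-lag-index (DSLI) indicator blocks.
3. **Model fitting** — an overdispersed Poisson STAR model

   log mu = offset + b0 + DOW gamma + DSLI delta + f_time(t) + f_temp(T) + f_spat(s),
   Var(y) = phi * mu,

   with cubic P-spline smooths under second-order random-walk penalties
   for calendar time and temperature, a Markov-random-field district
   effect with intrinsic CAR prior (graph-Laplacian precision,
   IG(0.001, 0.001) hyperpriors on the smoothing variances), fitted by
   penalized IWLS with empirical-Bayes REML variance updates and a
   Pearson estimate of the overdispersion phi.
4. **Reporting** — percent change in relative rate, `100*(exp(beta)-1)`,
   with 95% Wald intervals, and the three-way district classification by
   80% posterior probability of the relative rate lying above or below 1.
5. **Synthetic data** — a generator that draws panels from the exact
   model with known parameters (including presets matching published
   effect magnitudes), plus `recovery_experiment()` for coverage/bias
   studies.  This stands in for the confidential insurance-claims data
   such studies use.

## Worked example

Generate a small synthetic study (3 districts, 2 years, random storm
calendar), fit it, and report:

```r
library(adstar)

scen <- generate_scenario(scenario_config(
  n_districts = 3, study_start = "2001-01-01", study_end = "2002-12-31",
  calendar = "random", events_per_year = 7, age_groups = "all", seed = 42))

fit <- fit_star(scen$panel, "all")
fit
#> Structured additive regression fit (poisson working model)
#> Age group: all
#> n = 2190  total edf = 38.94  phi = 2.033
#> tau^2: time = 0.01054, temperature = 0.0004224, spatial = 0.0148
#> Outer iterations: 7  penalized deviance: 4422.17

er <- effect_report(fit)
er[er$block == "DSLI", ]
#>  block term percent     lo     hi        p
#>   DSLI lag0  -2.563 -3.837 -1.272 1.11e-04
#>   DSLI lag1  -0.410 -2.114  1.325 6.41e-01
#>   DSLI lag2   2.515  0.708  4.355 6.18e-03
#>   DSLI lag3   3.548  1.780  5.347 7.22e-05
#>   DSLI lag4  -0.913 -2.705  0.912 3.25e-01
#>   DSLI lag5   1.018 -0.840  2.911 2.85e-01
#>   DSLI lag6  -1.661 -3.434  0.145 7.12e-02
#>   DSLI lag7   2.662  0.795  4.563 5.02e-03
```

The `percent` column is the percent change in the daily visit rate on
each lag day relative to non-storm, non-lag days: here visits drop about
2.6% on storm days themselves (people stay in during the storm) and rise
2.5–3.5% on days 2, 3 and 7 after an event ends.  The generating values
for this scenario were (lag0..lag7) −3.66, −2.05, 1.78, 2.40, 0.66, 1.74,
−1.01, 2.26 percent, and the estimated overdispersion 2.03 sits next to
the generating phi = 2.  District effects classify by posterior
probability:

```r
classify_spatial(fit, threshold = 0.8)
#>  district  effect    rr      se p_above_1    class
#>       D01  0.0903 1.095 0.00180         1 positive
#>       D02 -0.1036 0.902 0.00169         0 negative
#>       D03  0.0133 1.013 0.00168         1 positive
```

`rr` is each district's relative rate against the citywide mean after
controlling for all temporal terms.  The full 12-district, 4017-day
reference scenario is one call: `paper_like_scenario(seed)`.

The shipped storm-day list for Taipei 1997–2007 is a first-class input:

```r
cal <- parse_calendar(system.file("extdata", "ads_days_taipei_1997_2007.csv",
                                  package = "adstar"), "1997-01-01", "2007-12-31")
cal
#> ADS event calendar: 76 events, 172 storm days
#> Study window: 1997-01-01 to 2007-12-31 (4017 days)
```

A thin command-line wrapper for the generator lives at
`inst/scripts/adstar-simulate.R` (`simulate` and `recover` subcommands).

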