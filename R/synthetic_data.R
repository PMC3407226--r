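#' Synthetic district-day panels with known ground truth
#'
#' Generates visit-count panels from the exact data-generating process of
#' the fitted model -- log-linear day-of-week and dust-storm-lag effects,
#' a smooth seasonal/long-term time trend, a nonlinear (U-shaped)
#' temperature effect, CAR-distributed district effects, log-population
#' offsets and gamma-Poisson overdispersion -- so that every pipeline
#' stage can be exercised and validated without the confidential claims
#' data the model was designed for.
#'
#' @name synthetic_data
#' @keywords internal
NULL

# Table-style effect presets: percent change in rate per dummy.
# DOW order Monday..Saturday; DSLI order lag0..lag7.
EFFECT_PRESETS <- list(
  preschool = list(dow = c(37.55, 0.81, 0.56, 1.35, 3.35, 5.65),
                   dsli = c(-2.53, -2.12, 2.12, 2.19, 0.63, 1.01, -1.07, 2.18)),
  school = list(dow = c(37.88, -1.11, 7.64, -2.09, 2.33, 10.76),
                dsli = c(-6.28, -1.66, 0.73, 3.17, 0.72, 2.44, -0.84, 3.20)),
  all = list(dow = c(37.64, 0.11, 2.90, 0.18, 2.98, 7.39),
             dsli = c(-3.66, -2.05, 1.78, 2.40, 0.66, 1.74, -1.01, 2.26)),
  null = list(dow = rep(0, 6), dsli = rep(0, 8))
)

# per-child daily visit rates setting the count scale of each group
GROUP_RATES <- c(preschool = 0.045, school = 0.032, all = 0.022)

pct_to_log <- function(pct) log(1 + pct / 100)

#' Scenario configuration for the synthetic generator
#'
#' @param n_districts number of districts (12 uses the shipped Taipei-like
#'   adjacency and population fixtures; other values generate a random
#'   connected adjacency and uniform populations)
#' @param study_start,study_end study window (defaults to the 1997--2007
#'   window of the shipped storm calendar)
#' @param calendar `"taipei"` (the shipped storm-day list) or `"random"`
#'   (random events, `events_per_year` per year of 1--3 days)
#' @param events_per_year mean number of random events per year
#' @param effects name of an effect preset (`"preschool"`, `"school"`,
#'   `"all"`, `"null"`) applied to every generated group, or `"paper"` to
#'   give each group its own preset
#' @param age_groups which groups to generate
#' @param phi overdispersion (`Var = phi * mu`); must be `>= 1`
#' @param tau2_spat variance of the CAR prior the district effects are
#'   drawn from
#' @param trend_amp amplitude (log scale) of the seasonal time trend
#' @param temp_effect_amp curvature of the U-shaped temperature effect
#'   (log-rate units per degC^2)
#' @param seed integer seed; the generated panel is a deterministic
#'   function of the configuration
#' @return a list of class `scenario_config`
#' @export
scenario_config <- function(n_districts = 12,
                            study_start = "1997-01-01",
                            study_end = "2007-12-31",
                            calendar = c("taipei", "random"),
                            events_per_year = 7,
                            effects = "paper",
                            age_groups = c("preschool", "school", "all"),
                            phi = 2,
                            tau2_spat = 0.0225,
                            trend_amp = 0.12,
                            temp_effect_amp = 0.0015,
                            seed = 1) {
  calendar <- match.arg(calendar)
  if (phi < 1) stop("phi must be >= 1 (Var = phi * mu)")
  if (!identical(effects, "paper") && !effects %in% names(EFFECT_PRESETS))
    stop("unknown effect preset '", effects, "'")
  stopifnot(all(age_groups %in% AGE_GROUPS))
  structure(list(n_districts = n_districts,
                 study_start = as.Date(study_start),
                 study_end = as.Date(study_end),
                 calendar = calendar,
                 events_per_year = events_per_year,
                 effects = effects,
                 age_groups = age_groups,
                 phi = phi, tau2_spat = tau2_spat,
                 trend_amp = trend_amp,
                 temp_effect_amp = temp_effect_amp,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Log-scale effect preset for one age group
#'
#' @param group `"preschool"`, `"school"`, `"all"` or `"null"`
#' @return list `dow` (6 log effects, Monday..Saturday) and `dsli`
#'   (8 log effects, lag0..lag7)
#' @export
effect_preset <- function(group) {
  p <- EFFECT_PRESETS[[match.arg(group, names(EFFECT_PRESETS))]]
  list(dow = stats::setNames(pct_to_log(p$dow),
                             c("Monday", "Tuesday", "Wednesday", "Thursday",
                               "Friday", "Saturday")),
       dsli = stats::setNames(pct_to_log(p$dsli), paste0("lag", 0:7)))
}

# random storm calendar: ~events_per_year events of 1-3 days, >=2-day gaps
random_calendar <- function(study_start, study_end, events_per_year) {
  n_days <- as.integer(study_end - study_start) + 1L
  n_events <- max(1L, round(events_per_year * n_days / 365.25))
  starts <- sort(sample.int(n_days - 5L, n_events))
  durations <- sample(1:3, n_events, replace = TRUE)
  keep_s <- integer(0); keep_e <- integer(0)
  last_end <- -10L
  for (i in seq_len(n_events)) {
    s <- starts[i]; e <- min(s + durations[i] - 1L, n_days - 1L)
    if (s > last_end + 2L) { keep_s <- c(keep_s, s); keep_e <- c(keep_e, e); last_end <- e }
  }
  ads_calendar_from_events(study_start + keep_s, study_start + keep_e,
                           study_start, study_end)
}

# random connected district graph: random spanning tree + a few chords
random_adjacency <- function(districts) {
  n <- length(districts)
  if (n == 1) stop("need at least 2 districts")
  a <- character(0); b <- character(0)
  for (i in 2:n) {
    j <- if (i == 2) 1L else sample.int(i - 1L, 1L)
    a <- c(a, districts[j]); b <- c(b, districts[i])
  }
  extra <- max(0L, round(n / 4))
  tries <- 0L
  while (extra > 0L && tries < 50L) {
    ij <- sort(sample.int(n, 2L))
    tries <- tries + 1L
    e <- paste(districts[ij[1]], districts[ij[2]])
    if (!e %in% paste(a, b)) {
      a <- c(a, districts[ij[1]]); b <- c(b, districts[ij[2]])
      extra <- extra - 1L
    }
  }
  data.frame(district_a = a, district_b = b)
}

# draw centered spatial effects from the intrinsic CAR prior with
# variance tau2: spectral sample on the Laplacian's non-null eigenvectors
draw_car_effects <- function(K, tau2) {
  eg <- eigen(K, symmetric = TRUE)
  pos <- eg$values > 1e-9 * max(eg$values)
  z <- stats::rnorm(sum(pos))
  drop(eg$vectors[, pos, drop = FALSE] %*% (z * sqrt(tau2 / eg$values[pos])))
}

# seasonal temperature series with AR(1) noise (single citywide station)
simulate_temperature <- function(dates) {
  doy <- as.POSIXlt(dates)$yday
  seasonal <- 23 + 6 * sin(2 * pi * (doy - 110) / 365.25)
  n <- length(dates)
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, 1.5)
  innov <- stats::rnorm(n - 1, 0, 1.5 * sqrt(1 - 0.7^2))
  for (t in 2:n) e[t] <- 0.7 * e[t - 1] + innov[t - 1]
  seasonal + e
}

# gamma-Poisson counts with mean mu and variance phi * mu
draw_counts <- function(mu, phi) {
  if (phi == 1) return(stats::rpois(length(mu), mu))
  stats::rnbinom(length(mu), size = mu / (phi - 1), mu = mu)
}

#' Generate a synthetic panel and its ground truth
#'
#' Draws a full district-day panel from the model's own data-generating
#' process at the configured parameter values.  Deterministic given
#' `config$seed`.
#'
#' @param config a [scenario_config()]
#' @return list with `panel` (a `panel_dataset`), `truth` (class
#'   `synthetic_truth`: per-group intercepts and log effects, the
#'   time-trend and temperature-effect values used, the spatial effects,
#'   `phi`, populations, adjacency, calendar, seed), and `calendar`
#' @export
generate_scenario <- function(config) {
  set.seed(config$seed)
  dates <- seq(config$study_start, config$study_end, by = "day")
  n_days <- length(dates)

  # calendar and lag classes
  cal <- if (config$calendar == "taipei") {
    parse_calendar(system.file("extdata", "ads_days_taipei_1997_2007.csv",
                               package = "adstar", mustWork = TRUE),
                   config$study_start, config$study_end)
  } else random_calendar(config$study_start, config$study_end,
                         config$events_per_year)
  lag <- assign_lags(cal)

  # districts, adjacency, populations
  if (config$n_districts == 12) {
    adjacency <- utils::read.csv(system.file(
      "extdata", "taipei_district_adjacency.csv", package = "adstar",
      mustWork = TRUE))
    populations <- utils::read.csv(system.file(
      "extdata", "taipei_populations_synthetic.csv", package = "adstar",
      mustWork = TRUE))
    districts <- sort(unique(c(adjacency$district_a, adjacency$district_b)))
  } else {
    districts <- sprintf("D%02d", seq_len(config$n_districts))
    adjacency <- random_adjacency(districts)
    populations <- expand.grid(district = districts, age_group = AGE_GROUPS,
                               KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    populations$population <- round(stats::runif(nrow(populations), 15000, 35000))
  }
  populations <- populations[populations$age_group %in% config$age_groups, ]

  temps <- data.frame(date = dates, temp_c = simulate_temperature(dates))

  # shared smooth truths (log scale, centered over the window)
  tt <- as.numeric(dates - dates[1])
  Tn <- max(tt)
  f_time <- config$trend_amp * sin(2 * pi * tt / 365.25 - 0.3) +
    0.4 * config$trend_amp * sin(4 * pi * tt / 365.25 + 0.8) +
    0.6 * config$trend_amp * ((2 * tt / Tn - 1)^2)
  f_time <- f_time - mean(f_time)
  f_temp_fun <- function(tc) config$temp_effect_amp * (tc - 23)^2
  f_temp <- f_temp_fun(temps$temp_c)
  f_temp <- f_temp - mean(f_temp)

  Kmrf <- mrf_penalty(adjacency)$K
  Kmrf <- Kmrf[districts, districts]

  dow_idx <- as.POSIXlt(dates)$wday          # 0 = Sunday
  lag_idx <- as.integer(lag$lag_class)       # 1..8 = lag0..lag7, 9 = reference

  truth_groups <- list()
  counts <- NULL
  for (g in config$age_groups) {
    preset <- if (identical(config$effects, "paper")) effect_preset(g)
              else effect_preset(config$effects)
    beta0 <- log(GROUP_RATES[[g]])
    spat <- draw_car_effects(Kmrf, config$tau2_spat)
    names(spat) <- districts

    dow_contrib <- c(0, preset$dow)[dow_idx + 1]          # Sunday = 0
    dsli_contrib <- c(preset$dsli, 0)[lag_idx]            # reference = 0
    day_log <- beta0 + dow_contrib + dsli_contrib + f_time + f_temp

    pops_g <- populations[populations$age_group == g, ]
    for (s in districts) {
      pop <- pops_g$population[pops_g$district == s]
      mu <- pop * exp(day_log + spat[[s]])
      y <- draw_counts(mu, config$phi)
      counts <- rbind(counts, data.frame(date = dates, district = s,
                                         age_group = g, visits = y))
    }
    truth_groups[[g]] <- list(beta0 = beta0, dow = preset$dow,
                              dsli = preset$dsli, spatial = spat)
  }

  panel <- build_panel(counts, temps, populations, adjacency, lag)
  truth <- structure(list(groups = truth_groups,
                          f_time = f_time, f_temp = f_temp,
                          f_temp_fun = f_temp_fun,
                          phi = config$phi,
                          tau2_spat = config$tau2_spat,
                          populations = populations,
                          adjacency = adjacency,
                          calendar = cal,
                          seed = config$seed),
                     class = "synthetic_truth")
  list(panel = panel, truth = truth, calendar = cal)
}

#' The full-scale reference scenario
#'
#' 12 districts by the full 1997--2007 window (4017 days) by three age
#' groups, storm calendar from the shipped storm-day list, dummy-effect
#' presets per age group, overdispersion 2, and district populations
#' calibrated so that mean daily counts per district fall in the
#' hundreds-to-low-thousands range typical of citywide pediatric
#' respiratory visit data.
#'
#' @param seed integer seed
#' @return as [generate_scenario()]
#' @export
paper_like_scenario <- function(seed = 1) {
  generate_scenario(scenario_config(seed = seed))
}

#' Write a generated scenario as its four input CSVs plus truth JSON
#'
#' @param scenario result of [generate_scenario()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panel <- scenario$panel
  rec <- panel$records
  utils::write.csv(data.frame(date = format(rec$date), district = rec$district,
                              age_group = rec$age_group, visits = rec$visits),
                   file.path(dir, "counts.csv"), row.names = FALSE)
  tmp <- unique(rec[, c("date", "temp_c")])
  tmp <- tmp[order(tmp$date), ]
  utils::write.csv(data.frame(date = format(tmp$date), temp_c = tmp$temp_c),
                   file.path(dir, "temperature.csv"), row.names = FALSE)
  utils::write.csv(panel$populations, file.path(dir, "populations.csv"),
                   row.names = FALSE)
  el <- igraph::as_data_frame(panel$graph)
  utils::write.csv(data.frame(district_a = el$from, district_b = el$to),
                   file.path(dir, "adjacency.csv"), row.names = FALSE)
  tr <- scenario$truth
  jsonlite::write_json(
    list(groups = lapply(tr$groups, function(g)
           list(beta0 = g$beta0, dow = as.list(g$dow), dsli = as.list(g$dsli),
                spatial = as.list(g$spatial))),
         phi = tr$phi, tau2_spat = tr$tau2_spat, seed = tr$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates a scenario (one fresh seed per replicate), fits
#' the model to one age group, and tabulates bias, RMSE and 95% Wald CI
#' coverage for the day-of-week and dust-storm-lag log effects, plus the
#' relative error of the overdispersion estimate.
#'
#' @param config a [scenario_config()]; its `seed` seeds the experiment
#'   stream unless `seeds` is given
#' @param n_reps number of replicates (>= 2)
#' @param age_group group to fit
#' @param seeds optional integer vector of per-replicate seeds
#' @param spec a [star_spec()] for the fits
#' @return list of class `recovery_experiment`: `summary` (per-parameter
#'   table: truth, mean estimate, bias, rmse, coverage), `phi` (truth,
#'   mean estimate, relative errors), `n_converged`, `failures`,
#'   `estimates` (replicate-level draws)
#' @export
recovery_experiment <- function(config, n_reps, age_group = "all",
                                seeds = NULL, spec = star_spec()) {
  if (n_reps < 2) stop("need at least 2 replicates")
  if (is.null(seeds)) {
    set.seed(config$seed)
    seeds <- sample.int(.Machine$integer.max %/% 2, n_reps)
  }
  stopifnot(length(seeds) == n_reps)

  est <- list(); failures <- list()
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- seeds[r]
    scen <- generate_scenario(cfg)
    tg <- scen$truth$groups[[age_group]]
    truth_vec <- c(tg$dow, tg$dsli)
    res <- tryCatch({
      fit <- fit_star(scen$panel, age_group, spec)
      fx <- fixed_effects(fit)
      fx <- fx[fx$term != "(Intercept)", ]
      data.frame(rep = r, seed = seeds[r], term = fx$term,
                 truth = unname(truth_vec[fx$term]),
                 estimate = fx$estimate, se = fx$se, p = fx$p,
                 phi_hat = fit$phi)
    }, error = function(e) e)
    if (inherits(res, "error")) failures[[length(failures) + 1]] <-
      list(rep = r, seed = seeds[r], message = conditionMessage(res))
    else est[[length(est) + 1]] <- res
  }
  if (!length(est)) stop("every replicate failed to fit")
  est <- do.call(rbind, est)
  est$covered <- abs(est$estimate - est$truth) <= 1.96 * est$se

  terms <- unique(est$term)
  summary <- do.call(rbind, lapply(terms, function(tm) {
    e <- est[est$term == tm, ]
    data.frame(term = tm, truth = e$truth[1],
               mean_estimate = mean(e$estimate),
               bias = mean(e$estimate - e$truth),
               rmse = sqrt(mean((e$estimate - e$truth)^2)),
               coverage = mean(e$covered),
               sign_agreement = mean(sign(e$estimate) == sign(e$truth)))
  }))
  phi_hat <- tapply(est$phi_hat, est$rep, function(v) v[1])
  structure(list(summary = summary,
                 phi = list(truth = config$phi,
                            mean_estimate = mean(phi_hat),
                            rel_error = mean(abs(phi_hat - config$phi) / config$phi)),
                 n_converged = length(unique(est$rep)),
                 failures = failures,
                 estimates = est),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat("Parameter-recovery experiment:", x$n_converged, "converged replicates",
      sprintf("(%d failed)\n", length(x$failures)))
  cat(sprintf("phi: truth %.3g, mean estimate %.3g (mean rel. error %.1f%%)\n",
              x$phi$truth, x$phi$mean_estimate, 100 * x$phi$rel_error))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
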