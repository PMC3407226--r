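# Toy model-term builder shared by the oracle tests: small panel, small bases.
toy_terms <- function(seed = 5, years = 1, knots = c(7, 7)) {
  scen <- small_scenario(seed = seed, years = years)
  spec <- star_spec(time_knots = knots[1], temp_knots = knots[2])
  list(scen = scen, spec = spec,
       tm = adstar:::build_model_terms(scen$panel, "all", spec))
}

test_that("the intercept-only Poisson model hits its closed form", {
  set.seed(7)
  y <- rpois(40, 25)
  off <- log(runif(40, 500, 2000))
  f <- adstar:::fit_star_engine(y, off,
                                matrix(1, 40, 1, dimnames = list(NULL, "(Intercept)")),
                                list(), star_spec(phi = 1))
  expect_equal(unname(f$coefficients), log(sum(y) / sum(exp(off))), tolerance = 1e-10)
  expect_equal(unname(f$edf["fixed"]), 1)
})

test_that("penalized IWLS with fixed smoothing matches a dense Newton oracle", {
  tt <- toy_terms(seed = 5)
  stk <- adstar:::stack_blocks(tt$tm$fixed, tt$tm$smooths)
  lam <- list(time = 2, temperature = 5, spatial = 1.3)
  S <- adstar:::total_penalty(stk, lam)
  init <- numeric(ncol(stk$X))
  init[1] <- log(sum(tt$tm$y) / sum(exp(tt$tm$offset)))
  res <- adstar:::piwls(tt$tm$y, stk$X, tt$tm$offset, S, init, tol = 1e-12)
  oracle <- newton_penalized_poisson(tt$tm$y, stk$X, tt$tm$offset, S, init)
  expect_lt(max(abs(res$beta - oracle)), 1e-6)
})

test_that("fit_star with all variances fixed solves the same penalized likelihood", {
  scen <- small_scenario(seed = 6, years = 1)
  tau2 <- c(time = 0.05, temperature = 0.02, spatial = 0.1)
  spec <- star_spec(time_knots = 7, temp_knots = 7, phi = 1, tau2_fixed = tau2)
  fit <- fit_star(scen$panel, "all", spec)
  stk <- fit$stack
  S <- adstar:::total_penalty(stk, as.list(1 / tau2))
  init <- numeric(ncol(stk$X))
  init[1] <- log(sum(fit$y) / sum(exp(fit$offset)))
  oracle <- newton_penalized_poisson(fit$y, stk$X, fit$offset, S, init)
  expect_lt(max(abs(unname(fit$coefficients) - oracle)), 1e-6)
})

test_that("the REML variance update matches a grid search of the restricted likelihood", {
  set.seed(8)
  n <- 200
  x <- seq(0, 1, length.out = n)
  sigma2 <- 0.25
  y <- sin(2 * pi * x) + rnorm(n, 0, sqrt(sigma2))
  bb <- bspline_basis(x, 12, 3)
  pp <- rw2_penalty(ncol(bb$X))
  sm <- list(s1 = apply_constraint(bb$X, pp$K, null_dim = pp$null_dim))
  f <- adstar:::fit_star_engine(y, rep(0, n),
                                matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                                sm, star_spec(phi = sigma2, prior = "flat"),
                                family = "gaussian")
  X <- cbind(1, sm$s1$X)
  jp <- 1 + seq_len(ncol(sm$s1$X))
  grid <- exp(seq(log(1e-5), log(10), length.out = 500))
  vals <- vapply(grid, function(t2) gaussian_reml(y, X, sm$s1$K, jp, sigma2, t2), 0)
  t2_grid <- grid[which.max(vals)]
  # agreement within the multiplicative grid step (~2.8%)
  expect_lt(abs(log(f$tau2[["s1"]]) - log(t2_grid)), diff(log(grid[1:2])) * 2)
})

test_that("penalized deviance matches a from-scratch recomputation and the trace descends", {
  scen <- small_scenario(seed = 9, years = 1)
  fit <- fit_star(scen$panel, "all", star_spec(time_knots = 7, temp_knots = 7))
  # independent recomputation from (y, mu, b, K)
  mu <- fit$fitted; y <- fit$y
  dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  pen <- 0
  for (nm in names(fit$stack$Ks)) {
    bj <- fit$coefficients[fit$stack$idx[[nm]]]
    pen <- pen + (fit$phi / fit$tau2[[nm]]) * drop(t(bj) %*% fit$stack$Ks[[nm]] %*% bj)
  }
  expect_equal(penalized_deviance(fit), dev + pen, tolerance = 1e-10)

  # inner-loop trace of a single penalized IWLS run is non-increasing
  stk <- fit$stack
  S <- adstar:::total_penalty(stk, as.list(fit$phi / fit$tau2))
  init <- numeric(ncol(stk$X)); init[1] <- log(sum(y) / sum(exp(fit$offset)))
  res <- adstar:::piwls(y, stk$X, fit$offset, S, init)
  expect_true(all(diff(res$trace) <= 1e-8))
})

test_that("a saturated unpenalized fit drives the deviance to zero", {
  y <- c(3, 8, 1, 12, 6)
  X <- diag(5); colnames(X) <- paste0("c", 1:5)
  f <- adstar:::fit_star_engine(y, rep(0, 5), X, list(), star_spec(phi = 1))
  expect_lt(f$deviance, 1e-8)
})

test_that("effective degrees of freedom behave as hat-matrix traces", {
  scen <- small_scenario(seed = 10, years = 1)
  fit <- fit_star(scen$panel, "all", star_spec(time_knots = 7, temp_knots = 7))
  edf <- effective_dof(fit)
  # unpenalized fixed block (intercept + 6 DOW + 8 DSLI) counts exactly
  expect_equal(unname(edf["fixed"]), 15, tolerance = 1e-6)
  # per-term edf within [null dim, basis dim]
  for (nm in names(fit$smooths)) {
    expect_gte(edf[[nm]], fit$smooths[[nm]]$null_dim - 1e-6)
    expect_lte(edf[[nm]], ncol(fit$smooths[[nm]]$X) + 1e-6)
  }
  # total equals the dense hat-matrix trace
  stk <- fit$stack
  w <- fit$fitted
  S <- adstar:::total_penalty(stk, as.list(fit$phi / fit$tau2))
  H <- (stk$X * sqrt(w)) %*% solve(crossprod(stk$X * sqrt(w)) + S, t(stk$X * sqrt(w)))
  expect_equal(fit$edf_total, sum(diag(H)), tolerance = 1e-8)

  # extreme smoothing drives a smooth's edf to its null-space dimension
  fit2 <- fit_star(scen$panel, "all",
                   star_spec(time_knots = 7, temp_knots = 7, phi = 1,
                             tau2_fixed = c(time = 1e-12, spatial = 1e-12)))
  edf2 <- effective_dof(fit2)
  expect_equal(unname(edf2["time"]), 1, tolerance = 1e-3)      # linear trend left
  expect_equal(unname(edf2["spatial"]), 0, tolerance = 1e-3)   # nothing left
})

test_that("district relabeling permutes spatial effects and nothing else", {
  scen <- small_scenario(seed = 15, years = 1, n_districts = 4)
  fit1 <- fit_star(scen$panel, "all", star_spec(time_knots = 7, temp_knots = 7))

  relab <- c(D01 = "Z4", D02 = "Z3", D03 = "Z2", D04 = "Z1")
  rec <- scen$panel$records
  counts <- data.frame(date = rec$date, district = unname(relab[rec$district]),
                       age_group = rec$age_group, visits = rec$visits)
  temps <- unique(rec[, c("date", "temp_c")])
  pops <- scen$panel$populations
  pops$district <- unname(relab[pops$district])
  el <- igraph::as_data_frame(scen$panel$graph)
  adj <- data.frame(district_a = unname(relab[el$from]),
                    district_b = unname(relab[el$to]))
  panel2 <- build_panel(counts, temps, pops, adj, scen$panel$lag)
  fit2 <- fit_star(panel2, "all", star_spec(time_knots = 7, temp_knots = 7))

  fx1 <- fixed_effects(fit1); fx2 <- fixed_effects(fit2)
  expect_equal(fx2$estimate, fx1$estimate, tolerance = 1e-5)
  sp1 <- spatial_effects(fit1); sp2 <- spatial_effects(fit2)
  sp1$relabeled <- unname(relab[sp1$district])
  expect_equal(sp2$effect[match(sp1$relabeled, sp2$district)], sp1$effect,
               tolerance = 1e-5)
})

test_that("a calendar without storms drops the exposure block entirely", {
  mp <- manual_panel(n_days = 60, visits = rpois(120, 50))
  fit <- fit_star(mp$panel, "all", star_spec(time_knots = 7, temp_knots = 7))
  expect_false(any(grepl("^lag", names(fit$coefficients))))
  expect_equal(unname(effective_dof(fit)["fixed"]), 7, tolerance = 1e-6)
})

test_that("degenerate inputs and non-convergence raise informative conditions", {
  mp <- manual_panel(n_days = 21, visits = rep(0, 42))
  expect_error(fit_star(mp$panel, "all"), "all counts are zero")

  scen <- small_scenario(seed = 16, years = 1)
  err <- tryCatch(
    fit_star(scen$panel, "all",
             star_spec(time_knots = 7, temp_knots = 7, outer_cap = 1, tol = 1e-14)),
    error = function(e) e)
  expect_s3_class(err, "star_fit_nonconvergence")
  expect_true(length(err$trace) >= 1)

  expect_warning(
    fit_star(scen$panel, "all",
             star_spec(time_knots = 7, temp_knots = 7, tau2_floor = 10)),
    "floored")
})

test_that("weighted and unweighted constraint centering give the same fitted model", {
  scen <- small_scenario(seed = 17, years = 1)
  f1 <- fit_star(scen$panel, "all", star_spec(time_knots = 7, temp_knots = 7))
  f2 <- fit_star(scen$panel, "all",
                 star_spec(time_knots = 7, temp_knots = 7, constraint = "weighted"))
  expect_equal(f2$fitted, f1$fitted, tolerance = 1e-3)
  fx1 <- fixed_effects(f1); fx2 <- fixed_effects(f2)
  expect_equal(fx2$estimate[-1], fx1$estimate[-1], tolerance = 1e-4)
})

test_that("fits serialize to a readable CSV/JSON bundle", {
  scen <- small_scenario(seed = 18, years = 1)
  fit <- fit_star(scen$panel, "all", star_spec(time_knots = 7, temp_knots = 7))
  d <- withr::local_tempdir()
  write_fit(fit, d)
  co <- read.csv(file.path(d, "coefficients.csv"))
  expect_equal(nrow(co), length(fit$coefficients))
  js <- jsonlite::read_json(file.path(d, "fit_summary.json"))
  expect_equal(js$phi, fit$phi, tolerance = 1e-12)
  expect_equal(js$n, length(fit$y))
})
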