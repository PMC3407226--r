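#' Model specification for the structured additive regression fit
#'
#' Collects the tuning knobs of [fit_star()]: basis sizes for the time
#' and temperature smoothers, the inverse-gamma hyperprior on each
#' smoothing variance, convergence tolerances and iteration caps, and the
#' treatment of the overdispersion parameter.
#'
#' @param time_knots interior knots of the calendar-time smoother;
#'   `"auto"` (default) uses about 8 knots per year of study window
#'   (floor 7), enough to resolve annual respiratory seasonality
#' @param temp_knots interior knots of the temperature smoother
#' @param spline_degree B-spline degree for both smoothers
#' @param hyper_a,hyper_b inverse-gamma hyperprior shape and scale for
#'   every smoothing variance tau^2 (default IG(0.001, 0.001))
#' @param prior `"ig"` applies the hyperprior in the tau^2 update (its
#'   posterior-mode shift), `"flat"` drops it
#' @param tol relative-change convergence tolerance (coefficients and
#'   variance components)
#' @param inner_cap,outer_cap iteration caps for the penalized IWLS inner
#'   loop and the variance-update outer loop
#' @param tau2_floor lower floor for each tau^2 (warning when hit)
#' @param tau2_init initial value for each tau^2
#' @param phi `"estimate"` uses the Pearson estimator; a positive number
#'   fixes the overdispersion at that value
#' @param tau2_fixed optional named vector fixing the smoothing variance
#'   of some or all smooth terms (e.g. `c(time = 0.1)`); fixed terms skip
#'   the REML update
#' @param constraint `"unweighted"` (default) centers each smooth by its
#'   plain column sums; `"weighted"` re-centers with the working weights
#'   at each outer iteration
#' @param offset_population `"group"` (default) offsets by the modeled
#'   age band's own population, `"all"` by the total district population
#' @return a list of class `star_spec`
#' @export
star_spec <- function(time_knots = "auto", temp_knots = 10, spline_degree = 3,
                      hyper_a = 0.001, hyper_b = 0.001,
                      prior = c("ig", "flat"),
                      tol = 1e-6, inner_cap = 50, outer_cap = 200,
                      tau2_floor = 1e-8, tau2_init = 0.1,
                      phi = "estimate",
                      tau2_fixed = NULL,
                      constraint = c("unweighted", "weighted"),
                      offset_population = c("group", "all")) {
  structure(list(time_knots = time_knots, temp_knots = temp_knots,
                 spline_degree = spline_degree,
                 hyper_a = hyper_a, hyper_b = hyper_b,
                 prior = match.arg(prior),
                 tol = tol, inner_cap = inner_cap, outer_cap = outer_cap,
                 tau2_floor = tau2_floor, tau2_init = tau2_init,
                 phi = phi, tau2_fixed = tau2_fixed,
                 constraint = match.arg(constraint),
                 offset_population = match.arg(offset_population)),
            class = "star_spec")
}

# Assemble fixed blocks + constrained smooth blocks for one age group.
# Returns the pieces fit_star() and its oracles work from.
build_model_terms <- function(panel, age_group, spec) {
  dg <- build_design(panel, age_group)
  n <- length(dg$y)

  use_all_pop <- identical(spec$offset_population, "all") &&
    "all" %in% panel$populations$age_group
  offset <- if (use_all_pop) {
    pops <- panel$populations[panel$populations$age_group == "all", ]
    log(pops$population[match(dg$records$district, pops$district)])
  } else dg$offset

  fixed <- cbind(`(Intercept)` = rep(1, n), dg$dow, dg$dsli)

  time_knots <- spec$time_knots
  if (identical(time_knots, "auto")) {
    n_days <- diff(range(dg$time_index)) + 1
    time_knots <- max(7, round(8 * n_days / 365.25))
  }
  smooths <- list()
  bt <- bspline_basis(dg$time_index, time_knots, spec$spline_degree)
  pt <- rw2_penalty(ncol(bt$X))
  smooths$time <- apply_constraint(bt$X, pt$K, null_dim = pt$null_dim)
  smooths$time$basis <- bt

  bte <- bspline_basis(dg$temperature, spec$temp_knots, spec$spline_degree)
  pte <- rw2_penalty(ncol(bte$X))
  smooths$temperature <- apply_constraint(bte$X, pte$K, null_dim = pte$null_dim)
  smooths$temperature$basis <- bte

  if (length(panel$districts) > 1L) {
    mp <- mrf_penalty(panel$graph)
    A <- matrix(0, n, length(mp$districts),
                dimnames = list(NULL, mp$districts))
    A[cbind(seq_len(n), match(dg$records$district, mp$districts))] <- 1
    smooths$spatial <- apply_constraint(A, mp$K, null_dim = mp$null_dim)
    smooths$spatial$districts <- mp$districts
    smooths$spatial$incidence <- A
  }

  list(y = dg$y, offset = offset, fixed = fixed, smooths = smooths,
       records = dg$records, design = dg)
}

# Stack fixed + smooth blocks into one design matrix with block bookkeeping.
stack_blocks <- function(fixed, smooths) {
  X <- fixed
  idx <- list(fixed = seq_len(ncol(fixed)))
  Ks <- list()
  for (nm in names(smooths)) {
    s <- smooths[[nm]]
    idx[[nm]] <- ncol(X) + seq_len(ncol(s$X))
    colnames(s$X) <- paste0(nm, seq_len(ncol(s$X)))
    X <- cbind(X, s$X)
    Ks[[nm]] <- s$K
  }
  list(X = X, idx = idx, Ks = Ks)
}

# Block-diagonal total penalty S = sum_j lambda_j K_j on the stacked design.
total_penalty <- function(stk, lambda) {
  p <- ncol(stk$X)
  S <- matrix(0, p, p)
  for (nm in names(stk$Ks)) {
    j <- stk$idx[[nm]]
    S[j, j] <- S[j, j] + lambda[[nm]] * stk$Ks[[nm]]
  }
  S
}

# family plumbing for the working model: poisson log link (the model) or
# gaussian identity (used by variance-update oracles and tests)
fam_mu <- function(family, eta) if (family == "poisson") exp(eta) else eta
fam_weights <- function(family, mu) if (family == "poisson") mu else rep(1, length(mu))
fam_dev <- function(family, y, mu) {
  if (family == "poisson") {
    ll <- ifelse(y > 0, y * log(y / mu), 0) - (y - mu)
    2 * sum(ll)
  } else sum((y - mu)^2)
}

# One penalized IWLS run at fixed penalty weights lambda.
# Minimizes deviance(beta) + sum_j lambda_j b_j' K_j b_j.
piwls <- function(y, X, offset, S, beta, family = "poisson",
                  tol = 1e-8, cap = 50) {
  pen_obj <- function(beta) {
    mu <- fam_mu(family, drop(X %*% beta) + offset)
    fam_dev(family, y, mu) + drop(crossprod(beta, S %*% beta))
  }
  obj <- pen_obj(beta)
  trace <- obj
  for (it in seq_len(cap)) {
    eta <- drop(X %*% beta) + offset
    mu <- fam_mu(family, eta)
    w <- fam_weights(family, mu)
    z <- (eta - offset) + (y - mu) / w
    A <- crossprod(X * sqrt(w)) + S
    b <- drop(crossprod(X, w * z))
    beta_new <- drop(solve(A, b))
    # step halving on the penalized deviance
    step <- 1
    repeat {
      cand <- beta + step * (beta_new - beta)
      obj_new <- pen_obj(cand)
      if (is.finite(obj_new) && obj_new <= obj + 1e-10) break
      step <- step / 2
      if (step < 1e-8) { cand <- beta; obj_new <- obj; break }
    }
    rel <- max(abs(cand - beta)) / max(1, max(abs(beta)))
    beta <- cand
    trace <- c(trace, obj_new)
    converged <- rel < tol || abs(obj - obj_new) < tol * (abs(obj) + tol)
    obj <- obj_new
    if (converged) break
  }
  list(beta = beta, trace = trace, iterations = it, converged = converged)
}

#' Fit the overdispersed Poisson structured additive regression model
#'
#' Fits daily counts `y ~ Poisson-type(mu)`, `Var = phi * mu`, with
#' `log mu = offset + b0 + DOW gamma + DSLI delta + f_time + f_temp +
#' f_spatial`, by alternating (a) penalized iteratively reweighted least
#' squares for the coefficients at fixed smoothing weights
#' `lambda_j = phi / tau_j^2`, and (b) empirical-Bayes REML fixed-point
#' updates of each smoothing variance
#' `tau_j^2 <- (b_j' K_j b_j + 2 b) / (edf_j - null_j + 2 (a + 1))`
#' (the IG(a, b) hyperprior's posterior-mode shift; `prior = "flat"`
#' drops the `a`, `b` terms), with the overdispersion `phi` estimated by
#' the Pearson statistic over `n -` total effective degrees of freedom.
#'
#' @param panel a `panel_dataset`
#' @param age_group which age group's counts to fit
#' @param spec a [star_spec()]
#' @return an object of class `star_fit`: coefficients, covariance
#'   (scaled by `phi`), per-term effective degrees of freedom, variance
#'   components, overdispersion, fitted means, iteration trace, and the
#'   term bookkeeping needed by the reporting functions.
#' @export
fit_star <- function(panel, age_group = "all", spec = star_spec()) {
  terms <- build_model_terms(panel, age_group, spec)
  y <- terms$y
  if (all(y == 0)) stop("all counts are zero: nothing to fit")
  fit <- fit_star_engine(y, terms$offset, terms$fixed, terms$smooths, spec)
  if (identical(spec$constraint, "weighted")) {
    # re-center each smooth with the converged working weights and refit;
    # the fitted-value space is unchanged, only the intercept/smooth split
    for (pass in 1:2) {
      w <- fit$fitted
      sm <- terms$smooths
      sm$time <- reconstrain(sm$time, w)
      sm$temperature <- reconstrain(sm$temperature, w)
      if (!is.null(sm$spatial)) sm$spatial <- reconstrain(sm$spatial, w)
      terms$smooths <- sm
      fit <- fit_star_engine(y, terms$offset, terms$fixed, terms$smooths, spec)
    }
  }
  fit$age_group <- age_group
  fit$terms <- terms
  fit$districts <- terms$smooths$spatial$districts
  class(fit) <- "star_fit"
  fit
}

# Core fitting loop on prepared blocks; family is poisson for the model,
# gaussian for the working-model oracles used in tests.
fit_star_engine <- function(y, offset, fixed, smooths, spec = star_spec(),
                            family = "poisson") {
  stk <- stack_blocks(fixed, smooths)
  X <- stk$X
  n <- nrow(X); p <- ncol(X)
  smooth_names <- names(stk$Ks)

  tau2 <- stats::setNames(rep(spec$tau2_init, length(smooth_names)), smooth_names)
  fixed_tau <- intersect(names(spec$tau2_fixed), smooth_names)
  tau2[fixed_tau] <- spec$tau2_fixed[fixed_tau]
  phi_fixed <- is.numeric(spec$phi)
  phi <- if (phi_fixed) spec$phi else 1

  beta <- numeric(p)
  if (family == "poisson")
    beta[1] <- log(sum(y) / sum(exp(offset)))   # intercept closed form
  else beta[1] <- mean(y - offset)

  null_dim <- vapply(smooths, function(s) as.numeric(s$null_dim), 0)
  a <- spec$hyper_a; b <- spec$hyper_b
  use_prior <- identical(spec$prior, "ig")

  outer_trace <- numeric(0)
  floored <- character(0)
  for (outer in seq_len(spec$outer_cap)) {
    lambda <- as.list(phi / tau2)
    S <- total_penalty(stk, lambda)
    inner <- piwls(y, X, offset, S, beta, family = family,
                   tol = spec$tol, cap = spec$inner_cap)
    beta_new <- inner$beta
    outer_trace <- c(outer_trace, inner$trace[length(inner$trace)])

    eta <- drop(X %*% beta_new) + offset
    mu <- fam_mu(family, eta)
    w <- fam_weights(family, mu)
    XtWX <- crossprod(X * sqrt(w))
    Ainv_S <- solve(XtWX + S, S)
    edf_col <- 1 - diag(Ainv_S)               # per-column effective df
    edf <- vapply(smooth_names, function(nm) sum(edf_col[stk$idx[[nm]]]), 0)
    edf_total <- sum(edf_col)

    pearson <- sum((y - mu)^2 / w)
    if (!phi_fixed) phi <- max(pearson / (n - edf_total), 1e-6)

    tau2_new <- tau2
    for (nm in setdiff(smooth_names, fixed_tau)) {
      j <- stk$idx[[nm]]
      quad <- drop(crossprod(beta_new[j], stk$Ks[[nm]] %*% beta_new[j]))
      num <- quad + if (use_prior) 2 * b else 0
      den <- (edf[nm] - null_dim[nm]) + if (use_prior) 2 * (a + 1) else 0
      t2 <- if (den > 0) num / den else tau2[nm]
      if (!is.finite(t2) || t2 < spec$tau2_floor) {
        t2 <- spec$tau2_floor
        floored <- union(floored, nm)
      }
      tau2_new[nm] <- t2
    }

    rel_beta <- max(abs(beta_new - beta)) / max(1, max(abs(beta)))
    rel_tau <- if (length(tau2)) max(abs(tau2_new - tau2) / pmax(tau2, spec$tau2_floor)) else 0
    beta <- beta_new
    tau2 <- tau2_new
    if (rel_beta < spec$tol && rel_tau < spec$tol) break
  }
  if (outer == spec$outer_cap && (rel_beta >= spec$tol || rel_tau >= spec$tol))
    stop(structure(class = c("star_fit_nonconvergence", "error", "condition"),
                   list(message = sprintf(
                     "no convergence in %d outer iterations (last rel. changes: beta %.2e, tau2 %.2e)",
                     spec$outer_cap, rel_beta, rel_tau),
                     call = NULL, trace = outer_trace)))
  if (length(floored))
    warning("tau^2 floored at ", spec$tau2_floor, " for: ",
            paste(floored, collapse = ", "))

  # final state at converged beta / tau2 / phi
  lambda <- as.list(phi / tau2)
  S <- total_penalty(stk, lambda)
  eta <- drop(X %*% beta) + offset
  mu <- fam_mu(family, eta)
  w <- fam_weights(family, mu)
  XtWX <- crossprod(X * sqrt(w))
  Ainv <- solve(XtWX + S)
  edf_col <- 1 - diag(Ainv %*% S)
  edf <- vapply(names(stk$idx), function(nm) sum(edf_col[stk$idx[[nm]]]), 0)
  covariance <- phi * Ainv
  covariance <- (covariance + t(covariance)) / 2

  list(coefficients = stats::setNames(drop(beta), colnames(X)),
       covariance = covariance,
       tau2 = tau2,
       phi = phi,
       edf = edf,
       edf_total = sum(edf_col),
       fitted = mu,
       linear_predictor = eta,
       deviance = fam_dev(family, y, mu),
       pearson = sum((y - mu)^2 / w),
       trace = outer_trace,
       outer_iterations = outer,
       stack = stk,
       smooths = smooths,
       offset = offset,
       y = y,
       spec = spec,
       family = family,
       prior_used = if (use_prior) sprintf("IG(%g, %g) posterior-mode update", a, b)
                    else "flat (plain REML fixed point)")
}

#' @export
print.star_fit <- function(x, ...) {
  cat("Structured additive regression fit (", x$family, " working model)\n", sep = "")
  if (!is.null(x$age_group)) cat("Age group:", x$age_group, "\n")
  cat("n =", length(x$y), " total edf =", round(x$edf_total, 2),
      " phi =", signif(x$phi, 4), "\n")
  cat("tau^2:", paste(sprintf("%s = %.4g", names(x$tau2), x$tau2), collapse = ", "), "\n")
  cat("Outer iterations:", x$outer_iterations,
      " penalized deviance:", signif(x$trace[length(x$trace)], 6), "\n")
  invisible(x)
}

#' Penalized deviance of a fit
#'
#' `-2 log Poisson likelihood (deviance form) + sum_j (phi / tau_j^2)
#' b_j' K_j b_j`, the objective decreased by the inner penalized IWLS
#' loop at the fit's final variance components.
#'
#' @param fit a `star_fit`
#' @return numeric scalar
#' @export
penalized_deviance <- function(fit) {
  pen <- 0
  for (nm in names(fit$stack$Ks)) {
    j <- fit$stack$idx[[nm]]
    bj <- fit$coefficients[j]
    pen <- pen + (fit$phi / fit$tau2[[nm]]) * drop(crossprod(bj, fit$stack$Ks[[nm]] %*% bj))
  }
  unname(fit$deviance + pen)
}

#' Per-term effective degrees of freedom
#'
#' Trace of each term's block of the influence (hat) operator
#' `(X'WX + S)^{-1} X'WX` at the converged fit.  Unpenalized fixed
#' blocks count their full column dimension.
#'
#' @param fit a `star_fit`
#' @return named numeric vector (one entry per term, incl. `fixed`)
#' @export
effective_dof <- function(fit) {
  fit$edf
}

#' Extract fixed-effect estimates with Wald inference
#'
#' @param fit a `star_fit`
#' @return data frame `term, estimate, se, z, p` for the intercept, DOW
#'   and DSLI coefficients
#' @export
fixed_effects <- function(fit) {
  j <- fit$stack$idx$fixed
  est <- fit$coefficients[j]
  se <- sqrt(diag(fit$covariance)[j])
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
             row.names = NULL)
}

#' District-level spatial effects of a fit
#'
#' Maps the constrained spatial coefficients back to one effect per
#' district (log relative-rate scale, sum-to-zero) with its marginal
#' posterior standard deviation.
#'
#' @param fit a `star_fit`
#' @return data frame `district, effect, se`
#' @export
spatial_effects <- function(fit) {
  s <- fit$smooths$spatial
  if (is.null(s)) stop("fit has no spatial term (single-district panel)")
  j <- fit$stack$idx$spatial
  theta <- drop(s$Z %*% fit$coefficients[j])
  V <- s$Z %*% fit$covariance[j, j, drop = FALSE] %*% t(s$Z)
  data.frame(district = s$districts, effect = unname(theta),
             se = sqrt(pmax(diag(V), 0)), row.names = NULL)
}

#' Evaluate a fitted smooth term
#'
#' @param fit a `star_fit`
#' @param term `"time"` or `"temperature"`
#' @param at covariate values to evaluate at (defaults to the training values)
#' @return data frame `x, fit, se`
#' @export
smooth_estimate <- function(fit, term = c("time", "temperature"), at = NULL) {
  term <- match.arg(term)
  s <- fit$smooths[[term]]
  j <- fit$stack$idx[[term]]
  if (is.null(at)) {
    Xb <- s$X
    xv <- if (term == "time") fit$terms$design$time_index else fit$terms$design$temperature
  } else {
    B <- splines::splineDesign(s$basis$knots, at, ord = s$basis$degree + 1)
    Xb <- B %*% s$Z
    xv <- at
  }
  est <- drop(Xb %*% fit$coefficients[j])
  V <- Xb %*% fit$covariance[j, j, drop = FALSE] %*% t(Xb)
  data.frame(x = xv, fit = est, se = sqrt(pmax(diag(V), 0)))
}

#' Serialize a fit to a CSV/JSON bundle
#'
#' Writes `coefficients.csv` (all coefficients with SEs),
#' `fixed_effects.csv`, `spatial_effects.csv` and `fit_summary.json`
#' (variance components, overdispersion, edf, convergence trace) into a
#' directory.
#'
#' @param fit a `star_fit`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- data.frame(term = names(fit$coefficients),
                   estimate = unname(fit$coefficients),
                   se = sqrt(diag(fit$covariance)))
  utils::write.csv(co, file.path(dir, "coefficients.csv"), row.names = FALSE)
  utils::write.csv(fixed_effects(fit), file.path(dir, "fixed_effects.csv"),
                   row.names = FALSE)
  utils::write.csv(spatial_effects(fit), file.path(dir, "spatial_effects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(age_group = fit$age_group,
         n = length(fit$y),
         tau2 = as.list(fit$tau2),
         phi = fit$phi,
         edf = as.list(fit$edf),
         edf_total = fit$edf_total,
         deviance = fit$deviance,
         penalized_deviance = penalized_deviance(fit),
         outer_iterations = fit$outer_iterations,
         trace = fit$trace,
         prior = fit$prior_used),
    file.path(dir, "fit_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
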