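# Independent oracles used to validate the package's implementations.
# None of these share code with the functions they check.

# O(days x events) brute-force lag classifier: for every study day,
# scan all events; membership wins, else the smallest 1..7 day distance
# past any event end, else reference.
brute_force_lags <- function(cal) {
  dates <- seq(cal$study_start, cal$study_end, by = "day")
  ev <- cal$events
  sapply(seq_along(dates), function(i) {
    d <- dates[i]
    best <- Inf
    for (j in seq_len(nrow(ev))) {
      if (d >= ev$start[j] && d <= ev$end[j]) return("lag0")
      k <- as.integer(d - ev$end[j])
      if (k >= 1 && k <= 7) best <- min(best, k)
    }
    if (is.finite(best)) paste0("lag", best) else "reference"
  })
}

# Textbook Cox-de Boor recursion for a single B-spline basis function.
deboor_B <- function(x, knots, i, k) {
  if (k == 0)
    return(as.numeric(x >= knots[i] & x < knots[i + 1]))
  w1 <- if (knots[i + k] > knots[i])
    (x - knots[i]) / (knots[i + k] - knots[i]) else 0
  w2 <- if (knots[i + k + 1] > knots[i + 1])
    (knots[i + k + 1] - x) / (knots[i + k + 1] - knots[i + 1]) else 0
  w1 * deboor_B(x, knots, i, k - 1) + w2 * deboor_B(x, knots, i + 1, k - 1)
}

deboor_basis <- function(x, knots, degree) {
  p <- length(knots) - degree - 1
  sapply(seq_len(p), function(i) deboor_B(x, knots, i, degree))
}

# Dense full-Newton minimizer of -2 * Poisson loglik + beta' S beta,
# written directly from the formulas (no IWLS).
newton_penalized_poisson <- function(y, X, offset, S, init,
                                     tol = 1e-12, cap = 200) {
  obj <- function(b) {
    eta <- offset + drop(X %*% b)
    -2 * sum(y * eta - exp(eta)) + drop(t(b) %*% S %*% b)
  }
  beta <- init
  for (it in seq_len(cap)) {
    eta <- offset + drop(X %*% beta)
    mu <- exp(eta)
    g <- -2 * drop(crossprod(X, y - mu)) + 2 * drop(S %*% beta)
    H <- 2 * crossprod(X * sqrt(mu)) + 2 * S
    d <- solve(H, g)
    f0 <- obj(beta)
    st <- 1
    while (obj(beta - st * d) > f0 - 1e-12 && st > 1e-10) st <- st / 2
    beta <- beta - st * d
    if (max(abs(st * d)) < tol) break
  }
  beta
}

# Exact restricted log-likelihood of the Gaussian working model
# y = X beta + e, e ~ N(0, sigma2 I), penalized block jp with prior
# precision K / tau2; constants independent of tau2 dropped.
gaussian_reml <- function(y, X, K, jp, sigma2, tau2) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  rankK <- sum(ev > 1e-9 * max(ev))
  ldetK <- sum(log(ev[seq_len(rankK)]))
  P <- matrix(0, ncol(X), ncol(X))
  P[jp, jp] <- K / tau2
  A <- crossprod(X) / sigma2 + P
  beta <- solve(A, crossprod(X, y) / sigma2)
  rss <- sum((y - X %*% beta)^2)
  quad <- drop(t(beta[jp]) %*% K %*% beta[jp])
  -rss / (2 * sigma2) - quad / (2 * tau2) -
    0.5 * as.numeric(determinant(A)$modulus) +
    0.5 * (ldetK - rankK * log(tau2))
}
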