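#' Penalized smoother building blocks
#'
#' The model's smooth terms combine a design block with a quadratic
#' penalty: cubic B-splines on equidistant knots with a second-order
#' random-walk (second-difference) penalty for calendar time and
#' temperature, and a district incidence block with the graph-Laplacian
#' penalty of the conditional autoregressive (CAR) spatial prior.
#'
#' @name smoothers
#' @keywords internal
NULL

#' Evaluate a B-spline basis on equidistant knots
#'
#' Knots are placed equidistantly over the covariate range and extended
#' `degree` knots beyond each boundary, so that the basis functions form a
#' partition of unity everywhere on `[min(values), max(values)]` and the
#' second-order random-walk prior on the coefficients has its usual
#' P-spline meaning.  Basis dimension is `n_interior_knots + degree + 1`.
#'
#' @param values covariate vector to evaluate at
#' @param n_interior_knots number of interior knots (default 20)
#' @param degree spline degree (default 3, cubic)
#' @param range optional length-2 numeric giving the basis support;
#'   defaults to `range(values)`.  Values outside it are an error.
#' @return list with the design matrix `X` (rows = values), the full
#'   `knots` vector, `degree`, and `range`.
#' @export
bspline_basis <- function(values, n_interior_knots = 20, degree = 3,
                          range = NULL) {
  if (is.null(range)) range <- base::range(values)
  lo <- range[1]; hi <- range[2]
  if (!(hi > lo)) stop("covariate is constant: cannot build a spline basis")
  if (n_interior_knots < degree)
    stop("need at least `degree` interior knots")
  if (any(values < lo | values > hi))
    stop("values outside the basis range")
  h <- (hi - lo) / (n_interior_knots + 1)
  knots <- lo + h * seq(-degree, n_interior_knots + 1 + degree)
  knots[degree + n_interior_knots + 2] <- hi   # exact right boundary
  X <- splines::splineDesign(knots, values, ord = degree + 1, outer.ok = FALSE)
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  list(X = X, knots = knots, degree = degree, range = c(lo, hi))
}

#' Second-order random-walk penalty matrix
#'
#' `K = t(D) %*% D` with `D` the (n-2) x n second-difference operator;
#' the null space is spanned by constant and linear coefficient
#' sequences, matching a second-order random-walk prior.
#'
#' @param n_coef number of basis coefficients (>= 3)
#' @return list `K` (penalty matrix), `null_dim = 2`
#' @export
rw2_penalty <- function(n_coef) {
  if (n_coef < 3) stop("second-order random walk needs at least 3 coefficients")
  D <- diff(diag(n_coef), differences = 2)
  list(K = crossprod(D), null_dim = 2L)
}

#' Markov-random-field (CAR) penalty matrix from an adjacency graph
#'
#' The graph Laplacian: diagonal entries are neighbour counts,
#' off-diagonals are -1 for adjacent districts.  This is the precision
#' structure of the intrinsic CAR prior in which each district's effect
#' is conditionally normal around the mean of its neighbours with
#' variance `tau^2 / n_s`.
#'
#' @param graph an igraph object or a two-column edge-list data frame
#' @return list `K` (Laplacian, districts in sorted name order),
#'   `null_dim` (= number of connected components), `districts`
#' @export
mrf_penalty <- function(graph) {
  if (!inherits(graph, "igraph"))
    graph <- igraph::graph_from_data_frame(graph, directed = FALSE)
  if (any(igraph::which_loop(graph))) stop("self-loops are not allowed")
  if (igraph::any_multiple(graph)) stop("duplicate edges are not allowed")
  ord <- order(igraph::V(graph)$name)
  K <- as.matrix(igraph::laplacian_matrix(graph))
  K <- K[ord, ord, drop = FALSE]
  list(K = K,
       null_dim = igraph::count_components(graph),
       districts = igraph::V(graph)$name[ord])
}

#' Absorb a sum-to-zero constraint into a smooth term
#'
#' Removes the component of the smooth confounded with the intercept by
#' reparameterizing the design so that the fitted contribution has
#' (optionally weighted) zero sum over the sample: with `C = t(X) %*% w`,
#' coefficients are restricted to the null space `Z` of `t(C)` and the
#' penalty becomes `t(Z) %*% K %*% Z`.  For a random-walk penalty this
#' leaves the linear trend inside the block as its remaining (unpenalized)
#' null-space direction; for the MRF only the constant is removed and the
#' constrained penalty has full rank.
#'
#' @param X design block of the smooth (n x p)
#' @param K penalty matrix (p x p)
#' @param weights observation weights for the constraint (default 1)
#' @param null_dim null-space dimension of `K`
#' @return list (class `constrained_smooth`): `X` (n x (p-1)), `K`
#'   ((p-1) x (p-1)), `Z` (p x (p-1) transform), `null_dim` (of the
#'   constrained penalty)
#' @export
apply_constraint <- function(X, K, weights = rep(1, nrow(X)), null_dim = NULL) {
  if (ncol(X) != nrow(K)) stop("design block and penalty are not conformable")
  C <- drop(crossprod(X, weights))          # 1 x p constraint
  if (sqrt(sum(C^2)) < 1e-10 * sqrt(sum(weights^2)) * max(abs(X))) {
    # constraint already satisfied (e.g. re-applied): keep the block as is
    nd <- penalty_null_dim(K)
    return(structure(list(X = X, K = K, Z = diag(ncol(X)), null_dim = nd,
                          X_raw = X, K_raw = K, null_dim_raw = nd),
                     class = "constrained_smooth"))
  }
  qrC <- qr(matrix(C, ncol = 1))
  Z <- qr.Q(qrC, complete = TRUE)[, -1, drop = FALSE]
  if (is.null(null_dim)) null_dim <- penalty_null_dim(K)
  structure(list(X = X %*% Z,
                 K = crossprod(Z, K %*% Z),
                 Z = Z,
                 null_dim = max(0L, null_dim - 1L),
                 X_raw = X, K_raw = K, null_dim_raw = null_dim),
            class = "constrained_smooth")
}

# Re-absorb the constraint of a constrained_smooth with new weights,
# keeping any extra fields (basis, districts, ...) attached to it.
reconstrain <- function(s, weights) {
  s2 <- apply_constraint(s$X_raw, s$K_raw, weights = weights,
                         null_dim = s$null_dim_raw)
  extra <- setdiff(names(s), names(s2))
  s2[extra] <- s[extra]
  s2
}

# Null-space dimension of a PSD penalty by relative eigenvalue threshold.
penalty_null_dim <- function(K, tol = 1e-9) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  sum(ev < tol * max(ev, 1))
}
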