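#' Soft-thresholding operator
#'
#' Elementwise \code{sign(a) * max(|a| - delta, 0)}, the proximal operator
#' of the L1 norm and the basic primitive of the penalized matrix
#' decomposition.
#'
#' @param a Numeric vector.
#' @param delta Nonnegative threshold.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' soft_threshold(c(3, -0.5, 0), 1)
soft_threshold <- function(a, delta) {
  if (delta < 0) stop("delta must be nonnegative")
  sign(a) * pmax(abs(a) - delta, 0)
}

#' L1-constrained unit-norm maximizer
#'
#' Solves \eqn{\max_w w^T a} subject to \eqn{\|w\|_2 \le 1} and
#' \eqn{\|w\|_1 \le c}: the sCCA subproblem.  The solution is
#' \code{soft_threshold(a, delta)} rescaled to unit L2 norm, with
#' \code{delta = 0} when the unconstrained unit vector already meets the L1
#' budget, and otherwise found by bisection so that the L1 norm equals
#' \code{c} to within \code{tol}.  At the maximal-sparsity limit
#' (\code{c = 1}) a single coordinate carries all mass; exact ties in
#' \code{|a|} are broken deterministically in favor of the lowest index.
#'
#' @param a Nonzero numeric vector.
#' @param c L1 budget, clamped into \code{[1, sqrt(length(a))]}.
#' @param tol Bisection tolerance on the L1 norm.
#' @return Unit-L2 weight vector with \code{sum(abs(w)) <= c + tol}.
#' @export
#' @examples
#' l1_constrained_unit(c(3, 4), 2)   # unconstrained: (0.6, 0.8)
#' l1_constrained_unit(c(3, 4), 1)   # maximal sparsity: (0, 1)
l1_constrained_unit <- function(a, c, tol = 1e-8) {
  if (all(a == 0) || !all(is.finite(a)))
    stop("undefined direction: input vector is all-zero or non-finite")
  n <- length(a)
  c <- max(1, min(c, sqrt(n)))
  w <- a / sqrt(sum(a^2))
  if (sum(abs(w)) <= c + tol) return(w)
  if (c <= 1 + tol) return(top_coordinate(a))
  lo <- 0; hi <- max(abs(a))
  for (iter in 1:500) {
    mid <- (lo + hi) / 2
    s <- soft_threshold(a, mid)
    ns <- sqrt(sum(s^2))
    l1 <- if (ns == 0) 0 else sum(abs(s)) / ns
    if (l1 > c) lo <- mid else hi <- mid
    if (hi - lo < 1e-15 * max(1, max(abs(a)))) break
  }
  # the hi endpoint always satisfies the budget (invariant of the search);
  # if it degenerates to the all-zero vector the top |a| entries are exactly
  # tied and a single coordinate is returned deterministically
  s <- soft_threshold(a, hi)
  ns <- sqrt(sum(s^2))
  if (ns == 0) return(top_coordinate(a))
  s / ns
}

# single active coordinate: largest |a|, lowest index on ties
top_coordinate <- function(a) {
  k <- which.max(abs(a))  # which.max returns the first maximum
  w <- numeric(length(a))
  w[k] <- sign(a[k])
  w
}

# map a penalty t in (0, 1] to the L1 budget t * sqrt(dim), clamped to the
# feasible range [1, sqrt(dim)] (unit L2 norm forces L1 >= 1)
l1_budget <- function(t, dim) {
  if (t <= 0 || t > 1) stop("penalty parameters must lie in (0, 1]")
  max(1, min(t * sqrt(dim), sqrt(dim)))
}

#' Sparse canonical correlation fit (single variate pair)
#'
#' From-scratch penalized matrix decomposition: with \eqn{M = X^T Z},
#' alternate \code{u <- l1_constrained_unit(M v, t_x sqrt(p))} and
#' \code{v <- l1_constrained_unit(M^T u, t_z sqrt(q))} until the largest
#' weight change falls below \code{tol}.  Initialization is the leading
#' right singular vector of \eqn{M} obtained by deterministic power
#' iteration, so fits are reproducible without random restarts.  Only the
#' first canonical pair is computed (no deflation).
#'
#' The returned pair is jointly sign-aligned so that \code{sum(u) <= 0}
#' (risk orientation: a higher genetic composite accompanies worse clinical
#' scores); the joint flip leaves the canonical correlation unchanged.
#'
#' @param X Subjects x p clinical matrix.
#' @param Z Subjects x q genetic matrix (same rows).
#' @param penalty_x,penalty_z L1 penalties in (0, 1]; smaller is sparser.
#' @param max_iter Maximum alternations.
#' @param tol Convergence tolerance on weight changes.
#' @param standardize Column-standardize both matrices before fitting
#'   (sample-SD convention).  Set \code{FALSE} only if inputs are already
#'   standardized.
#' @return Object of class \code{scca_fit}: weight vectors \code{u}
#'   (clinical) and \code{v} (genetic), canonical correlation \code{rho}
#'   (Pearson correlation of the two fitted composites), \code{iterations},
#'   \code{converged}, and the penalties.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(100), 50, 2); Z <- matrix(rnorm(100), 50, 2)
#' fit <- fit_scca(X, Z, 0.8, 0.8)
#' fit$rho
fit_scca <- function(X, Z, penalty_x, penalty_z,
                     max_iter = 100L, tol = 1e-6, standardize = TRUE) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (nrow(X) != nrow(Z)) stop("X and Z must have the same number of rows")
  if (standardize) {
    X <- scale_columns(X, strict = TRUE)
    Z <- scale_columns(Z, strict = TRUE)
  }
  cx <- l1_budget(penalty_x, ncol(X))
  cz <- l1_budget(penalty_z, ncol(Z))
  fit <- scca_core(X, Z, cx, cz, max_iter = max_iter, tol = tol)
  structure(c(fit, list(penalty_x = penalty_x, penalty_z = penalty_z)),
            class = "scca_fit")
}

# lean solver on pre-standardized matrices; cx/cz are L1 budgets
scca_core <- function(X, Z, cx, cz, max_iter = 100L, tol = 1e-6) {
  M <- crossprod(X, Z)
  if (all(M == 0)) stop("cross-covariance matrix is identically zero")
  v <- power_init(M)
  u <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    u <- l1_constrained_unit(as.vector(M %*% v), cx)
    v_new <- l1_constrained_unit(as.vector(crossprod(M, u)), cz)
    delta <- max(abs(v_new - v))
    v <- v_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # joint sign alignment: sum of clinical weights <= 0
  if (sum(u) > 0) { u <- -u; v <- -v }
  rho <- suppressWarnings(stats::cor(as.vector(X %*% u), as.vector(Z %*% v)))
  if (is.na(rho)) rho <- 0
  list(u = stats::setNames(u, colnames(X)),
       v = stats::setNames(v, colnames(Z)),
       rho = rho, iterations = it, converged = converged)
}

# leading right singular vector of M via power iteration, fixed start
power_init <- function(M, iter = 50L, tol = 1e-10) {
  q <- ncol(M)
  v <- rep(1 / sqrt(q), q)
  MtM <- crossprod(M)
  for (i in seq_len(iter)) {
    v2 <- as.vector(MtM %*% v)
    n2 <- sqrt(sum(v2^2))
    if (n2 == 0) return(v)  # degenerate; keep uniform start
    v2 <- v2 / n2
    if (max(abs(v2 - v)) < tol) { v <- v2; break }
    v <- v2
  }
  v
}

#' @export
print.scca_fit <- function(x, ...) {
  cat(sprintf(
    "sCCA fit: rho = %.4f, support |u| = %d/%d, |v| = %d/%d (t = %.2f/%.2f)%s\n",
    x$rho, sum(x$u != 0), length(x$u), sum(x$v != 0), length(x$v),
    x$penalty_x, x$penalty_z,
    if (x$converged) "" else "  [not converged]"))
  invisible(x)
}
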