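# Independent oracles used to pin expected values.  Each is deliberately
# naive (grid scans, O(n^2) rank counting) and shares no code with the
# implementation paths it checks.

# L1-constrained unit-norm subproblem by brute-force threshold scan:
# normalize soft(a, delta) over a dense delta grid and keep the feasible
# point with the largest inner product with a.
oracle_l1_unit <- function(a, c, n_grid = 1e6) {
  deltas <- seq(0, max(abs(a)), length.out = n_grid)
  best <- NULL; best_obj <- -Inf
  for (d in deltas) {
    s <- sign(a) * pmax(abs(a) - d, 0)
    ns <- sqrt(sum(s^2))
    if (ns == 0) next
    w <- s / ns
    if (sum(abs(w)) <= c + 1e-6) {
      obj <- sum(w * a)
      if (obj > best_obj) { best_obj <- obj; best <- w }
    }
  }
  best
}

# exhaustive sCCA oracle for p = q = 2: parameterize both unit weight
# vectors by angle, reject pairs violating the L1 budgets, maximize the
# penalized-matrix-decomposition objective u' X'Z v over the feasible grid,
# and report the empirical correlation of the composites at the argmax.
oracle_scca_2d <- function(X, Z, tx, tz, step_deg = 0.05) {
  cx <- max(1, min(tx * sqrt(2), sqrt(2)))
  cz <- max(1, min(tz * sqrt(2), sqrt(2)))
  ang <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  U <- rbind(cos(ang), sin(ang))
  feas_u <- colSums(abs(U)) <= cx + 1e-12
  feas_v <- colSums(abs(U)) <= cz + 1e-12
  Uf <- U[, feas_u, drop = FALSE]; Vf <- U[, feas_v, drop = FALSE]
  M <- crossprod(X, Z)
  obj <- crossprod(Uf, M %*% Vf)          # u' M v over the whole grid
  best <- arrayInd(which.max(obj), dim(obj))
  u <- Uf[, best[1]]; v <- Vf[, best[2]]
  stats::cor(as.vector(X %*% u), as.vector(Z %*% v))
}

# definitional tie-corrected Spearman: O(n^2) mid-ranks, then the Pearson
# product-moment formula applied to the ranks.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(seq_along(v), function(i)
      1 + sum(v < v[i]) + (sum(v == v[i]) - 1) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# per-subject ordinary least squares line (oracle for balanced noise-free
# mixed-model recovery)
oracle_ols_lines <- function(clinical, measure) {
  d <- clinical[clinical$measure == measure, ]
  do.call(rbind, lapply(split(d, d$subject_id), function(g) {
    fit <- stats::lm(value ~ visit_month, data = g)
    data.frame(subject_id = g$subject_id[1],
               intercept = unname(coef(fit)[1]),
               slope = unname(coef(fit)[2]))
  }))
}
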