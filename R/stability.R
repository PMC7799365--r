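#' Penalty grid search
#'
#' Fits the sparse CCA at every combination of L1 penalties on a 10 x 10
#' grid (default 0.1 to 1.0 in steps of 0.1 on each axis, 100 fits) and
#' selects the pair attaining the largest canonical correlation of the
#' first variate.  Ties within 1e-12 are broken toward sparsity: smallest
#' \code{penalty_x + penalty_z}, then smallest \code{penalty_x}.
#'
#' @param X,Z Clinical and genetic matrices (rows are subjects).
#' @param penalties Penalty values used on both axes.
#' @param ... Passed to \code{\link{fit_scca}}.
#' @return Object of class \code{scca_grid}: \code{cells} (data.frame with
#'   penalty_x, penalty_z, rho, converged for every cell), \code{surface}
#'   (rho matrix, rows penalty_x), and \code{best} (named vector).
#' @export
scca_grid_search <- function(X, Z, penalties = seq(0.1, 1, by = 0.1), ...) {
  grid <- expand.grid(penalty_x = penalties, penalty_z = penalties,
                      KEEP.OUT.ATTRS = FALSE)
  # sparsest-first enumeration so the tie-break is a plain argmax
  grid <- grid[order(grid$penalty_x + grid$penalty_z, grid$penalty_x), ]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    fit <- tryCatch(
      fit_scca(X, Z, grid$penalty_x[i], grid$penalty_z[i], ...),
      error = function(e) stop(sprintf(
        "grid cell (penalty_x = %.2f, penalty_z = %.2f) failed: %s",
        grid$penalty_x[i], grid$penalty_z[i], conditionMessage(e)),
        call. = FALSE))
    c(rho = fit$rho, converged = as.numeric(fit$converged))
  })
  res <- do.call(rbind, res)
  cells <- data.frame(grid, rho = res[, "rho"],
                      converged = res[, "converged"] == 1)
  rownames(cells) <- NULL
  best_i <- which(cells$rho > max(cells$rho) - 1e-12)[1]
  surface <- matrix(NA_real_, length(penalties), length(penalties),
                    dimnames = list(penalty_x = format(penalties),
                                    penalty_z = format(penalties)))
  surface[cbind(match(cells$penalty_x, penalties),
                match(cells$penalty_z, penalties))] <- cells$rho
  structure(list(cells = cells, surface = surface,
                 best = c(penalty_x = cells$penalty_x[best_i],
                          penalty_z = cells$penalty_z[best_i]),
                 best_rho = cells$rho[best_i]),
            class = "scca_grid")
}

#' @export
print.scca_grid <- function(x, ...) {
  cat(sprintf("sCCA penalty grid: %d cells; best rho = %.4f at (%.1f, %.1f)\n",
              nrow(x$cells), x$best_rho, x$best["penalty_x"],
              x$best["penalty_z"]))
  invisible(x)
}

# draw a subsample, restandardize within it, fit; columns constant within
# the subsample are zeroed (they carry no signal there).  permute = "rows"
# shuffles whole rows of each dataset (breaking the X-Z linkage while
# preserving within-dataset correlation); permute = "columns" shuffles every
# column independently (also flattening within-dataset structure).
subsample_fit <- function(X, Z, m, cx, cz, replace, permute = "none") {
  n <- nrow(X)
  idx <- sample.int(n, m, replace = replace)
  Xs <- scale_columns(X[idx, , drop = FALSE])
  Zs <- scale_columns(Z[idx, , drop = FALSE])
  if (permute == "rows") {
    Xs <- Xs[sample.int(m), , drop = FALSE]
    Zs <- Zs[sample.int(m), , drop = FALSE]
  } else if (permute == "columns") {
    for (j in seq_len(ncol(Xs))) Xs[, j] <- Xs[sample.int(m), j]
    for (j in seq_len(ncol(Zs))) Zs[, j] <- Zs[sample.int(m), j]
  }
  scca_core(Xs, Zs, cx, cz)
}

#' Bootstrap-stabilized sparse CCA
#'
#' Runs \code{B} sparse CCA fits, each on a random subsample of
#' \code{floor(frac * n)} distinct subjects (75\% by default, drawn without
#' replacement; set \code{replace = TRUE} for a classical with-replacement
#' bootstrap).  Columns are restandardized within every subsample and the
#' risk-orientation sign convention is applied to each fit, so medians
#' across iterations are well defined.
#'
#' @param X,Z Clinical and genetic matrices.
#' @param penalty_x,penalty_z L1 penalties (typically the grid-search
#'   optimum).
#' @param B Number of iterations (default 10000).
#' @param frac Subsample fraction (default 0.75).
#' @param seed Integer seed; same seed + inputs gives bit-identical output.
#' @param replace Draw subsamples with replacement instead.
#' @param max_fail_frac Abort if more than this fraction of iterations fail.
#' @param store_iterations Keep the per-iteration rho vector and weight
#'   matrices (needed for the permutation p-value and audit output).
#' @return Object of class \code{scca_bootstrap}: \code{median_rho},
#'   percentile \code{rho_ci}, per-genetic-feature \code{median_weight} and
#'   \code{selection_pct}, per-clinical-feature \code{clinical_selection_pct},
#'   and provenance fields.
#' @export
bootstrap_scca <- function(X, Z, penalty_x, penalty_z,
                           B = 10000L, frac = 0.75, seed = 1L,
                           replace = FALSE, max_fail_frac = 0.01,
                           store_iterations = TRUE) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  stopifnot(nrow(X) == nrow(Z))
  m <- floor(frac * nrow(X))
  if (m < 10) stop("subsample size below 10; increase frac or sample size")
  cx <- l1_budget(penalty_x, ncol(X))
  cz <- l1_budget(penalty_z, ncol(Z))
  local_seed(seed)
  rho <- rep(NA_real_, B)
  U <- matrix(NA_real_, ncol(X), B, dimnames = list(colnames(X), NULL))
  V <- matrix(NA_real_, ncol(Z), B, dimnames = list(colnames(Z), NULL))
  failures <- 0L
  for (b in seq_len(B)) {
    fit <- tryCatch(subsample_fit(X, Z, m, cx, cz, replace),
                    error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    rho[b] <- fit$rho; U[, b] <- fit$u; V[, b] <- fit$v
  }
  if (failures > max_fail_frac * B)
    stop(sprintf("%d of %d bootstrap iterations failed", failures, B))
  if (failures > 0)
    message(sprintf("bootstrap: skipped %d failed iteration(s)", failures))
  ok <- !is.na(rho)
  out <- list(
    median_rho = stats::median(rho[ok]),
    rho_ci = stats::quantile(rho[ok], c(0.025, 0.975), names = FALSE),
    median_weight = apply(V[, ok, drop = FALSE], 1, stats::median),
    selection_pct = 100 * rowMeans(V[, ok, drop = FALSE] != 0),
    clinical_selection_pct = 100 * rowMeans(U[, ok, drop = FALSE] != 0),
    B = B, n_failed = failures, frac = frac, replace = replace, seed = seed,
    penalty_x = penalty_x, penalty_z = penalty_z
  )
  if (store_iterations) {
    out$rho <- rho; out$U <- U; out$V <- V
  }
  structure(out, class = "scca_bootstrap")
}

#' @export
print.scca_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Bootstrapped sCCA (B = %d, %.0f%% subsamples): median rho = %.3f [%.3f, %.3f]\n",
    x$B, 100 * x$frac, x$median_rho, x$rho_ci[1], x$rho_ci[2]))
  top <- names(sort(x$clinical_selection_pct, decreasing = TRUE))[1]
  cat(sprintf("  most-selected clinical feature: %s (%.1f%%)\n",
              top, max(x$clinical_selection_pct)))
  invisible(x)
}

#' Permutation null model for the bootstrapped sparse CCA
#'
#' Repeats the bootstrap procedure with the linkage between the two
#' datasets destroyed: in every iteration, after subsampling and
#' restandardization, each dataset is permuted before fitting.  The
#' resulting null distribution of canonical correlations yields the
#' p-value of the observed bootstrap median: the probability under the
#' null of a canonical correlation at least as large.  Reported both as
#' \code{b/B} (primary) and as the never-zero variant \code{(b+1)/(B+1)}.
#'
#' Two permutation schemes are provided.  \code{"rows"} (default) applies
#' one independent whole-row permutation to each dataset, which breaks the
#' X-Z linkage while preserving each dataset's internal correlation
#' structure -- the appropriate null for testing the cross-dataset
#' association.  \code{"columns"} additionally shuffles every column
#' independently, flattening within-dataset structure as community-matrix
#' randomization routines do; under it all same-distribution features are
#' selected with equal probability, so null selection percentages spread
#' evenly across features.
#'
#' @inheritParams bootstrap_scca
#' @param permute \code{"rows"} or \code{"columns"} (see Details).
#' @param observed_rho Observed median canonical correlation (from
#'   \code{\link{bootstrap_scca}}); may be omitted and supplied later via
#'   \code{\link{null_p_value}}.
#' @return Object of class \code{scca_null}: \code{rho} (null distribution),
#'   per-feature null selection percentages, \code{p_value},
#'   \code{p_value_add_one}, and provenance.
#' @export
permutation_null <- function(X, Z, penalty_x, penalty_z,
                             B = 10000L, frac = 0.75, seed = 1L,
                             observed_rho = NULL, replace = FALSE,
                             permute = c("rows", "columns"),
                             max_fail_frac = 0.01) {
  permute <- match.arg(permute)
  X <- as.matrix(X); Z <- as.matrix(Z)
  stopifnot(nrow(X) == nrow(Z))
  m <- floor(frac * nrow(X))
  if (m < 10) stop("subsample size below 10; increase frac or sample size")
  cx <- l1_budget(penalty_x, ncol(X))
  cz <- l1_budget(penalty_z, ncol(Z))
  local_seed(seed)
  rho <- rep(NA_real_, B)
  selU <- matrix(NA, ncol(X), B, dimnames = list(colnames(X), NULL))
  selV <- matrix(NA, ncol(Z), B, dimnames = list(colnames(Z), NULL))
  failures <- 0L
  for (b in seq_len(B)) {
    fit <- tryCatch(subsample_fit(X, Z, m, cx, cz, replace,
                                  permute = permute),
                    error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    rho[b] <- fit$rho
    selU[, b] <- fit$u != 0
    selV[, b] <- fit$v != 0
  }
  if (failures > max_fail_frac * B)
    stop(sprintf("%d of %d null iterations failed", failures, B))
  ok <- !is.na(rho)
  out <- structure(list(
    rho = rho,
    clinical_selection_pct = 100 * rowMeans(selU[, ok, drop = FALSE]),
    genetic_selection_pct = 100 * rowMeans(selV[, ok, drop = FALSE]),
    B = B, n_failed = failures, frac = frac, seed = seed,
    permute = permute,
    penalty_x = penalty_x, penalty_z = penalty_z
  ), class = "scca_null")
  if (!is.null(observed_rho)) out <- null_p_value(out, observed_rho)
  out
}

#' Attach the permutation p-value for an observed median correlation
#'
#' @param null An \code{scca_null} object.
#' @param observed_rho Observed median canonical correlation.
#' @return The \code{scca_null} with \code{observed_rho}, \code{p_value}
#'   (\code{b/B}) and \code{p_value_add_one} (\code{(b+1)/(B+1)}) filled in.
#' @export
null_p_value <- function(null, observed_rho) {
  stopifnot(inherits(null, "scca_null"))
  r <- null$rho[!is.na(null$rho)]
  b <- sum(r >= observed_rho)
  null$observed_rho <- observed_rho
  null$p_value <- b / length(r)
  null$p_value_add_one <- (b + 1) / (length(r) + 1)
  null
}

#' @export
print.scca_null <- function(x, ...) {
  cat(sprintf("Permutation null (B = %d): median null rho = %.3f\n",
              x$B, stats::median(x$rho, na.rm = TRUE)))
  if (!is.null(x$p_value))
    cat(sprintf("  observed median rho = %.3f, p = %.4g (add-one %.4g)\n",
                x$observed_rho, x$p_value, x$p_value_add_one))
  invisible(x)
}
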