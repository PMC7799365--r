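#' Median canonical weights from a bootstrap summary
#'
#' Distills a bootstrapped sparse CCA into the weight vector used for
#' polygenic scoring: the per-genetic-feature median canonical weight, a
#' \code{selected} flag (non-zero median), and provenance.
#'
#' @param bootstrap An \code{\link{bootstrap_scca}} result.
#' @return Object of class \code{weight_vector}: data.frame with columns
#'   \code{feature}, \code{weight}, \code{selected}, \code{selection_pct};
#'   attributes carry \code{B}, \code{seed}, and the penalty pair.
#' @export
median_weights <- function(bootstrap) {
  stopifnot(inherits(bootstrap, "scca_bootstrap"))
  w <- data.frame(feature = names(bootstrap$median_weight),
                  weight = unname(bootstrap$median_weight),
                  selected = unname(bootstrap$median_weight != 0),
                  selection_pct = unname(bootstrap$selection_pct),
                  stringsAsFactors = FALSE)
  structure(w, class = c("weight_vector", "data.frame"),
            B = bootstrap$B, seed = bootstrap$seed,
            penalty_x = bootstrap$penalty_x,
            penalty_z = bootstrap$penalty_z)
}

#' Weighted and unweighted polygenic risk scores
#'
#' The weighted score (wPRS) multiplies each subject's raw allele dosage or
#' binary coding at every included genetic feature by that feature's median
#' canonical weight and sums; the unweighted score (uPRS) sums raw dosages
#' over the selected (non-zero-weight) features.  Ancestry principal
#' component columns are adjustment features inside the sparse CCA and are
#' excluded from both scores by default, so the score transfers to cohorts
#' where the discovery-cohort PC axes do not exist.
#'
#' @param genotypes Raw (unstandardized) genotype feature matrix with
#'   subject rownames.
#' @param weights A \code{\link{median_weights}} result, or any data.frame
#'   with \code{feature}, \code{weight}, \code{selected}.
#' @param include_pcs Include principal-component features in the scores.
#' @return data.frame: \code{subject_id}, \code{wPRS}, \code{uPRS}.
#'   Subjects with a missing feature value get NA scores (with a message).
#' @export
#' @examples
#' G <- matrix(c(0, 1, 2), 1, dimnames = list("s1", c("a", "b", "c")))
#' w <- data.frame(feature = c("a", "b", "c"), weight = c(0.5, -0.2, 0.1),
#'                 selected = c(TRUE, TRUE, TRUE))
#' compute_scores(G, w)  # wPRS = 0*0.5 + 1*-0.2 + 2*0.1 = 0
compute_scores <- function(genotypes, weights, include_pcs = FALSE) {
  G <- as.matrix(genotypes)
  w <- as.data.frame(weights)
  missing_feat <- setdiff(w$feature, colnames(G))
  if (length(missing_feat))
    stop("features absent from genotype matrix: ",
         paste(missing_feat, collapse = ", "))
  ft <- attr(genotypes, "feature_type")
  is_pc <- if (!is.null(ft)) {
    stats::setNames(ft == "pc", colnames(G))[w$feature]
  } else grepl("^PC[0-9]+$", w$feature)
  keep <- if (include_pcs) rep(TRUE, nrow(w)) else !is_pc
  wk <- w[keep, , drop = FALSE]
  Gk <- G[, wk$feature, drop = FALSE]
  incomplete <- rowSums(is.na(Gk)) > 0
  if (any(incomplete))
    message(sprintf("compute_scores: %d subject(s) with missing features get NA scores",
                    sum(incomplete)))
  wprs <- as.vector(Gk %*% wk$weight)
  sel <- wk$selected
  uprs <- if (any(sel)) rowSums(Gk[, sel, drop = FALSE]) else
    rep(0, nrow(Gk))
  wprs[incomplete] <- NA_real_; uprs[incomplete] <- NA_real_
  data.frame(subject_id = rownames(G), wPRS = wprs, uPRS = unname(uprs),
             stringsAsFactors = FALSE)
}

#' Spearman associations with family-wise error control
#'
#' Tie-corrected Spearman rank correlations between a per-subject score and
#' each outcome column, with Holm step-down adjustment across the outcome
#' family.  Pairs with a constant score or outcome are flagged and excluded
#' from the family.
#'
#' @param score Named numeric vector (names = subject ids) or data.frame
#'   with \code{subject_id} and a score column.
#' @param outcomes Matrix or data.frame of per-subject outcome values with
#'   subject rownames.
#' @param score_col Score column used when \code{score} is a data.frame.
#' @param min_pairs Minimum paired observations per outcome.
#' @return data.frame: \code{outcome}, \code{n}, \code{rho}, \code{p},
#'   \code{p_adj} (Holm), \code{flagged}.
#' @export
spearman_assoc <- function(score, outcomes, score_col = "wPRS",
                           min_pairs = 10) {
  if (is.data.frame(score))
    score <- stats::setNames(score[[score_col]], score$subject_id)
  outcomes <- as.matrix(outcomes)
  res <- lapply(colnames(outcomes), function(oc) {
    y <- outcomes[, oc]
    ids <- intersect(names(score)[!is.na(score)],
                     rownames(outcomes)[!is.na(y)])
    x <- score[ids]; yy <- y[ids]
    if (length(ids) < min_pairs)
      stop(sprintf("outcome %s: only %d paired observations (need >= %d)",
                   oc, length(ids), min_pairs))
    if (stats::sd(x) < 1e-12 || stats::sd(yy) < 1e-12)
      return(data.frame(outcome = oc, n = length(ids), rho = NA_real_,
                        p = NA_real_, flagged = TRUE))
    ct <- suppressWarnings(
      stats::cor.test(x, yy, method = "spearman", exact = FALSE))
    data.frame(outcome = oc, n = length(ids),
               rho = unname(ct$estimate), p = ct$p.value, flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- NA_real_
  in_family <- !res$flagged
  res$p_adj[in_family] <- stats::p.adjust(res$p[in_family], method = "holm")
  rownames(res) <- NULL
  res[, c("outcome", "n", "rho", "p", "p_adj", "flagged")]
}

#' Proportional-odds association of a score with an ordinal outcome
#'
#' Cumulative-logit (proportional-odds) regression of an ordinal rating
#' (e.g., 0-3 neuronal-loss severity in a sampled cortical region) on a
#' polygenic score, with optional covariate adjustment (age at death,
#' disease duration).  Fit by maximum likelihood via \code{MASS::polr}.
#' The odds ratio per unit score is \code{exp(coef)} with a Wald 95\% CI;
#' when quasi-separation is detected (inflated standard error), the fit is
#' flagged and a profile-likelihood CI is reported instead.
#'
#' @param score Numeric vector.
#' @param outcome Integer/factor ordinal ratings; at least two levels.
#' @param covariates Optional data.frame of adjustment covariates (same
#'   rows as \code{score}).
#' @param min_n Minimum sample size.
#' @return List: \code{or}, \code{ci} (95\%), \code{p}, \code{coef},
#'   \code{se}, \code{ci_method} ("wald" or "profile"), \code{flagged},
#'   \code{n}.
#' @export
ordinal_assoc <- function(score, outcome, covariates = NULL, min_n = 20) {
  keep <- !is.na(score) & !is.na(outcome)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  score <- score[keep]; outcome <- outcome[keep]
  d <- data.frame(.y = factor(outcome, ordered = TRUE), .score = score)
  if (!is.null(covariates)) d <- cbind(d, covariates[keep, , drop = FALSE])
  if (nlevels(droplevels(d$.y)) < 2)
    stop("ordinal outcome has fewer than 2 observed levels")
  if (nrow(d) < min_n) stop("need at least ", min_n, " observations")
  d$.y <- droplevels(d$.y)
  form <- stats::as.formula(paste(".y ~ .score",
                                  if (!is.null(covariates))
                                    paste("+", paste(colnames(covariates),
                                                     collapse = " + "))
                                  else ""))
  fit <- suppressWarnings(MASS::polr(form, data = d, Hess = TRUE))
  sm <- suppressWarnings(summary(fit))
  est <- sm$coefficients[".score", "Value"]
  se <- sm$coefficients[".score", "Std. Error"]
  flagged <- !is.finite(se) || se > 10 * max(1, abs(est))
  if (flagged) {
    ci_l <- suppressWarnings(suppressMessages(tryCatch(
      stats::confint(fit, parm = ".score", level = 0.95),
      error = function(e) c(NA_real_, NA_real_))))
    ci <- exp(as.numeric(ci_l))
    ci_method <- "profile"
  } else {
    ci <- exp(est + c(-1, 1) * stats::qnorm(0.975) * se)
    ci_method <- "wald"
  }
  p <- 2 * stats::pnorm(-abs(est / se))
  list(or = exp(est), ci = ci, p = p, coef = est, se = se,
       ci_method = ci_method, flagged = flagged, n = nrow(d))
}

#' Simulate ordinal ratings from a latent logistic model
#'
#' Generates 0-3 ordinal outcomes whose cumulative log-odds increase by
#' \code{log_or} per unit score: the generative counterpart of
#' \code{\link{ordinal_assoc}}, used as its recovery oracle.
#'
#' @param score Numeric vector.
#' @param log_or True per-unit log odds (0 for a null outcome).
#' @param thresholds Latent cutpoints separating the four levels.
#' @param covariates Optional data.frame; \code{covariate_log_or} gives the
#'   per-column latent effects.
#' @param covariate_log_or Numeric vector, one per covariate column.
#' @param seed Integer seed.
#' @return Integer vector of ratings in 0..3.
#' @export
simulate_ordinal_outcomes <- function(score, log_or = 0,
                                      thresholds = c(-1.5, 0, 1.5),
                                      covariates = NULL,
                                      covariate_log_or = NULL,
                                      seed = 1L) {
  local_seed(seed)
  eta <- log_or * score
  if (!is.null(covariates))
    eta <- eta + as.vector(as.matrix(covariates) %*% covariate_log_or)
  latent <- eta + stats::rlogis(length(score))
  findInterval(latent, thresholds)
}

#' Sensitivity rerun of the bootstrapped model under exclusions
#'
#' Re-runs the bootstrapped sparse CCA after excluding genetic features
#' (e.g., one member of each high-LD pair) and/or subjects, recomputes the
#' weighted score, and compares the run to a base run: Pearson correlation
#' between the two wPRS variants over shared subjects and the
#' sign-agreement of shared non-zero weights.
#'
#' @param X,Z Clinical and genetic matrices of the base analysis.
#' @param genotypes Raw genotype feature matrix (for scoring).
#' @param base Base \code{\link{bootstrap_scca}} result.
#' @param exclude_features,exclude_subjects Character vectors of feature /
#'   subject names to drop (either may be empty; both empty is a no-op
#'   rerun and warns).
#' @param B,frac,seed Bootstrap settings of the rerun (defaults match the
#'   base run).
#' @return List: \code{wprs_cor} (Pearson r between base and rerun wPRS),
#'   \code{sign_agreement} (fraction of features non-zero in both runs with
#'   matching weight sign), \code{weights} (rerun), \code{scores} (rerun),
#'   \code{bootstrap} (rerun).
#' @export
sensitivity_rerun <- function(X, Z, genotypes, base,
                              exclude_features = character(),
                              exclude_subjects = character(),
                              B = base$B, frac = base$frac,
                              seed = base$seed) {
  stopifnot(inherits(base, "scca_bootstrap"))
  if (!length(exclude_features) && !length(exclude_subjects))
    warning("empty exclusion lists: rerun is an identity check")
  keep_r <- setdiff(rownames(X), exclude_subjects)
  keep_c <- setdiff(colnames(Z), exclude_features)
  ft <- attr(genotypes, "feature_type")
  Z2 <- Z[keep_r, keep_c, drop = FALSE]
  X2 <- X[keep_r, , drop = FALSE]
  boot2 <- bootstrap_scca(X2, Z2, base$penalty_x, base$penalty_z,
                          B = B, frac = frac, seed = seed)
  w_base <- median_weights(base)
  w2 <- median_weights(boot2)
  G2 <- genotypes[, keep_c, drop = FALSE]
  if (!is.null(ft))
    attr(G2, "feature_type") <- ft[match(keep_c, colnames(genotypes))]
  s_base <- compute_scores(genotypes, w_base)
  s2 <- compute_scores(G2, w2)
  shared <- intersect(s_base$subject_id, s2$subject_id)
  wprs_cor <- stats::cor(s_base$wPRS[match(shared, s_base$subject_id)],
                         s2$wPRS[match(shared, s2$subject_id)])
  common <- merge(w_base, w2, by = "feature")
  both_nz <- common$weight.x != 0 & common$weight.y != 0
  sign_agreement <- if (any(both_nz))
    mean(sign(common$weight.x[both_nz]) == sign(common$weight.y[both_nz]))
  else NA_real_
  list(wprs_cor = wprs_cor, sign_agreement = sign_agreement,
       weights = w2, scores = s2, bootstrap = boot2)
}
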