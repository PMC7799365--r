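#' Per-subject adjusted trajectories from a linear mixed-effects model
#'
#' Fits, for one clinical measure, a linear mixed-effects model of the
#' observed scores with fixed effects for age at baseline (years), lag from
#' symptom onset to baseline (years), college education, bulbar onset, and
#' visit month, and a per-subject random intercept and random slope on
#' visit month.  The model is fit by maximum likelihood (not REML).  The
#' adjusted baseline for a subject is the population intercept plus the
#' subject's predicted (empirical BLUP) random intercept; the adjusted rate
#' of decline is the population visit-month coefficient plus the predicted
#' random slope.  Covariate fixed effects are thereby regressed out of both
#' quantities.
#'
#' Covariate columns are mean-centered internally, so the adjusted
#' intercept refers to a subject with cohort-average covariates and is
#' invariant to constant shifts of any covariate column.  Subjects missing
#' any baseline covariate are dropped from the fit (complete case) with a
#' message.  Slopes are reported only for subjects with at least two
#' observations.
#'
#' @param clinical Long-format data.frame: \code{subject_id},
#'   \code{measure}, \code{visit_month}, \code{value}.
#' @param covariates Per-subject data.frame: \code{subject_id},
#'   \code{age_at_baseline}, \code{onset_lag}, \code{college},
#'   \code{bulbar_onset}.
#' @param measure Measure name to fit.
#' @return data.frame: \code{subject_id}, \code{measure}, \code{intercept},
#'   \code{slope} (NA when \code{n_obs < 2}), \code{n_obs},
#'   \code{converged}.
#' @export
fit_trajectories <- function(clinical, covariates, measure) {
  d <- clinical[clinical$measure == measure, , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for measure ", measure)
  d <- merge(d, covariates, by = "subject_id")
  cc <- stats::complete.cases(
    d[, c("value", "visit_month", "age_at_baseline", "onset_lag",
          "college", "bulbar_onset")])
  if (any(!cc)) {
    message(sprintf("%s: dropping %d incomplete observation(s)",
                    measure, sum(!cc)))
    d <- d[cc, , drop = FALSE]
  }
  if (length(unique(d$subject_id)) < 2)
    stop("need at least 2 subjects to fit ", measure)
  d$subject_id <- factor(d$subject_id)
  d <- center_covariates(d)

  warned <- FALSE
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(
        value ~ age_at_baseline + onset_lag + college + bulbar_onset +
          visit_month + (1 + visit_month | subject_id),
        data = d, REML = FALSE,
        control = lme4::lmerControl(check.conv.singular = "ignore")),
      error = function(e) NULL),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))

  n_obs <- table(d$subject_id)
  subjects <- names(n_obs)
  if (is.null(fit)) {
    warning("mixed model for ", measure, " failed to fit; estimates absent")
    return(data.frame(subject_id = subjects, measure = measure,
                      intercept = NA_real_, slope = NA_real_,
                      n_obs = as.integer(n_obs), converged = FALSE,
                      stringsAsFactors = FALSE))
  }
  fx <- lme4::fixef(fit)
  re <- lme4::ranef(fit)$subject_id
  est <- data.frame(
    subject_id = subjects,
    measure = measure,
    intercept = fx[["(Intercept)"]] + re[subjects, "(Intercept)"],
    slope = fx[["visit_month"]] + re[subjects, "visit_month"],
    n_obs = as.integer(n_obs),
    converged = !warned,
    stringsAsFactors = FALSE
  )
  est$slope[est$n_obs < 2] <- NA_real_
  rownames(est) <- NULL
  est
}

# mean-center the covariate fixed effects (not visit_month): the adjusted
# intercept then refers to a subject with cohort-average covariates, and
# adding a constant to any covariate column provably leaves every adjusted
# estimate unchanged
center_covariates <- function(d) {
  for (v in c("age_at_baseline", "onset_lag", "college", "bulbar_onset"))
    d[[v]] <- d[[v]] - mean(d[[v]])
  d
}

#' Fit adjusted trajectories for a set of measures
#'
#' @inheritParams fit_trajectories
#' @param measures Measure names (default: every measure present).
#' @return Row-bound data.frame of \code{\link{fit_trajectories}} results.
#' @export
fit_all_trajectories <- function(clinical, covariates, measures = NULL) {
  if (is.null(measures)) measures <- unique(clinical$measure)
  do.call(rbind, lapply(measures, function(m)
    fit_trajectories(clinical, covariates, m)))
}

#' Matrix of column-scaled adjusted baselines
#'
#' Reshapes trajectory estimates into a subjects x measures matrix of
#' adjusted intercepts and z-scores every column (sample-SD convention,
#' mean 0, variance 1) -- the clinical dataset entering the sparse CCA.
#' Subjects missing the intercept for any requested measure are dropped
#' with a message.
#'
#' @param estimates Output of \code{\link{fit_all_trajectories}}.
#' @param measures Measures to include (default: all present).
#' @return Numeric matrix with subject rownames; columns have mean 0 and
#'   unit variance.  A zero-variance column is an error naming the measure.
#' @export
scale_intercepts <- function(estimates, measures = NULL) {
  W <- trajectory_matrix(estimates, "intercept", measures)
  keep <- stats::complete.cases(W)
  if (any(!keep))
    message(sprintf("scale_intercepts: dropping %d subject(s) with missing measures",
                    sum(!keep)))
  W <- W[keep, , drop = FALSE]
  scale_columns(W, strict = TRUE)
}

#' Subjects x measures matrix of one trajectory quantity
#'
#' @param estimates Output of \code{\link{fit_all_trajectories}}.
#' @param what \code{"intercept"} or \code{"slope"}.
#' @param measures Measures to include.
#' @return Numeric matrix (NA where a subject lacks the estimate).
#' @export
trajectory_matrix <- function(estimates, what = c("intercept", "slope"),
                              measures = NULL) {
  what <- match.arg(what)
  if (is.null(measures)) measures <- unique(estimates$measure)
  subjects <- sort(unique(estimates$subject_id))
  W <- matrix(NA_real_, length(subjects), length(measures),
              dimnames = list(subjects, measures))
  for (m in measures) {
    e <- estimates[estimates$measure == m, ]
    W[e$subject_id, m] <- e[[what]]
  }
  W
}

#' Univariate SNP scan across clinical measures
#'
#' Post-hoc complement to the multivariate analysis: one mixed-effects
#' model per (SNP, measure) pair, adding the SNP dosage to the five
#' baseline covariates as a fixed effect (45 SNPs x 11 measures = 495
#' models on the default panel).  Satterthwaite p-values for the dosage
#' coefficient are obtained via \pkg{lmerTest}.  Monomorphic SNP columns
#' are flagged and their models skipped; per-model failures are recorded
#' and the scan continues.
#'
#' @inheritParams fit_trajectories
#' @param genotypes Genotype feature matrix; only columns of type
#'   \code{"snp"} (or all columns if untyped) are scanned.
#' @param measures Measures to scan (default: all present).
#' @return List of SNP x measure matrices \code{coef}, \code{p}, and
#'   logical \code{converged}.
#' @export
per_snp_scan <- function(clinical, covariates, genotypes, measures = NULL) {
  if (is.null(measures)) measures <- unique(clinical$measure)
  ft <- attr(genotypes, "feature_type")
  snp_cols <- if (is.null(ft)) colnames(genotypes) else colnames(genotypes)[ft == "snp"]
  dos <- data.frame(subject_id = rownames(genotypes),
                    genotypes[, snp_cols, drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  co <- matrix(NA_real_, length(snp_cols), length(measures),
               dimnames = list(snp_cols, measures))
  pv <- co
  cv <- matrix(FALSE, length(snp_cols), length(measures),
               dimnames = dimnames(co))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  for (m in measures) {
    d0 <- clinical[clinical$measure == m, , drop = FALSE]
    d0 <- merge(merge(d0, covariates, by = "subject_id"), dos,
                by = "subject_id")
    d0$subject_id <- factor(d0$subject_id)
    d0 <- center_covariates(d0)
    for (s in snp_cols) {
      if (stats::var(genotypes[, s]) < 1e-12) next  # monomorphic: flagged
      d0$snp_dosage <- d0[[s]]
      fit <- tryCatch(suppressWarnings(suppressMessages(
        lmerTest::lmer(
          value ~ snp_dosage + age_at_baseline + onset_lag + college +
            bulbar_onset + visit_month + (1 + visit_month | subject_id),
          data = d0, REML = FALSE, control = ctrl))),
        error = function(e) NULL)
      if (is.null(fit)) next
      sm <- tryCatch(suppressWarnings(stats::coef(summary(fit))),
                     error = function(e) NULL)
      if (is.null(sm) || !"snp_dosage" %in% rownames(sm)) next
      co[s, m] <- sm["snp_dosage", "Estimate"]
      pv[s, m] <- sm["snp_dosage", "Pr(>|t|)"]
      cv[s, m] <- TRUE
    }
  }
  list(coef = co, p = pv, converged = cv)
}
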