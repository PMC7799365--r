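#' Synthetic cohort configuration
#'
#' Bundles and validates all parameters of the synthetic ALS cohort
#' generator.  Defaults mirror the study conditions of the discovery
#' analysis: 327 subjects, a 45-SNP dosage panel plus five covariate
#' features (sex, C9orf72 repeat-expansion carrier, other-mutation carrier,
#' two ancestry principal components), scheduled visits at 0/3/6/12/18
#' months, and monotone attrition leaving 84.7\% of subjects with two or
#' more visits.
#'
#' @param n_subjects Number of subjects.
#' @param maf Vector of minor-allele frequencies in (0, 0.5], one per SNP.
#' @param planted_weights True sparse weight vector over the genetic
#'   features (length \code{length(maf) + 5}); defines the latent genetic
#'   liability driving cognitive baseline and decline.  Default plants a
#'   10-SNP support among the 45 SNPs with mixed signs; zero covariate
#'   loadings.  \code{NULL} keeps the default; pass \code{0} for a null
#'   cohort (scalar is recycled).
#' @param signal_frac Named vector, fraction of between-subject baseline
#'   variance per measure explained by the genetic composite; defaults from
#'   \code{\link{clinical_measures}} (motor measures 0).  A scalar is applied
#'   to all cognitive measures.
#' @param shared_frac Fraction of between-subject variance per measure due
#'   to a shared non-genetic domain factor (one factor for the cognitive
#'   measures, an independent one for the motor measures).  This reproduces
#'   the strong within-domain collinearity of real clinical batteries --
#'   the ECAS Total literally aggregates its subscores, and overall disease
#'   severity drives all motor scores -- while keeping the cognitive and
#'   motor domains independent.  Scalar or named vector; default 0.45 for
#'   cognitive and 0.50 for motor measures.
#' @param slope_attenuation Factor (default 0.6) by which the genetic
#'   composite's loading on rates of decline is attenuated relative to its
#'   loading on baselines.
#' @param visit_months Scheduled visit times in months since baseline.
#' @param dropout_prob Per-visit attrition probability in [0, 1]: the
#'   baseline visit is always observed; at every later scheduled visit the
#'   subject permanently drops out with this probability.  Probability of
#'   retaining >= 2 visits is therefore \code{1 - dropout_prob}.
#' @param covariate_effects List of per-SD effects on cognitive baselines:
#'   \code{age} (per year, centered), \code{college}, \code{bulbar},
#'   \code{onset_lag} (per year).
#' @param ld_blocks Optional list describing block-correlated SNPs for
#'   linkage-disequilibrium sensitivity reruns: each element
#'   \code{list(snps = <indices>, r = <latent correlation>)} induces
#'   exchangeable correlation among the named SNP dosages via a Gaussian
#'   copula.
#' @param p_sex,p_c9,p_othermut Bernoulli rates of the binary covariate
#'   features.
#' @param seed Integer seed; identical seed + config gives bit-identical
#'   cohorts.
#' @param allow_degenerate_maf Permit \code{maf = 0} columns (test mode).
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 327L,
                          maf = seq(0.05, 0.5, length.out = 45),
                          planted_weights = NULL,
                          signal_frac = NULL,
                          shared_frac = NULL,
                          slope_attenuation = 0.6,
                          visit_months = c(0, 3, 6, 12, 18),
                          dropout_prob = 0.153,
                          covariate_effects = list(age = -0.015,
                                                   college = 0.4,
                                                   bulbar = -0.2,
                                                   onset_lag = 0),
                          ld_blocks = NULL,
                          p_sex = 0.5, p_c9 = 0.09, p_othermut = 0.04,
                          seed = 1L,
                          allow_degenerate_maf = FALSE) {
  stopifnot(n_subjects >= 1, length(maf) >= 1)
  lo <- if (allow_degenerate_maf) 0 else 1e-12
  if (any(maf < lo | maf > 0.5))
    stop("all minor-allele frequencies must lie in (0, 0.5]")
  if (dropout_prob < 0 || dropout_prob > 1)
    stop("dropout_prob must lie in [0, 1]")
  n_feat <- length(maf) + 5L
  if (is.null(planted_weights)) {
    planted_weights <- default_planted_weights(length(maf))
  } else if (length(planted_weights) == 1L) {
    planted_weights <- rep(planted_weights, n_feat)
  }
  if (length(planted_weights) != n_feat)
    stop("planted_weights must have length n_snps + 5 (genetic features)")
  meta <- clinical_measures()
  sf <- meta$signal_frac
  names(sf) <- meta$measure
  if (!is.null(signal_frac)) {
    if (is.null(names(signal_frac)) && length(signal_frac) == 1L) {
      sf[meta$domain == "cognitive"] <- signal_frac
    } else {
      sf[names(signal_frac)] <- signal_frac
    }
  }
  if (any(sf < 0 | sf > 1)) stop("signal fractions must lie in [0, 1]")
  cf <- stats::setNames(ifelse(meta$domain == "cognitive", 0.45, 0.50),
                        meta$measure)
  if (!is.null(shared_frac)) {
    if (is.null(names(shared_frac)) && length(shared_frac) == 1L) {
      cf[] <- shared_frac
    } else {
      cf[names(shared_frac)] <- shared_frac
    }
  }
  if (any(cf < 0) || any(sf + cf > 1))
    stop("signal_frac + shared_frac must lie in [0, 1] for every measure")
  structure(list(
    n_subjects = as.integer(n_subjects), maf = maf,
    planted_weights = planted_weights, signal_frac = sf, shared_frac = cf,
    slope_attenuation = slope_attenuation,
    visit_months = sort(unique(visit_months)),
    dropout_prob = dropout_prob,
    covariate_effects = covariate_effects, ld_blocks = ld_blocks,
    p_sex = p_sex, p_c9 = p_c9, p_othermut = p_othermut,
    seed = as.integer(seed),
    allow_degenerate_maf = allow_degenerate_maf
  ), class = "cohort_config")
}

# default planted signal: 10 SNPs with mixed signs, unit L2 norm
default_planted_weights <- function(n_snps) {
  w <- numeric(n_snps + 5L)
  support <- round(seq(2, n_snps - 1, length.out = 10))
  vals <- seq(1, 0.4, length.out = 10) * c(-1, 1)  # alternating signs
  w[support] <- vals
  w / sqrt(sum(w^2))
}

#' Names of the genetic features in a simulated panel
#' @param n_snps Number of SNPs in the panel.
#' @return Character vector: SNP ids then sex, c9orf72, other_mutation, PC1, PC2.
#' @export
genetic_feature_names <- function(n_snps = 45L) {
  c(sprintf("snp%02d", seq_len(n_snps)),
    "sex", "c9orf72", "other_mutation", "PC1", "PC2")
}

#' Simulate a genotype feature matrix
#'
#' SNP dosages are drawn per subject as Binomial(2, maf) under
#' Hardy-Weinberg equilibrium (additive coding: 0/1/2 copies of the minor
#' allele), binary covariates as Bernoulli, and placeholder ancestry
#' principal components as standard normal.  An optional Gaussian-copula
#' block mode induces linkage disequilibrium among chosen SNPs.
#'
#' @inheritParams cohort_config
#' @param maf Minor-allele frequency vector.
#' @return Numeric matrix (subjects x features) with a \code{feature_type}
#'   attribute ("snp", "binary", "pc") and rownames \code{s0001, ...}.
#' @export
#' @examples
#' G <- simulate_genotypes(c(0.1, 0.3, 0.5), n_subjects = 20, seed = 7)
#' dim(G)
simulate_genotypes <- function(maf, n_subjects, seed,
                               p_sex = 0.5, p_c9 = 0.09, p_othermut = 0.04,
                               ld_blocks = NULL,
                               allow_degenerate_maf = FALSE) {
  lo <- if (allow_degenerate_maf) 0 else 1e-12
  if (any(maf < lo | maf > 0.5))
    stop("all minor-allele frequencies must lie in (0, 0.5]")
  stopifnot(n_subjects >= 1)
  local_seed(seed)
  q <- length(maf)
  snps <- vapply(maf, function(m) stats::rbinom(n_subjects, 2L, m),
                 numeric(n_subjects))
  if (n_subjects == 1L) snps <- matrix(snps, nrow = 1L)
  if (!is.null(ld_blocks)) {
    for (blk in ld_blocks) {
      idx <- blk$snps
      r <- blk$r
      k <- length(idx)
      z0 <- stats::rnorm(n_subjects)
      z <- sqrt(r) * matrix(z0, n_subjects, k) +
        sqrt(1 - r) * matrix(stats::rnorm(n_subjects * k), n_subjects, k)
      for (j in seq_len(k)) {
        snps[, idx[j]] <- stats::qbinom(stats::pnorm(z[, j]), 2L, maf[idx[j]])
      }
    }
  }
  G <- cbind(snps,
             stats::rbinom(n_subjects, 1L, p_sex),
             stats::rbinom(n_subjects, 1L, p_c9),
             stats::rbinom(n_subjects, 1L, p_othermut),
             stats::rnorm(n_subjects),
             stats::rnorm(n_subjects))
  colnames(G) <- genetic_feature_names(q)
  rownames(G) <- sprintf("s%04d", seq_len(n_subjects))
  attr(G, "feature_type") <- c(rep("snp", q), rep("binary", 3), rep("pc", 2))
  G
}

#' Simulate longitudinal clinical phenotypes from a genotype matrix
#'
#' A latent genetic liability (standardized genetic features times the
#' planted weight vector, scaled to unit variance) drives per-subject true
#' baselines and rates of decline on the cognitive measures; motor measures
#' (ALSFRS-R, UMN, LMN) are generated independently of the liability.
#' Observed values are truth plus i.i.d. Gaussian noise at the scheduled
#' visits, with monotone attrition and clipping to instrument bounds.
#'
#' @param genotypes Matrix from \code{\link{simulate_genotypes}}.
#' @param config A \code{\link{cohort_config}}.
#' @return List with \code{clinical} (long data.frame: subject_id, measure,
#'   visit_month, value), \code{covariates} (per-subject baseline
#'   covariates), and \code{truth} (planted weights, liability, true
#'   intercept/slope matrices, clipped fraction).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(genotypes)
  meta <- clinical_measures()
  local_seed(config$seed + 1L)

  # latent liability: standardized features x planted weights, unit variance
  Gs <- scale_columns(genotypes)
  liab <- as.vector(Gs %*% config$planted_weights)
  liab_degenerate <- stats::sd(liab) < 1e-12
  if (!liab_degenerate) liab <- liab / stats::sd(liab)

  covars <- data.frame(
    subject_id = rownames(genotypes),
    age_at_baseline = round(stats::rnorm(n, 58, 11), 1),
    onset_lag = round(pmax(0.2, stats::rnorm(n, 3.8, 3.0)), 1),
    college = stats::rbinom(n, 1L, 0.7),
    bulbar_onset = stats::rbinom(n, 1L, 0.2),
    stringsAsFactors = FALSE
  )
  ce <- config$covariate_effects
  cov_sd_units <- ce$age * (covars$age_at_baseline - mean(covars$age_at_baseline)) +
    ce$college * covars$college + ce$bulbar * covars$bulbar_onset +
    ce$onset_lag * (covars$onset_lag - mean(covars$onset_lag))

  nm <- nrow(meta)
  true_int <- matrix(NA_real_, n, nm, dimnames = list(rownames(genotypes), meta$measure))
  true_slp <- true_int
  a <- config$slope_attenuation
  # shared non-genetic domain factors (baseline and decline), independent
  # between the cognitive and motor domains
  fac_int <- list(cognitive = stats::rnorm(n), motor = stats::rnorm(n))
  fac_slp <- list(cognitive = stats::rnorm(n), motor = stats::rnorm(n))
  for (j in seq_len(nm)) {
    # a degenerate (all-zero) liability carries no variance: its share
    # collapses into the idiosyncratic term so columns stay unit-variance
    # and exchangeable within domain under a null configuration
    s <- if (liab_degenerate) 0 else config$signal_frac[[meta$measure[j]]]
    cshr <- config$shared_frac[[meta$measure[j]]]
    dom <- meta$domain[j]
    # risk orientation: higher liability -> lower cognitive scores, faster decline
    int_std <- -sqrt(s) * liab + sqrt(cshr) * fac_int[[dom]] +
      sqrt(1 - s - cshr) * stats::rnorm(n)
    c_slp <- min(cshr, 1 - a^2 * s)
    slp_std <- -a * sqrt(s) * liab + sqrt(c_slp) * fac_slp[[dom]] +
      sqrt(1 - a^2 * s - c_slp) * stats::rnorm(n)
    true_int[, j] <- meta$mean[j] + meta$sd[j] * (int_std + cov_sd_units)
    true_slp[, j] <- meta$slope_mean[j] + meta$slope_sd[j] * slp_std
  }

  # monotone attrition: baseline always observed, then drop for good
  vm <- config$visit_months
  n_visits <- length(vm)
  kept <- matrix(FALSE, n, n_visits)
  kept[, 1] <- TRUE
  if (n_visits > 1) {
    for (v in 2:n_visits) {
      kept[, v] <- kept[, v - 1] &
        (stats::runif(n) >= config$dropout_prob)
    }
  }

  total <- 0L; clipped <- 0L
  rows <- vector("list", nm)
  for (j in seq_len(nm)) {
    obs <- lapply(seq_len(n_visits), function(v) {
      idx <- which(kept[, v])
      if (!length(idx)) return(NULL)
      val <- true_int[idx, j] + true_slp[idx, j] * vm[v] +
        stats::rnorm(length(idx), 0, meta$noise_sd[j])
      data.frame(subject_id = rownames(genotypes)[idx],
                 measure = meta$measure[j],
                 visit_month = vm[v], value = val,
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, obs)
    lo <- meta$min[j]; hi <- meta$max[j]
    clipped <- clipped + sum(d$value < lo | d$value > hi)
    total <- total + nrow(d)
    d$value <- pmin(pmax(d$value, lo), hi)
    rows[[j]] <- d
  }
  clinical <- do.call(rbind, rows)
  clinical <- clinical[order(clinical$measure, clinical$subject_id,
                             clinical$visit_month), ]
  rownames(clinical) <- NULL

  truth <- list(planted_weights = config$planted_weights,
                liability = stats::setNames(liab, rownames(genotypes)),
                true_intercepts = true_int, true_slopes = true_slp,
                clipped_fraction = clipped / total)
  list(clinical = clinical, covariates = covars, truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper drawing genotypes and phenotypes from one config.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return Object of class \code{synthetic_cohort}: list with
#'   \code{genotypes}, \code{clinical}, \code{covariates}, \code{truth},
#'   \code{config}.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 40, seed = 3)
#' coh <- simulate_cohort(cfg)
#' head(coh$clinical)
simulate_cohort <- function(config = cohort_config()) {
  G <- simulate_genotypes(config$maf, config$n_subjects, config$seed,
                          p_sex = config$p_sex, p_c9 = config$p_c9,
                          p_othermut = config$p_othermut,
                          ld_blocks = config$ld_blocks,
                          allow_degenerate_maf = config$allow_degenerate_maf)
  ph <- simulate_phenotypes(G, config)
  structure(c(list(genotypes = G), ph, list(config = config)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic ALS cohort:", nrow(x$genotypes), "subjects,",
      sum(attr(x$genotypes, "feature_type") == "snp"), "SNPs,",
      length(unique(x$clinical$measure)), "clinical measures\n")
  cat(sprintf("  observations: %d  (clipped fraction %.3f)\n",
              nrow(x$clinical), x$truth$clipped_fraction))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits tab-separated tables (clinical long table, baseline covariates,
#' dosage matrix, SNP panel) and a minimal VCF 4.2 with the SNP dosages
#' recoded as genotypes, so the readers in this package can be exercised
#' end to end.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ft <- attr(cohort$genotypes, "feature_type")
  snp_cols <- which(ft == "snp")
  panel <- synthetic_panel(length(snp_cols), cohort$config$maf)
  paths <- c(
    clinical = file.path(dir, "clinical.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    dosages = file.path(dir, "dosages.tsv"),
    panel = file.path(dir, "panel.tsv"),
    vcf = file.path(dir, "genotypes.vcf")
  )
  write_tsv_table(cohort$clinical, paths[["clinical"]])
  write_tsv_table(cohort$covariates, paths[["covariates"]])
  dos <- data.frame(subject_id = rownames(cohort$genotypes),
                    as.data.frame(cohort$genotypes),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(dos, paths[["dosages"]])
  write_tsv_table(panel, paths[["panel"]])
  write_vcf(cohort$genotypes[, snp_cols, drop = FALSE], panel, paths[["vcf"]])
  invisible(paths)
}

# panel description for simulated SNPs: minor allele is ALT by construction
synthetic_panel <- function(n_snps, maf) {
  data.frame(snp_id = sprintf("snp%02d", seq_len(n_snps)),
             chrom = "1", pos = 1000L + 10L * seq_len(n_snps),
             ref = "A", alt = "G",
             effect_allele = "G", maf = maf,
             stringsAsFactors = FALSE)
}
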