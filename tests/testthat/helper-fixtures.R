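# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# default planted-signal cohort at the study scale used across tests
fx_cohort300 <- function() get_fixture("cohort300", function() {
  simulate_cohort(cohort_config(n_subjects = 300, seed = 301))
})

# planted-null cohort (no genetic signal anywhere)
fx_null_cohort <- function() get_fixture("null300", function() {
  simulate_cohort(cohort_config(n_subjects = 300, planted_weights = 0,
                                seed = 401))
})

# scaled true-intercept clinical matrix for a cohort (bypasses LME; the
# trajectory stage has its own recovery tests)
truth_X <- function(cohort) {
  scale(cohort$truth$true_intercepts)
}

# permutation-null calibration experiment at the study conditions:
# 50 planted-null cohorts (n = 300), bootstrap and null at B = 500 each,
# clinical penalty 0.1 (single-selection regime), genetic penalty 0.6
fx_null_calibration <- function() get_fixture("null_calibration", function() {
  pvals <- numeric(50)
  clin_sel <- matrix(NA_real_, 3, 11)
  for (r in 1:50) {
    coh <- simulate_cohort(cohort_config(n_subjects = 300,
                                         planted_weights = 0,
                                         seed = 9000 + r))
    X <- truth_X(coh)
    Z <- coh$genotypes
    boot <- bootstrap_scca(X, Z, 0.1, 0.6, B = 500, seed = 2 * r)
    nul <- permutation_null(X, Z, 0.1, 0.6, B = 500, seed = 2 * r + 1,
                            observed_rho = boot$median_rho)
    pvals[r] <- nul$p_value
    # selection symmetry is a property of the column-permutation scheme
    # (features exchangeable only once within-dataset structure is
    # flattened); measured on the first cohorts and pooled
    if (r <= 3) {
      nc <- permutation_null(X, Z, 0.1, 0.6, B = 500, seed = 2 * r + 1,
                             permute = "columns")
      clin_sel[r, ] <- nc$clinical_selection_pct
      colnames(clin_sel) <- names(nc$clinical_selection_pct)
    }
  }
  list(pvals = pvals, clinical_selection_pct = colMeans(clin_sel))
})

# noise-free deterministic long table: y = 20 + 0.5 * month, covariates 0
fx_deterministic_clinical <- function(n_subjects = 25,
                                      months = c(0, 3, 6, 12, 18)) {
  ids <- sprintf("d%03d", seq_len(n_subjects))
  clin <- expand.grid(subject_id = ids, visit_month = months,
                      stringsAsFactors = FALSE)
  clin$measure <- "ECAS_Total"
  clin$value <- 20 + 0.5 * clin$visit_month
  cov <- data.frame(subject_id = ids, age_at_baseline = 0, onset_lag = 0,
                    college = 0, bulbar_onset = 0)
  list(clinical = clin, covariates = cov)
}
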