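test_that("SNP dosages follow Hardy-Weinberg sampling", {
  n <- 10000
  G <- simulate_genotypes(c(0.5, 0.3, 0.1), n, seed = 7)

  # E(dosage) = 2 * maf, law-of-large-numbers check at 3 standard errors
  for (j in 1:3) {
    maf <- c(0.5, 0.3, 0.1)[j]
    se <- sqrt(2 * maf * (1 - maf) / n)
    expect_lt(abs(mean(G[, j]) - 2 * maf), 3 * se)
  }

  # genotype class frequencies at maf = 0.3 vs analytic HWE proportions
  counts <- tabulate(G[, 2] + 1, nbins = 3)
  ht <- chisq.test(counts, p = c(0.49, 0.42, 0.09))
  expect_gt(ht$p.value, 0.01)
})

test_that("degenerate and invalid allele frequencies are handled", {
  G <- simulate_genotypes(c(0, 0.2), 50, seed = 1,
                          allow_degenerate_maf = TRUE)
  expect_true(all(G[, 1] == 0))
  expect_error(simulate_genotypes(c(0, 0.2), 50, seed = 1),
               "minor-allele frequencies")
  expect_error(simulate_genotypes(c(0.2, 0.6), 50, seed = 1),
               "minor-allele frequencies")
  expect_error(cohort_config(maf = c(0.1, 0.7)), "minor-allele")
  expect_error(cohort_config(dropout_prob = 1.2), "dropout_prob")
  expect_error(cohort_config(planted_weights = c(1, 2)), "length")
})

test_that("identical seed and config give bit-identical cohorts", {
  cfg <- cohort_config(n_subjects = 60, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
})

test_that("variance partition matches the planted signal fraction", {
  # cor(liability, cognitive true intercept) = sqrt(signal_frac) when
  # covariate effects are off; checked within 3 Monte-Carlo SEs at large n
  n <- 100000
  cfg <- cohort_config(n_subjects = n, signal_frac = 0.3,
                       covariate_effects = list(age = 0, college = 0,
                                                bulbar = 0, onset_lag = 0),
                       seed = 11)
  coh <- simulate_cohort(cfg)
  r <- cor(coh$truth$liability,
           coh$truth$true_intercepts[, "ECAS_ALS_Specific"])
  mc_se <- (1 - 0.3) / sqrt(n)  # delta-method SE of a correlation
  expect_lt(abs(abs(r) - sqrt(0.3)), 3 * mc_se)
  # risk orientation: higher liability, lower cognitive score
  expect_lt(r, 0)
})

test_that("null cohorts carry no genotype-phenotype association", {
  # planted_weights = 0: mean |cor| between any genetic feature and any
  # true intercept stays near zero over seeded replicates
  rs <- vapply(1:50, function(s) {
    cfg <- cohort_config(n_subjects = 400, planted_weights = 0, seed = s)
    coh <- simulate_cohort(cfg)
    cor(coh$genotypes[, "snp05"],
        coh$truth$true_intercepts[, "ECAS_Total"])
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.05)
})

test_that("attrition schedule behaves at the boundaries", {
  cfg <- cohort_config(n_subjects = 40, dropout_prob = 1, seed = 5)
  coh <- simulate_cohort(cfg)
  obs <- table(coh$clinical$subject_id, coh$clinical$measure)
  expect_true(all(obs == 1))  # baseline only, every measure

  cfg0 <- cohort_config(n_subjects = 40, dropout_prob = 0, seed = 5)
  coh0 <- simulate_cohort(cfg0)
  obs0 <- table(coh0$clinical$subject_id)
  expect_true(all(obs0 == 5 * 11))  # full schedule, 11 measures
})

test_that("motor and cognitive trajectories are independent by construction", {
  # mirrors the observed near-independence of cognition and motor burden:
  # |Spearman| between motor and cognitive true slopes < 0.2
  ok <- vapply(1:10, function(s) {
    coh <- simulate_cohort(cohort_config(n_subjects = 300, seed = 500 + s))
    rs <- abs(cor(coh$truth$true_slopes[, c("ALSFRS_R", "UMN", "LMN")],
                  coh$truth$true_slopes[, c("ECAS_Total",
                                            "ECAS_ALS_Specific")],
                  method = "spearman"))
    all(rs < 0.2)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("observed values respect instrument bounds and truth + noise structure", {
  coh <- fx_cohort300()
  meta <- clinical_measures()
  for (j in seq_len(nrow(meta))) {
    v <- coh$clinical$value[coh$clinical$measure == meta$measure[j]]
    expect_true(all(v >= meta$min[j] & v <= meta$max[j]))
  }
  expect_gte(coh$truth$clipped_fraction, 0)
  expect_lt(coh$truth$clipped_fraction, 0.25)
})

test_that("block-correlated mode induces LD between chosen SNPs", {
  cfg <- cohort_config(n_subjects = 2000, seed = 77,
                       ld_blocks = list(list(snps = c(10, 11), r = 0.9)))
  coh <- simulate_cohort(cfg)
  r_in <- cor(coh$genotypes[, 10], coh$genotypes[, 11])
  r_out <- cor(coh$genotypes[, 10], coh$genotypes[, 20])
  expect_gt(r_in, 0.6)
  expect_lt(abs(r_out), 0.1)
})

test_that("cohorts round-trip through the on-disk formats", {
  coh <- simulate_cohort(cohort_config(n_subjects = 25, seed = 13))
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))

  dos <- read_genotypes(paths[["dosages"]])
  expect_equal(unname(dos), unname(coh$genotypes), tolerance = 1e-12)

  skip_if_not_installed("vcfR")
  panel <- utils::read.table(paths[["panel"]], sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  vg <- read_genotypes(paths[["vcf"]], panel = panel)
  snp_cols <- which(attr(coh$genotypes, "feature_type") == "snp")
  expect_equal(vg[, ], coh$genotypes[, snp_cols],
               ignore_attr = TRUE, tolerance = 1e-12)
})
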