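make_weights <- function(feature, weight) {
  data.frame(feature = feature, weight = weight, selected = weight != 0,
             stringsAsFactors = FALSE)
}

test_that("score arithmetic follows the weighted/unweighted definitions", {
  G <- matrix(c(0, 1, 2,
                2, 0, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  w <- make_weights(c("a", "b", "c"), c(0.5, -0.2, 0.1))
  sc <- compute_scores(G, w)
  expect_equal(sc$wPRS, c(0 * 0.5 + 1 * -0.2 + 2 * 0.1,
                          2 * 0.5 + 0 * -0.2 + 1 * 0.1))
  expect_equal(sc$uPRS, c(3, 3))  # all three features selected

  # all-zero weights: wPRS identically 0, nothing selected so uPRS = 0
  w0 <- make_weights(c("a", "b", "c"), c(0, 0, 0))
  sc0 <- compute_scores(G, w0)
  expect_equal(sc0$wPRS, c(0, 0))
  expect_equal(sc0$uPRS, c(0, 0))

  # missing dosage: subject's scores absent with a message
  G2 <- G; G2["s2", "b"] <- NA
  expect_message(sc2 <- compute_scores(G2, w), "missing features")
  expect_true(is.na(sc2$wPRS[2]) && is.na(sc2$uPRS[2]))
  expect_false(is.na(sc2$wPRS[1]))

  expect_error(compute_scores(G[, 1:2], w), "absent")
})

test_that("PC features are excluded from scores unless requested", {
  G <- cbind(a = c(0, 2), PC1 = c(5, -5))
  rownames(G) <- c("s1", "s2")
  attr(G, "feature_type") <- c("snp", "pc")
  w <- make_weights(c("a", "PC1"), c(1, 1))
  expect_equal(compute_scores(G, w)$wPRS, c(0, 2))
  expect_equal(compute_scores(G, w, include_pcs = TRUE)$wPRS, c(5, -3))
})

test_that("wPRS is linear: cohort concatenation concatenates scores", {
  set.seed(2)
  G1 <- matrix(rbinom(20, 2, 0.3), 5, 4,
               dimnames = list(paste0("a", 1:5), paste0("f", 1:4)))
  G2 <- matrix(rbinom(16, 2, 0.3), 4, 4,
               dimnames = list(paste0("b", 1:4), paste0("f", 1:4)))
  w <- make_weights(paste0("f", 1:4), c(0.3, -0.1, 0, 0.7))
  both <- compute_scores(rbind(G1, G2), w)
  expect_equal(both$wPRS, c(compute_scores(G1, w)$wPRS,
                            compute_scores(G2, w)$wPRS))
})

test_that("Spearman associations match the definitional oracle and handle ties", {
  # hand-listed paired values with ties
  x <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7, 8, 8)
  y <- c(2, 1, 3, 3, 5, 4, 6, 5, 7, 9, 8, 8)
  names(x) <- rownames <- sprintf("s%02d", 1:12)
  out <- matrix(y, 12, 1, dimnames = list(names(x), "m"))
  res <- spearman_assoc(x, out)
  expect_equal(res$rho, oracle_spearman(x, y), tolerance = 1e-12)

  # monotone outcomes attain the +-1 boundaries
  z <- 1:12; names(z) <- names(x)
  mono <- matrix(cbind(z * 2 + 1, rev(z)), 12, 2,
                 dimnames = list(names(z), c("up", "down")))
  res2 <- spearman_assoc(z, mono)
  expect_equal(res2$rho, c(1, -1))
  expect_lt(res2$p[1], 1e-6)

  # constant outcome is flagged and leaves the family
  cst <- matrix(cbind(z, rep(1, 12)), 12, 2,
                dimnames = list(names(z), c("ok", "const")))
  res3 <- spearman_assoc(z, cst)
  expect_true(res3$flagged[2])
  expect_true(is.na(res3$p_adj[2]))
  expect_false(res3$flagged[1])
  expect_error(spearman_assoc(z[1:5], mono[1:5, ]), "paired observations")
})

test_that("Holm adjustment is monotone and never below raw p", {
  set.seed(4)
  sc <- rnorm(40); names(sc) <- sprintf("s%02d", 1:40)
  out <- matrix(rnorm(40 * 6), 40, 6,
                dimnames = list(names(sc), paste0("m", 1:6)))
  out[, 1] <- sc + rnorm(40, 0, 0.4)
  res <- spearman_assoc(sc, out)
  expect_true(all(res$p_adj >= res$p - 1e-15))
  ord <- order(res$p)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-15))
  expect_equal(res$p_adj, p.adjust(res$p, "holm"))
})

test_that("proportional-odds association recovers a planted odds ratio", {
  set.seed(5)
  n <- 2000
  score <- rnorm(n)
  covs <- data.frame(age_at_death = rnorm(n, 65, 8),
                     disease_duration = rexp(n, 1 / 3))
  y <- simulate_ordinal_outcomes(score, log_or = 0.69,
                                 covariates = scale(covs),
                                 covariate_log_or = c(0.2, -0.1), seed = 6)
  fit <- ordinal_assoc(score, y, covariates = covs)
  expect_gt(fit$or, 1.7)
  expect_lt(fit$or, 2.3)
  expect_lt(fit$p, 0.001)
  expect_true(fit$ci[1] < fit$or && fit$or < fit$ci[2])
})

test_that("proportional-odds association is unbiased under the null", {
  ors <- vapply(1:50, function(s) {
    set.seed(s)
    score <- rnorm(300)
    y <- simulate_ordinal_outcomes(score, log_or = 0, seed = s)
    ordinal_assoc(score, y)$or
  }, numeric(1))
  # mean log-OR within 3 Monte-Carlo SEs of 0
  lo <- log(ors)
  expect_lt(abs(mean(lo)), 3 * sd(lo) / sqrt(50))
})

test_that("ordinal association rejects degenerate outcomes", {
  expect_error(ordinal_assoc(rnorm(30), rep(1, 30)), "fewer than 2")
  expect_error(ordinal_assoc(rnorm(10), rep(c(0, 1), 5)), "at least 20")
})

test_that("sensitivity reruns compare weights and scores against the base run", {
  coh <- fx_cohort300()
  X <- truth_X(coh)
  Z <- coh$genotypes
  base <- bootstrap_scca(X, Z, 0.1, 0.6, B = 200, seed = 31)

  # identity rerun: same seed, nothing excluded -> identical wPRS
  expect_warning(same <- sensitivity_rerun(X, Z, coh$genotypes, base),
                 "identity")
  expect_equal(same$wprs_cor, 1, tolerance = 1e-12)
  expect_equal(same$sign_agreement, 1)

  # excluding a random 10% of subjects preserves weight signs
  drop_subj <- rownames(X)[seq(1, 30)]
  sub <- sensitivity_rerun(X, Z, coh$genotypes, base,
                           exclude_subjects = drop_subj)
  expect_gte(sub$sign_agreement, 0.9)
  expect_gt(sub$wprs_cor, 0.8)
})

test_that("dropping one member of each LD pair leaves the score stable", {
  cfg <- cohort_config(n_subjects = 300, seed = 91,
                       ld_blocks = list(list(snps = c(7, 8), r = 0.9),
                                        list(snps = c(22, 23), r = 0.9)))
  coh <- simulate_cohort(cfg)
  X <- truth_X(coh)
  Z <- coh$genotypes
  base <- bootstrap_scca(X, Z, 0.1, 0.6, B = 500, seed = 92)
  rerun <- sensitivity_rerun(X, Z, coh$genotypes, base,
                             exclude_features = c("snp08", "snp23"))
  expect_gte(rerun$wprs_cor, 0.8)
})
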