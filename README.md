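# sccaPRS

Machine-learning derivation of a polygenic risk score for cognitive
dysfunction in amyotrophic lateral sclerosis (ALS), for biostatisticians
and neurogenetics researchers working with longitudinal clinical cohorts
and candidate-variant panels.

A significant fraction of ALS patients develop cognitive impairment in the
domains shared with frontotemporal dementia, but no single variant
explains who.  `sccaPRS` asks the multivariate question: does a panel of
risk variants *collectively* track cognitive phenotype?  The pipeline:

1. **Adjusted trajectories.** Linear mixed-effects models (maximum
   likelihood) of 11 longitudinal measures — 8 ECAS scores, ALSFRS-R,
   UMN/LMN burden — with fixed effects for age, onset-to-baseline lag,
   college education, bulbar onset and visit month, and per-subject random
   intercepts and slopes.  Per-subject adjusted baseline = population
   intercept + predicted random intercept; adjusted decline rate =
   population month coefficient + predicted random slope.
2. **Sparse CCA.** With X the scaled adjusted baselines (subjects × 11)
   and Z the scaled genetic features (45 SNP dosages + sex + C9orf72 +
   other mutation + 2 PCs), solve

       max  uᵀXᵀZv   s.t.  ‖u‖₂ ≤ 1, ‖v‖₂ ≤ 1,
                            ‖u‖₁ ≤ t_x√11, ‖v‖₁ ≤ t_z√50

   by penalized matrix decomposition (alternating soft-thresholded
   updates); the canonical correlation ρ = cor(Xu, Zv).  Penalties come
   from a 10 × 10 grid search (t ∈ {0.1, …, 1.0}).
3. **Stability + null.** 10,000 sparse-CCA fits on random 75% subsamples
   give median ρ, median weights, and per-feature selection percentages;
   a permutation null (row-permuted datasets per iteration) gives the
   p-value of the observed median ρ.
4. **Scores + association.** wPRS_i = Σ_j dosage_ij · median-weight_j
   (uPRS: unweighted sum over selected features), then Spearman
   correlations with baselines and decline rates (Holm FWE) and
   proportional-odds regression against 0–3 ordinal neuropathology
   ratings.

Because the motivating cohorts are access-restricted, the package includes
a seeded synthetic-cohort generator with a planted sparse genetic signal
(ground truth for every downstream stage); see the vignette
`vignettes/polygenic-scca.Rmd` for the generative model and design
decisions.

## Worked example

```r
library(sccaPRS)

coh <- simulate_cohort(cohort_config(n_subjects = 300, seed = 1))
est <- fit_all_trajectories(coh$clinical, coh$covariates)
X   <- scale_intercepts(est)
Z   <- coh$genotypes[rownames(X), ]
attr(Z, "feature_type") <- attr(coh$genotypes, "feature_type")

g <- scca_grid_search(X, Z)
#> sCCA penalty grid: 100 cells; best rho = 0.6623 at (0.4, 0.7)

b <- bootstrap_scca(X, Z, 0.4, 0.7, B = 1000, seed = 2)
#> Bootstrapped sCCA (B = 1000, 75% subsamples): median rho = 0.671 [0.633, 0.710]
#>   most-selected clinical feature: ECAS_ALS_Specific (100.0%)

permutation_null(X, Z, 0.4, 0.7, B = 1000, seed = 3,
                 observed_rho = b$median_rho)
#> Permutation null (B = 1000): median null rho = 0.460
#>   observed median rho = 0.671, p = 0 (add-one 0.000999)

w  <- median_weights(b)
sc <- compute_scores(Z, w)
spearman_assoc(sc, trajectory_matrix(est, "slope")[,
               c("ECAS_ALS_Specific", "ECAS_Total", "ALSFRS_R")])
#>             outcome   n         rho            p        p_adj flagged
#> 1 ECAS_ALS_Specific 247 -0.31170346 5.761178e-07 1.728353e-06   FALSE
#> 2        ECAS_Total 247 -0.26251844 2.935798e-05 5.871597e-05   FALSE
#> 3          ALSFRS_R 247 -0.04098036 5.214842e-01 5.214842e-01   FALSE
```

Reading the output: the grid picks moderate sparsity; the bootstrapped
median canonical correlation (0.67) clearly exceeds the permutation null
(median 0.46, p ≈ 0), and the most-selected clinical feature is the
ECAS ALS-Specific score — the cognitive domain composite.  The derived
wPRS correlates with the adjusted rate of *cognitive* decline (ρ = −0.31
and −0.26, Holm-significant: higher risk score, faster decline) but not
with motor decline (ALSFRS-R, ρ = −0.04, p = 0.52) — the
cognition-specific polygenic pattern the pipeline is designed to detect.
Against the generator's ground truth, the median weights rank-recover the
planted support (Spearman of |weights|: 0.65).

`run_pipeline(pipeline_config(...), outdir)` executes all stages
(simulate → trajectories → scale → grid → bootstrap → null → score →
associate) and writes per-stage TSV/JSON artifacts plus a manifest with
the config hash and per-file checksums; identical config + seed
reproduces every checksum.

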