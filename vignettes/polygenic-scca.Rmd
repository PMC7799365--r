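---
title: "Deriving a polygenic risk score for cognitive decline in ALS with sparse canonical correlation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a polygenic risk score for cognitive decline in ALS with sparse canonical correlation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccaPRS)
```

## The problem

Cognitive dysfunction affects a substantial fraction of people with
amyotrophic lateral sclerosis (ALS) and marks a worse prognosis, yet which
patients develop it is poorly predicted by any single genetic variant.
`sccaPRS` implements a pipeline for asking whether a *panel* of common risk
variants — SNP dosages coded additively (0/1/2 minor-allele copies),
together with sex, C9orf72 repeat-expansion status, other-mutation status,
and two ancestry principal components — collectively tracks cognitive
phenotype in a longitudinal cohort, and for distilling that multivariate
association into a transferable weighted polygenic risk score (wPRS).

The pipeline has four statistical stages, each exposed as ordinary R
functions and orchestrated by `run_pipeline()`:

1. **Trajectory adjustment.** Each of 11 clinical measures — eight ECAS
   scores (Total, ALS-Specific, ALS-Non-Specific, Executive, Language,
   Verbal Fluency, Memory, Visuospatial), the ALSFRS-R, and UMN/LMN burden
   scores — is modeled longitudinally with a linear mixed-effects model
   (maximum likelihood): fixed effects for age at baseline, onset-to-baseline
   lag, college education, bulbar onset and visit month; a per-subject
   random intercept and random slope on visit month.  The per-subject
   *adjusted baseline* is the population intercept plus the subject's
   predicted (BLUP) random intercept, and the *adjusted rate of decline* is
   the population month coefficient plus the predicted random slope.
2. **Sparse canonical correlation.**  With $X$ the column-scaled matrix of
   adjusted baselines (subjects × 11) and $Z$ the column-scaled genetic
   feature matrix (subjects × 50), the solver maximizes
   $u^{\top} X^{\top} Z v$ subject to $\lVert u\rVert_2 \le 1$,
   $\lVert v\rVert_2 \le 1$, $\lVert u\rVert_1 \le t_x\sqrt{11}$,
   $\lVert v\rVert_1 \le t_z\sqrt{50}$ — the penalized matrix
   decomposition, solved by alternating soft-thresholded updates.  The
   reported canonical correlation $\rho$ is the Pearson correlation of the
   fitted composites $Xu$ and $Zv$.  Penalties $t_x, t_z \in (0,1]$ are
   chosen by a 10 × 10 grid search (0.1–1.0 in steps of 0.1, 100 fits)
   maximizing $\rho$ of the first variate.
3. **Stability and calibration.**  At the chosen penalties the fit is
   repeated 10,000 times on random 75% subsamples; the *median* canonical
   correlation, median per-feature weights, and per-feature selection
   percentages (fraction of iterations with a non-zero weight) summarize
   the bootstrap.  A permutation null repeats the same procedure with the
   X–Z linkage destroyed, yielding a null distribution of canonical
   correlations and the p-value of the observed median.
4. **Scoring and association.**  The wPRS multiplies each subject's raw
   dosage/binary coding at every genetic feature by that feature's median
   canonical weight and sums; the unweighted uPRS sums raw dosages over
   selected features.  Association stages: tie-corrected Spearman
   correlations with adjusted baselines and rates of decline (Holm
   family-wise correction), and a proportional-odds model for ordinal
   neuropathology ratings (0–3) with age-at-death and disease-duration
   adjustment.

## A worked run on a synthetic cohort

Real cohorts of this kind are access-restricted, so the package ships a
seeded generator whose defaults emulate the discovery study's conditions:
327 subjects, a 45-SNP panel under Hardy–Weinberg equilibrium, visits at
0/3/6/12/18 months, monotone attrition leaving 84.7% of subjects with two
or more visits, and a planted sparse weight vector (support 10 of 50) whose
latent liability drives cognitive — but not motor — baselines and slopes.

```{r smallrun, eval = FALSE}
cfg <- pipeline_config(cohort = cohort_config(n_subjects = 300, seed = 1),
                       B = 1000L, seed = 2L)
manifest <- run_pipeline(cfg, "run1")
```

Every stage writes TSV/JSON artifacts plus a manifest carrying the config
hash, seed and per-file checksums; identical config + seed reproduces every
checksum bit for bit.

## The synthetic cohort: what it does and does not emulate

The generator draws SNP dosages as Binomial(2, MAF) — Hardy–Weinberg
equilibrium with independent loci.  Linkage disequilibrium is *not*
emulated by default; an optional Gaussian-copula block mode
(`ld_blocks`) induces correlated dosages for the LD-pruning sensitivity
rerun.  Binary covariates are Bernoulli (sex 0.5, C9orf72 0.09, other
mutation 0.04) and the two PC placeholders standard normal.

Phenotypes follow an explicit variance partition.  For measure $m$ with
baseline SD $\sigma_m$, the true (pre-noise) baseline in SD units is

$$ -\sqrt{s_m}\,L \;+\; \sqrt{c_m}\,g_{d(m)} \;+\; \sqrt{1-s_m-c_m}\,\varepsilon, $$

where $L$ is the unit-variance planted liability (standardized genetic
features times the planted weights), $s_m$ the genetic signal fraction
(default 0.30 for ECAS ALS-Specific, tapering to 0.05 for Visuospatial,
0 for the motor measures), and $g_{d(m)}$ a shared non-genetic *domain
factor* — one for the cognitive measures ($c_m = 0.45$), an independent
one for the motor measures ($c_m = 0.50$).  The domain factors matter:
real clinical batteries are strongly collinear (the ECAS Total literally
aggregates its subscores; overall disease severity drives all motor
scores), and that collinearity is what makes a *sparse* clinical penalty
optimal — the solver maximizes composite covariance while $\rho$ is a
correlation, so dense composites over collinear columns inflate the
composite variance and depress $\rho$.  Without the domain factors the
penalty grid degenerates to dense clinical weights and the selection
percentages stop being informative.  The negative sign on $L$ encodes risk
orientation: higher genetic liability, worse cognition.  Rates of decline
share the liability with attenuation 0.6.  If the planted weights are all
zero the liability is degenerate and its variance share collapses into the
idiosyncratic term, keeping null-cohort columns unit-variance and
exchangeable within domain.

Observed values are truth plus i.i.d. Gaussian visit noise
(0.25 $\sigma_m$, consistent with the high short-term test–retest
stability of these instruments), clipped to instrument bounds (the clipped
fraction is recorded), under monotone attrition: the baseline visit is
always observed and a subject permanently drops out at each later visit
with probability 0.153, so 84.7% retain ≥ 2 visits.  The generator does
not emulate: alternate ECAS forms, site effects, non-linear trajectories,
informative dropout (attrition is independent of trajectory), realistic
allele-frequency spectra, or imaging/autopsy sampling.  Passing tests
therefore demonstrate that the machinery recovers structure *of this
generative class*, not that the biological findings replicate.

## Numerical and design choices

* **L1 budgets.**  A penalty $t$ maps to the budget $t\sqrt{\dim}$,
  clamped to $[1, \sqrt{\dim}]$ (a unit-L2 vector always has L1 ≥ 1).
  At the clamp floor exactly one coordinate is active; exact ties in
  $|a_i|$ are broken toward the lowest index.  The budget bisection runs
  to an L1 tolerance of 1e-8.
* **Initialization.**  The genetic weight vector starts at the leading
  right singular vector of $X^{\top}Z$, computed by power iteration from a
  fixed uniform start — deterministic, no random restarts.
* **Sign orientation.**  Each fit flips $(u, v)$ jointly so that
  $\sum_i u_i \le 0$ (the flip leaves $\rho$ unchanged).  Without a fixed
  orientation, medians across bootstrap iterations would be meaningless;
  the chosen convention makes a higher genetic composite accompany worse
  clinical scores, so the wPRS reads as risk.
* **Covariate centering.**  Covariate fixed effects are mean-centered
  inside each mixed model, so the adjusted baseline refers to a subject
  with cohort-average covariates and is exactly invariant to constant
  shifts of any covariate column.  (With uncentered covariates the
  population intercept — and hence every "adjusted" estimate — would move
  whenever a covariate were re-expressed.)
* **Subsampling.**  "Bootstrap" subsamples are 75% of subjects drawn
  *without* replacement (distinct subjects), matching the stabilization
  design; a classical with-replacement mode sits behind
  `replace = TRUE`.  Columns constant within a subsample are zeroed —
  they carry no information there — rather than aborting the iteration.
* **Permutation scheme.**  Two nulls are provided.  The default,
  `permute = "rows"`, applies one independent whole-row permutation to
  each dataset per iteration: it breaks the X–Z linkage while preserving
  each dataset's internal correlation structure, which is the appropriate
  null for the cross-dataset association and is the default for the
  reported p-value.  `permute = "columns"` additionally shuffles every
  column independently, flattening within-dataset structure the way
  community-matrix randomization routines do.  The distinction is not
  cosmetic: under the row scheme, winner-take-all selection on collinear
  clinical data concentrates in the larger correlated block, so null
  selection percentages are *not* evenly spread; only under the column
  scheme are same-distribution features exchangeable and selection even
  (≈ 100/11% each).  Even spread across all 11 measures in a reported
  null is thus a signature of a structure-flattening scheme.
* **p-value.**  $p = \#\{\rho_{\mathrm{null}} \ge
  \tilde{\rho}_{\mathrm{obs}}\}/B$ (primary), with the never-zero variant
  $(b+1)/(B+1)$ reported alongside.  Because the observed statistic is a
  *median* over subsample fits while the null distribution holds
  single-iteration fits, the p-value is mildly conservative rather than
  exactly uniform under the null; on planted-null cohorts with the default
  collinear generator it is close to uniform (the test suite checks both
  calibration and type-I control).
* **Medians everywhere.**  Bootstrap summaries use medians and percentile
  intervals, not means, to resist outlying iterations.
* **Scores.**  PC features are adjustment variables inside the sCCA but
  are excluded from the wPRS/uPRS by default (`include_pcs_in_scores`),
  because discovery-cohort PC axes do not exist in external cohorts.
  Slope associations are restricted to subjects with ≥ 2 observations.
  The family-wise correction is Holm step-down (uniformly at least as
  powerful as Bonferroni while controlling FWE); ordinal associations are
  reported per region, uncorrected, and flagged as such.
* **Dosage orientation.**  The SNP panel file, not the VCF, determines
  which allele is counted: when the panel's effect allele is the VCF ALT allele
  the ALT count is used, when it is REF the dosage is 2 − ALT count, and
  anything else is a hard error naming the site.

## Problem sizes used in validation

The shipped validation suite works at deliberately modest sizes chosen as
representative of the method's operating regime: cohorts of 300 subjects
for recovery and calibration experiments (50 replicate null cohorts with
B = 500 for the permutation calibration; 20 seeds for the wPRS-vs-uPRS
contrast), the full 45 × 11 = 495-model univariate scan on one null
cohort, and B = 10,000 for the end-to-end acceptance run.  Monte-Carlo
checks state their tolerance in simulation standard errors.

## Known limitations

Only the first canonical variate pair is computed (no deflation), matching
the single-variate design; there is no cross-validated penalty selection,
no REML option, no fused/ordered penalties, and no PLINK binary reader.
The permutation p-value inherits the conservativeness noted above.  The
proportional-odds stage assumes proportional odds across rating
thresholds and falls back to a profile-likelihood interval only when
quasi-separation inflates the Wald standard error.
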