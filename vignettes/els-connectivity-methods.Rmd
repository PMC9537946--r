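---
title: "Methods: early-life stress and resting-state network connectivity"
author: "elsconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early-life stress and resting-state network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elsconn)
```

# The scientific problem

Early-life stress (ELS) — adversity experienced in pregnancy, infancy or
childhood — is thought to leave lasting traces in the brain's resting-state
functional architecture, particularly in the default mode network (DMN) and
the fronto-limbic network (FLN). Two operationalizations of ELS coexist and
correlate only weakly with one another: *prospective* scores built from
parent questionnaires collected while the child grows up, and
*retrospective* scores from the grown participant's own recall of adverse
childhood experiences. `elsconn` implements a complete analysis chain for
asking whether either kind of ELS score is associated with resting-state
connectivity, at three resolutions: the network's mean connectivity, single
named edges, and the full multivariate connectivity profile.

# Risk scores

**Prospective cumulative risk.** The battery holds 20 variables: BDI and
GHQ (parental depression / general mental health) for both parents at three
timepoints, and DAS and PSI (relationship and parenting stress) for both
parents at two timepoints. Scoring follows the cumulative-risk convention:
each instrument is averaged over timepoints, then over the two parents,
z-standardized across participants, and the four standardized instrument
scores are averaged. The composite mean is exactly zero by construction.
Standardization uses the sample (n−1) SD — the usual questionnaire
convention; at the package's cohort sizes the distinction from the
population SD is negligible, but it is fixed and documented because the
composite's scale depends on it.

**Missing data.** Participants missing more than 8 of the 20 variables are
excluded (the battery's eligibility rule). Remaining gaps are filled by
single-imputation EM under a multivariate normal model: the E-step computes
conditional means and second moments of missing cells given observed ones,
the M-step re-estimates the mean vector and covariance, and iteration stops
when no parameter moves by more than `tol` (default 1e-6, `max_iter` 500, a
1e-8 ridge on the covariance diagonal). Two caveats matter. First, ML
estimation of a 20 × 20 covariance needs far more rows than columns: our
oracle comparison against column-mean imputation is run at n = 300, where
EM wins on every seed (RMSE ratio ≤ 0.91); at n ≈ 60 plain EM can overfit
and do worse. Designs of the kind emulated here typically impute from a
much larger parent cohort for exactly this reason; this package estimates
EM parameters from the analysis sample, which is the honest option when no
larger sample is available. Second, EM is a projection: re-running it on a
completed matrix changes nothing.

**Retrospective score.** Twelve adverse-childhood-experience domains: five
assessed by two items on a 0/1/2 never/sometimes/often scale (domain =
item mean), seven by a single binary item scored 0/2. The total is the sum
of the 12 domain scores, ranging 0–24, and is monotone nondecreasing in
every item.

# Connectivity

Each participant contributes a volumes × 12 matrix of preprocessed ROI-mean
BOLD signals (parcellation and denoising are upstream of this package; no
detrending or filtering is applied here). The package ships two 12-ROI
bilateral network definitions — DMN (PCC, mPFC, IPC, MTG, DLPFC,
hippocampus) and FLN (OFC, mPFC, ACC, amygdala, accumbens, hippocampus) —
with atlas parcel lists carried as metadata only. Pearson correlation of
every ROI pair gives a 12 × 12 connectivity matrix; its row-major upper
triangle, in the fixed packaged ROI order (left before right within each
region), is the participant's 66-edge connectivity profile. The fixed edge
order is the alignment contract that makes profiles comparable across
participants. Mean connectivity averages raw r by default; Fisher-z
averaging is available behind a flag, and raw r is the default everywhere
for internal consistency. Participants with mean framewise displacement
above 0.2 mm (strict inequality) are excluded before any analysis.

# Inter-subject representational similarity analysis

The connectivity RDM (representational dissimilarity matrix) has entries
1 − r(profile~a~, profile~b~); model RDMs are absolute score differences
|s~a~ − s~b~|. The IS-RSA statistic is the partial correlation of the two
vectorized upper triangles given the covariate RDM vectors (sex, ART,
mother's age, mother's SES), computed by residualizing both on the
covariates and correlating residuals. Rank (Spearman) correlation is the
default, as is standard in RSA where only the ordinal structure of
dissimilarities is trusted; Pearson is available. Inference is a
Mantel-style permutation test: rows and columns of the model RDM are
permuted jointly (equivalent to permuting the underlying scores and
rebuilding), covariate RDMs stay fixed so their structure is preserved
under the null, and the two-tailed p is `(1 + #{|r*| ≥ |r|})/(1 + n_perm)`
(default `n_perm` = 10,000). Because raw correlations are outlier-sensitive,
participants more than 2 SD from the mean (single pass) on the screening
variable are removed listwise before RDM construction; the screening
variable is the network's mean connectivity for mean-level analyses and
the participant's mean RDM row dissimilarity for IS-RSA, both configurable
since different choices are defensible.

# Multivariate distance matrix regression

MDMR regresses the Gower-centered matrix `G = −½ J D² J` on a design of
predictors and covariates. With `H` the full-design hat matrix and
`H_j = H − H_(−j)` the increment of term j, the package reports per term

* statistic = `tr(H_j G) / tr((I − H) G)`,
* pseudo-R² = `tr(H_j G) / tr(G)`,

and an omnibus row using `H − H₀` (intercept-only `H₀`). These trace
definitions were chosen because they satisfy the internal identity
pseudo-R²/statistic = 1 − omnibus pseudo-R² for every term, which published
MDMR tables of this form obey — the identity pins down the statistic
variant among the several in the literature, and the test suite asserts it
to 1e-12 on every fit. For a one-dimensional response the machinery
collapses to OLS: `G = ỹỹᵀ`, so the statistic is exactly SSR/SSE (another
asserted oracle). p-values use Freedman–Lane residual permutation — permute
the reduced-model-residualized `G`, recompute the term statistic — with
5,000 permutations by default. Covariates are tested exactly like
predictors of interest, one row each. Every term's test permutes only its
own reduced model, so term order is irrelevant; multiplying all distances
by c > 0 leaves all statistics and p-values unchanged.

# Univariate and edge-level inference

* **Spearman / partial correlations** of each ELS score with mean
  connectivity; partial correlations residualize on the covariates; p from
  the t approximation.
* **Steiger's test** compares the two dependent correlations (prospective
  vs retrospective, sharing the connectivity variable) via Fisher z and the
  pooled-r̄ asymptotic covariance.
* **Edge regressions**: OLS of a named edge (the OFC– and mPFC–amygdala
  edges in the packaged analysis) on an ELS score plus covariates. Cohen's
  d is reported as t/√n: among the standard conversions this is the one
  consistent with published triples of (t, n, d) for this analysis family
  (e.g. t = 3.00, n = 86 → d = 0.32); note t(86)-style labels in that
  literature print n, not the residual df, and the package keeps both. The
  16-test family (4 edges × 2 hemispheres × 2 ELS scores) is corrected with
  Benjamini–Hochberg FDR — `bh_fdr()` wraps `stats::p.adjust(method =
  "BH")`.
* **Extreme-group contrasts**: ⌊fraction·N⌋ participants per tail (ties at
  the boundary all included, so groups may be unequal), Welch t per edge,
  BH across the 66 edges, edges ranked by raw p — the table behind
  circulograph-style figures.

# The synthetic cohort generator

No individual-level data of this kind are public, so the package carries a
first-class generator whose defaults are the study conditions the analyses
are tested under. Latent prospective and retrospective ELS are bivariate
standard normal with correlation 0.2 (configurable), reflecting the poor
convergence typically reported between the two operationalizations.
Questionnaire variables load on the prospective latent with a common
standardized loading of 0.574, tuned once so the 20-variable Cronbach's
alpha is ≈ 0.88; instrument-specific location/scale make the columns look
like raw BDI/GHQ/DAS/PSI scores (all problem-scored: higher = more
adversity; the composite is invariant to these affine choices).
Retrospective items follow ordered-logit (0/1/2) and logit (0/2) models
with slope 0.5 on the retrospective latent and intercepts set so the
domain-sum total has mean ≈ 4.4 and SD ≈ 2.7 in an unselected cohort —
near the descriptives such questionnaires typically yield. Block
missingness removes one whole instrument with probability 8/92, item-level
MCAR runs at 0.004, and mean framewise displacement is lognormal, rescaled
so that round(6/92 · n) participants exceed the 0.2 mm cut-off exactly.

Time series are zero-mean multivariate normal over 150 volumes (TR 2.5 s)
with participant-specific covariance

```
Sigma_i = clip_pd(Sigma0 + beta_mean * z_retro_i * U + beta_pattern * z_prosp_i * P)
```

where `Sigma0` is a fixed block covariance (unit diagonal, 0.45 for
homologous left/right pairs, 0.25 within the three densely coupled
regions, 0.10 elsewhere), `U` is the all-off-diagonal unit pattern (a
mean-connectivity effect), and `P` is a fixed zero-trace symmetric pattern
with mean-zero, unit-RMS off-diagonal entries (a profile-shape effect that
leaves mean connectivity nearly untouched — this is what separates the two
planted effects). `P` is built from an internal constant seed, so it is
identical across runs and independent of the user's seed. Eigenvalue
clipping at 1e-6 is the smallest repair that restores positive
definiteness while preserving the perturbation direction. The monotone map
applied to the latent before scaling `P` is the identity — nothing in the
tested behaviour depends on its curvature, only on monotonicity.

What the generator does *not* emulate: hemodynamics, temporal
autocorrelation (an optional AR(1) exists but is off by default),
site/scanner effects, non-Gaussian BOLD marginals, and any true coupling
between motion and connectivity. Passing tests therefore show that the
*statistical machinery* is correct and calibrated, not that the pipeline
is robust to every artifact of real resting-state data.

**Calibrated conditions.** A pre-build pilot fixed the "moderate" planted
effects used by the power checks, then froze them: `beta_mean = 0.03`
(univariate Spearman rho ≈ 0.45 at n = 86) and `beta_pattern = 0.03`
(IS-RSA partial r ≈ 0.40 at n = 86). Both give ≥ 80% detection over 100
replicates; the observed effect sizes are of the order such studies
report. Null calibration (all betas 0) checks that IS-RSA, MDMR and
edge-contrast type-I error at α = 0.05 stays inside the exact binomial 95%
interval over 200 replicates at n = 50 with 499 permutations; the
edge-contrast check uses one pre-specified edge per replicate because the
66 within-replicate p-values are correlated.

# Numerical and design choices

* **Determinism.** Every stochastic routine requires a seed and refuses to
  run without one. The pipeline derives independent per-stage substreams
  from one master seed via a string hash, so disabling one analysis does
  not shift another's random numbers; identical configs give byte-identical
  output files (matrices are written at 17 significant digits for exact
  round trips, result tables at 10).
* **Outlier screening before vs after RDM construction.** Outliers are
  removed listwise before building any RDM in an analysis, the simpler and
  more conservative of the two defensible orders.
* **Degenerate inputs.** Constant ROI signals, constant profiles,
  zero-variance scores, rank-deficient designs and collinear covariate
  RDMs are hard errors naming the offender; a zero-variance outlier screen
  warns and flags nothing; an edge with zero variance in both contrast
  groups gets p = 1 with a warning.
* **Problem sizes in the test suite.** Simulated checks use n = 25–92
  participants, 60–150 volumes, 99–999 permutations; the two oracle
  equivalences that need precision (OLS ≡ MDMR, 9,999 permutations) and
  the calibration suites (200 null replicates, 100 power replicates) are
  the sizes a desk-scale replication of this design would use.

# Known limitations

EM parameters come from the analysis sample (see above). Permutation
schemes for IS-RSA (model-RDM label permutation with fixed covariates) and
MDMR (Freedman–Lane) are stated choices among defensible alternatives; the
packaged defaults follow the respective literatures. The IS-RSA correlation
method (Spearman) and the FDR family (the 16 edge regressions, BH) are
configurable because the emulated design leaves them ambiguous. The
generator's distributional choices are its own; nothing here claims to
reproduce any particular cohort's data-generating process.
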