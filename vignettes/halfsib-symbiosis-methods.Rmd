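---
title: "Methods: quantitative genetics of half-sib symbiosis trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative genetics of half-sib symbiosis trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizoQG)
```

## The problem

Nitrogen fixation through the legume–*Rhizobium* symbiosis is a
quantitative trait of the host plant: families differ in how much biomass
they build when their only nitrogen source is fixation. A breeding
programme needs the additive genetic variance of such symbiotic traits,
their heritability, how they are genetically correlated, and the gain a
given selection scheme would deliver. `rhizoQG` implements that analysis
for the standard screening design: half-sib families grown in replicated
controlled-environment rooms, one arm inoculated with a *Rhizobium*
strain (`TA1`), one arm fed mineral N (`NPLUS`, the positive control),
and a bulked, unlabelled negative control (`NEG`) that measures growth
from seed reserves alone.

## Traits

Shoot and root dry matter (mg per plant) are measured; the root:shoot
ratio (RSR) is the per-plant quotient, and the plot-level RSR is the
*mean of per-plant ratios*, not the ratio of plot means — the two differ,
and the per-plant mean is what a per-plant quotient trait aggregates to.
Symbiotic potential (SP) expresses inoculated growth as a percent of
N-fed growth after removing the seed-reserve baseline:

$$\mathrm{SP\%} = 100\,\frac{\mathrm{DM}_{\text{inoculated}} -
\overline{\mathrm{DM}}_{\text{uninoculated}}}
{\overline{\mathrm{DM}}_{\text{N-fed}} -
\overline{\mathrm{DM}}_{\text{uninoculated}}}.$$

The N-fed mean is family-specific (each family is compared with its own
genetics under mineral N); the uninoculated mean is global because the
negative control is a family bulk without labels. SP is computed per
plant and averaged over the quadrant; because the transform is affine in
the plant's dry matter this equals applying the definition to the plot
mean, and both bases are exposed (`sp_basis`) so the choice is explicit.
SP may legitimately be negative (plant below the seed-reserve baseline)
or exceed 100% (root growth under symbiosis can beat the N-fed control);
no truncation is applied.

## The trial model and its REML fit

The analysis unit is the family × replicate quadrant (plot) mean. Plot
values follow a purely random linear model — intercept plus family,
replicate (growth room), family × replicate interaction, and row and
column effects nested within replicate, plus a plot residual, each drawn
from a zero-mean normal with its own variance. Replicates are kept random
(treating them as fixed changes nothing material in a two-room design);
sub-plot terms are not modelled at all, reflecting the common finding
that quadrant-level structure contributes nothing once rows and columns
are in the model.

**Identifiability at plot scale.** With one plot per family × replicate
cell, the interaction's design matrix is the identity: it is confounded
with the plot residual. `fit_reml()` detects any random term with one
observation per level, drops it with a warning, and the residual then
estimates the *sum* σ²_fR + σ²_ε. Every downstream quantity that the
package computes from a fit — heritability, the among-family phenotypic
SD, gains — depends on the interaction and residual only through
(σ²_fR + σ²_ε)/n_R, so nothing is lost. When both components are known
separately (e.g. from a published table) they can be supplied directly to
`narrow_sense_heritability()` and `family_phenotypic_sd()`.

**Optimiser.** The restricted likelihood is maximised by a short
expectation-maximisation warm start (10 updates) followed by Newton-type
Fisher-scoring steps on log-variances with step halving, stopping when
the realised step is below 1e-7 on the log scale or the relative change
in restricted log-likelihood falls below 1e-8 (maximum 200 iterations).
The log parameterisation keeps components positive; a component is pinned
to exactly zero when it falls below 0.5% of the phenotypic variance *and*
the profile likelihood without it is within 1e-4 of the full optimum —
threshold-only pinning can strand genuinely tiny components, so the
profile check arbitrates. Standard errors come from the inverse expected
(Fisher) information at the optimum, the standard choice in
average-information REML implementations; pinned components report no SE.
Significance is a one-sided Wald test at α = 0.05 by default (a variance
is a one-sided hypothesis); a 50:50 χ²₀/χ²₁ mixture likelihood-ratio test
is available via `sig_method = "lrt"`. On balanced designs the optimum
matches the closed-form ANOVA estimators to better than 1e-6 relative,
and fits agree with `lme4::lmer` on simulated trials (both are exercised
in the test suite).

BLUPs solve the mixed-model equations at the estimated components;
family BLUPs shrink raw family-mean deviations towards zero and sum to
zero, and `mu + BLUP` gives the adjusted family means used everywhere
downstream.

## Heritability, correlations

Narrow-sense heritability on a half-sib family-mean basis is
σ²_f / (σ²_f + σ²_fR/n_R + σ²_ε/n_R). In a half-sib structure the family
variance already equals ¼ of the total additive variance, so no ×4
rescaling is applied — the same convention makes the gain equation below
use σ²_f directly. The delta-method SE reported by
`heritability_from_fit()` treats the family and residual information as
independent; it is an approximation and is not validated against any
published value.

Additive covariance between traits uses the variance-of-sums identity,
cov_A(X,Y) = (σ²_f(X+Y) − σ²_f(X) − σ²_f(Y))/2, from three univariate
REML fits (traits are rescaled to unit phenotypic SD before summing, for
numerical balance only). At balanced designs this equals the direct
cross-product (MANOVA-style) estimator, which the tests verify; it keeps
the engine univariate. Correlations r_A = cov_A/√(σ²_f(X)σ²_f(Y)) that
overshoot [−1, 1] are clamped and flagged rather than rejected — REML
correlation ratios overshoot routinely in small samples (see
*Limitations*). Phenotypic correlations are plain Pearson correlations of
the BLUP-adjusted family means with two-sided t-test p-values and no
multiplicity adjustment.

## Selection toolkit

Selection intensity uses the infinite-population truncation formula
k = φ(z)/p; at 5/10/20% pressure this gives 2.063, 1.755, 1.400, matching
the classical breeders' table (whose 10% entry prints as 1.76 by half-up
rounding of 1.755). No finite-population correction is applied — with 120
families the correction is below the precision anything downstream uses.
Predicted gain per cycle of among-half-sib-family selection is
ΔG = k c σ²_f / σ_PF with parental control c = 0.5 (only the maternal
parent is selected) and σ_PF = √(σ²_f + σ²_fR/n_R + σ²_ε/n_R). The
Smith-Hazel index solves P b = A w with P assembled from among-family
phenotypic (co)variances (family plus interaction-and-residual
(co)variances shrunk by n_R) and A from the additive (co)variances; the
solve is verified to 1e-8 relative residual. Weights default to (1, 1),
the equal-emphasis (desired-gain) choice for a two-trait ideotype.
Correlated response is CR_Y = k c h_X h_Y r_A σ_PY, signed by r_A.
Ranking ties are broken by family ID so selections are deterministic;
`select_top()` keeps ⌈p·n⌉ families.

## Pattern analysis

Families (or family × treatment entries) are clustered on their
standardised BLUP profiles — standardisation is necessary because the
traits mix mg, percent and ratios — using squared Euclidean dissimilarity
with Ward's minimum-variance linkage, its natural companion (the linkage
itself is not prescribed by the source methodology; Ward is this
package's choice). The number of groups comes from the Hartigan rule:
the smallest k with H(k) = (n−k−1)(W_k/W_{k+1} − 1) ≤ 10. PCA biplot
coordinates come from the correlation-matrix decomposition (standardised
columns); variance proportions are eigenvalue shares and sum to one.

The Hartigan threshold-10 rule deserves a caveat: because of the
(n−k−1) factor, H grows linearly with n at a fixed scatter ratio, and
splitting even a single spherical Gaussian reduces within-group scatter
by roughly 30%, so for n ≳ 50 the rule essentially always asks for more
groups. The canonical behaviours — k = 2 for two separated blobs, k = 1
for one Gaussian — therefore hold at modest sample sizes (the tests use
10 points per cloud), and on large BLUP matrices the rule should be read
as an upper-bound heuristic, with `threshold` configurable.

## The simulator and what passing tests mean

`simulation_config()` defaults describe the trial the package is built
around: 120 half-sib families × 2 growth rooms, 16 plants per quadrant,
30 four-quadrant containers per replicate per arm, treatment means 11.4
(shoot) and 5.03 (root) mg under inoculation, 25.1 and 9.00 mg under
mineral N, and plot-scale variance components (family / interaction /
residual) of 13.5/4.7/49.6 (shoot, inoculated), 2.2/0.9/10.2 (root,
inoculated), 23.3/23.6/220.6 and 3.4/2.6/30.7 (mineral-N arm). Replicate,
row and column variances are not published for this design; they are set
once to small room/spatial effects (1.0/0.5/0.5 mg² on the shoot scale,
proportionally smaller for root). The negative-control bulk is drawn
without family structure at 2.15/1.59 mg with 0.5/0.4 mg SD (four
containers per replicate). Family effects are *shared genetics*: one
underlying standard-normal score per family and organ, with shoot and
root scores correlated at 0.97 by default, scaled by each arm's family
SD — so the same families excel in both arms and both organs.
Missingness is completely at random with default rate 0 (no plant-loss
process is modelled). Variances are specified at the plot-mean scale; an
optional plant-level residual (`plant_sd`) can be layered on top and is
averaged back into quadrant means, and defaults to zero so that the
configured components are exactly the plot-scale truth.

What the simulator does *not* emulate: positivity of dry matter (a
Gaussian with the realistic residual occasionally dips below zero —
such plants are excluded from RSR with a warning), lognormal-like
skew of biomass, spatial autocorrelation beyond additive row/column
effects, germination failure, or any plant × strain interaction
structure. Passing recovery tests therefore demonstrate that the
estimators recover the parameters of the stated Gaussian world, not that
real trials satisfy it.

**Problem sizes in the tests.** The recovery suite uses 200 simulated
120-family × 2-replicate trials at the shoot components above (family
variance and heritability recovered within 2 Monte-Carlo SEs), and 200
seeds per truth for genetic-correlation recovery at r_A ∈ {0, 0.62,
0.97}. For the correlation recovery the simulated plot residual is set
to 1: the correlation estimator is a *ratio* with estimated family
variances in the denominator, and when those variances are poorly
identified — exactly the situation at the realistic noise level, where
the root family variance (2.2) carries an SE near 1.3 — the ratio is
biased far from the truth (pilot runs: mean estimate ≈ 1.15 at truth
0.97). In the near-noiseless regime the estimator's error is dominated by
the sampling of the 120 family effects themselves and recovery is clean;
the bias under realistic noise is a property of REML correlation ratios
at this design size, and is the reason estimated correlation matrices
expose clamping flags rather than silently truncating.

## Numerical and degenerate-input conventions

Zero-variance responses return all-zero components with the mean as
intercept. Single-level terms (one growth room) and residual-confounded
terms are dropped with warnings. A singular total covariance raises an
error naming the condition; a non-converged fit raises an error rather
than returning estimates. Index ranking and top-fraction selection break
ties by family ID with a warning when the cut falls inside a tie.
Constant trait columns are excluded from PCA and flagged as undefined in
correlation matrices.

## Limitations

* Genetic-correlation SEs are not provided (none are defined for the
  sum-trick estimator here), and correlation estimates at realistic
  noise are usable as descriptions, not precise estimands — see above.
* The heritability SE is a rough delta-method approximation.
* The pipeline analyses each treatment arm separately; no cross-arm
  mixed model is fitted.
* Multi-cycle selection, economic weighting models and genomic selection
  are out of scope.
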