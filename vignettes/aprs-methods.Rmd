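---
title: "Methods: ancestry-adjusted polygenic risk scores at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestry-adjusted polygenic risk scores at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Polygenic risk scores (PRS) are weighted sums of risk-allele dosages whose
weights come from genome-wide association studies performed, for the most
part, in European-ancestry cohorts. Applied to a cohort of a different
ancestry the raw score distribution is shifted: allele frequencies differ
between populations, and when per-variant weights are even slightly
correlated with those frequency differences the shifts accumulate over
thousands of variants. A percentile threshold computed on the pooled cohort
then assigns "high risk" almost entirely by ancestry rather than by
within-population risk. The standard remedy is an ancestry-adjusted score
(aPRS): regress the standardized PRS on the leading principal components of
the genotype matrix and standardize the residual,

    aPRS = standardize( PRS - (b0 + b1 PC1 + b2 PC2 + b3 PC3 + b4 PC4) ).

This package implements that pipeline end to end — scoring-file parsing and
harmonization, PRS computation, reference-panel PCA and projection, PC
residualization, percentile and family-history stratification, logistic and
Cox association models, discrimination evaluation — together with a
synthetic two-population cohort generator that gives every stage data with
the statistical structure the analysis assumes. Real biobank genotypes are
access-restricted; the generator makes the whole analysis reproducible at
desk scale, and parameter-recovery checks take the place of re-deriving
published effect estimates.

## The synthetic cohort generator

**Population structure.** Genotypes follow the Balding–Nichols F-model: per
variant an ancestral frequency `p0 ~ Uniform(0.05, 0.95)` (bounded away from
0/1 so variants stay polymorphic), and for each population a frequency drawn
from `Beta(p0(1-F)/F, (1-p0)(1-F)/F)`, which has mean `p0` and variance
`F·p0(1-p0)`. `F = 0` degenerates to the ancestral frequency exactly.
Genotypes are `Binomial(2, p)` within population (Hardy–Weinberg), variants
unlinked. The default `F = 0.1` separates two populations cleanly in PC
space at 1,000 variants while leaving ancestry assignment non-trivial at
small variant counts. A reference panel and a study cohort drawn from the
same frequencies play the roles of an external PCA reference (e.g. the 1000
Genomes superpopulations) and the analysis cohort.

**Scoring file.** Per-variant weights are normal with configurable mean/sd.
Two corruptions exercise the harmonizer exactly as published scoring files
do: a fraction of variants (default 5%) carries strand-ambiguous A/T or C/G
allele pairs, and a fraction of records (default 20%) is written with
swapped effect/other alleles and sign-flipped weight — an equivalent
encoding that the allele-flipping logic must undo.

**Non-portability.** The parameter `weight_freq_cor` sets the correlation
between a variant's weight and its between-population frequency difference.
The study condition used by the analysis scripts and the acceptance checks
is 0.05: because the induced mean difference accumulates linearly over
1,000 variants while the within-population score sd grows as the square
root, this small correlation already shifts the two raw score distributions
by more than a within-population standard deviation — a sharp separation of
the raw high-PRS fractions (roughly 35 vs 5 percent above the pooled 80th
percentile) — while leaving most score variance within population, so the
association and survival analyses still see genuine signal. Larger values
(say 0.5+) make ancestry consume essentially all score variance, which is
not a realistic portability scenario.

**Disease.** A liability-threshold model:
`L = beta_prs·G + beta_sex·sex + beta_age·age_std + e_fam + e`, with `G` the
standardized true weighted score, sex ~ Bernoulli(0.5), recruitment age ~
Uniform(40, 69) standardized as `(age - 54.5)/8.4` so `beta_age` is per SD,
`e_fam` a family-shared environment term with variance `fh_shared_env`, and
`e` independent noise scaled so `Var(L) = 1` under this coding (a
configuration that would require non-positive noise variance is rejected at
construction). A sample is a case iff `L > qnorm(1 - prevalence)`, with
prevalence settable per population. Liability thresholds give approximately
logistic marginal odds ratios, so the logistic analysis stage is correctly
specified up to link approximation, and the latent liability supports
family-history generation. Defaults: prevalence 0.1, `beta_prs = 0.5`,
`beta_sex = 0.2`, `beta_age = 0.3`, `fh_shared_env = 0.05` — a moderately
heritable common disease.

**Family history.** Each proband gets three first-degree relatives (two
parents, one sibling — all with genetic correlation 0.5 to the proband):
`g_rel = 0.5·g + sqrt(0.75)·g_new` on the standardized scale, the same
family-shared environment term as the proband, independent noise, own sex
and age, and the same liability threshold. FH = 1 iff any relative is
affected. With `beta_prs = 0` and `fh_shared_env = 0` family history is
exactly independent of case status; with either sharing mechanism active,
case probands have FH rates above the independence bound
`1 - (1 - prevalence)^3` — both are asserted in tests.

**Onset ages.** A proportional-hazards model on the age scale with constant
baseline hazard: `T ~ Exponential(hazard_baseline · exp(eta))`,
`eta = hazard_beta_prs·G + hazard_beta_sex·sex`. Onsets after the
recruitment-visit age are censored at the visit. The onset stage is the
event-defining mechanism: it overwrites the case indicator so the survival
columns are internally consistent. A cohort cannot simultaneously follow the
liability threshold and an independent hazard draw, so the logistic-model
analyses use the liability stage (no onset stage) and the survival analysis
uses the onset stage; both mechanisms load on the same true score. Onsets
may precede age 40 (prevalent cases enter at their onset age, there is no
left truncation); this mirrors cohort analyses that include prevalent
disease and is a known caveat of the resulting cumulative-incidence curves.

**Reproducibility.** Every stage draws from its own RNG substream derived
from one master seed by hashing a stage name (`substream_seed`), so adding
or removing a stage never perturbs another stage's draws, and fixed
configurations give byte-identical serialized outputs (asserted in tests).

## Scoring and harmonization

Scoring files use the PGS-Catalog tab-separated dialect (`#` header lines;
`rsID`/`rsid` and `effect_weight`/`beta` aliases accepted; duplicate ids and
non-numeric weights are hard errors). Harmonization matches records to
genotype variants by id, falling back to chromosome + position, and
classifies each record: strand-ambiguous pairs are excluded outright (their
strand cannot be resolved, the standard practice); effect = ALT is used
as-is; effect = REF flips the dosage to `2 - d`; pairs matching only after
strand complement are complemented first; anything else is dropped as an
allele mismatch, never guessed. The full 12-configuration truth table is
pinned in a test. `PRS_i = sum_j w_j d_ij`; missing dosages are mean-imputed
as twice the cohort effect-allele frequency (keeps the score unbiased under
missingness at random, matching common scoring tools; the choice is recorded
in the harmonization report). Standardization uses the whole-cohort mean and
the population (n-denominator) standard deviation; the sample-sd alternative
differs by `sqrt(n/(n-1))` and is immaterial downstream, but the convention
is pinned and tested.

## PCA, projection, adjustment

Reference PCA standardizes each variant by its mean dosage and
`sqrt(2 p (1-p))` (the usual genotype scaling; monomorphic variants are
dropped), takes loadings from the SVD, and records per-population centroids
of the reference scores. Study samples are projected with the *reference*
means and scales — the study never influences the basis — and variants
absent from the study contribute zero after centering. Ancestry is assigned
by nearest centroid over the first K components (K = 4 throughout, matching
the downstream models; exact ties break to the lexicographically first
label and are flagged). Two PC sets coexist deliberately: reference-panel
projection PCs serve ancestry assignment, while the adjustment regression
defaults to PCs computed on the study cohort itself, mirroring the common
design in which ancestry labels come from an external reference but the
correction uses within-cohort structure.

`adjust_prs` fits one pooled least-squares regression (QR decomposition) of
the score on an intercept plus the four PCs — not per-population regressions
— subtracts the fit, and standardizes the residual. Residuals are orthogonal
to every PC by construction (asserted to 1e-8), the result is invariant to
positive affine transforms of the input score (so standardizing before or
after the regression changes nothing), constant PC columns are dropped with
a warning so degenerate toy inputs run, and exact collinearity or zero
residual variance are hard errors.

## Stratification conventions

Percentile groups use rank-based thresholds, pinned because quantile
conventions differ across ecosystems: *low* iff the score is strictly below
the `(floor(q·n/100) + 1)`-th order statistic (the smallest value outside
the bottom q%), *high* iff strictly above the `ceil(q·n/100)`-th order
statistic, boundary ties falling inward to *intermediate*. With `n`
divisible by 5 and no ties this puts exactly 20% in each tail. Group
membership is invariant under strictly increasing transforms. Two reference
modes: `within_population` percentiles (used for the stratified association
models, matching the published analysis design) and `cohort_wide` (used for
the distribution-shift comparison, where the point is precisely that a
pooled threshold treats the populations asymmetrically). The joint
score-by-family-history factor has six levels with intermediate-score /
FH-negative fixed as the reference.

## Association and discrimination

Logistic models are fitted by maximum likelihood (`stats::glm`) with Wald
standard errors; odds ratios are `exp(beta)` with 95% intervals
`exp(beta ± 1.96 se)`. Diverging slopes (|beta| > 15) are reported as
complete/quasi-complete separation naming the offending term; empty group
levels are errors (three-level model) or dropped with a warning (six-level
joint model, where sparse cells are expected). The group-by-FH interaction
is a likelihood-ratio test of the product terms against the additive model.
Crude 2x2 odds ratios use the cross-product with the Haldane–Anscombe 0.5
correction for single zero cells.

Discrimination uses a 75/25 train/test split, stratified by outcome (the
source analysis splits "randomly"; stratification prevents degenerate test
sets at realistic case counts and is seeded). AUROC is the Mann–Whitney
statistic over test predictions with midrank tie handling; its CI is the
DeLong placement-variance interval (cross-checked against pROC in tests).
AUPRC is step-interpolated precision–recall integration, preferred under
class imbalance. Downsampling removes samples from the over-represented
side until the case:control ratio matches a target within one sample, for
comparing performance across cohorts with different base rates.

## Survival analysis

Cox partial likelihood with Efron tie handling (ages are coarse; ties are
certain — the choice is pinned against a hand-computed six-record oracle).
Time is age: onset age for events, most-recent-visit age for censored
controls; age therefore does not also appear as a covariate (listing it both
as time scale and covariate would be contradictory). Proportional hazards
are checked by correlating scaled Schoenfeld residuals with event time
(identity transform, pinned for determinism) per covariate plus the global
chi-square. Adjusted cumulative incidence for each joint stratum is
`1 - exp(-Lambda0(t) · exp(x'beta))` evaluated at "this stratum, every other
covariate at its cohort mean" (the conditional-at-means convention). No left
truncation is applied, so with prevalent cases included the curves can reach
high incidences by late ages; this mirrors the analysis design the pipeline
reproduces rather than correcting it.

## What the tests do and do not show

The generator emulates population structure, a score-loaded liability,
correlated family history, and proportional-hazards onsets — the structure
the analysis assumes. It deliberately omits linkage disequilibrium,
imputation error, realistic allele-frequency spectra, X-chromosome dosages,
and gene–environment interaction. Passing tests therefore demonstrate that
the pipeline's logic is correct under its stated assumptions (parameters are
recovered, intervals cover, the distribution shift is removed, diagnostics
hold their size), not that published effect sizes from restricted biobank
data are reproduced — those require the original genotypes.

Problem sizes used by the checks: the distribution-shift analysis runs two
populations of 5,000 samples at 1,000 variants; interval-coverage and
null-score checks use 200 replicates at n = 3,000–5,000; Cox recovery uses
n = 10,000 and the Schoenfeld size check 500 replicates of n = 300. These
sizes give Monte-Carlo error comfortably inside the asserted tolerances.

## Known limitations

- Exponential baseline hazard (constant over age); fine for recovery checks,
  not a realistic age-incidence curve.
- Relatives share one environment term and a 0.5 genetic correlation with
  the proband, but sibling–parent and parent–parent correlations are not
  modelled.
- The obesity pathway treats BMI as an auxiliary covariate with a strict
  BMI > 25 indicator (missing BMI excludes a sample from that analysis
  only); BMI is not modelled as a heritable quantitative trait.
- Self-reported and hospital diagnosis codes are unioned; no precedence or
  date reconciliation.
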