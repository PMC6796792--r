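---
title: "Stratifying obesity with a family-derived polygenic risk score: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying obesity with a family-derived polygenic risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famprs)
```

`famprs` re-implements, as a tested pipeline over synthetic data, a
family-cohort polygenic-score analysis of obesity: per-SNP association
testing in ascertained nuclear families with kinship-aware logistic mixed
models, construction of an odds-ratio-weighted allele score, evaluation of
the score's ability to stratify obesity (trend and quintile odds ratios,
optimism-corrected AUC, reclassification indices, BMI variance explained),
and the analytic power of the score in independent target samples. This
vignette documents the models, every tunable that matters, and the design
decisions that were genuinely open.

## The synthetic family cohort

No individual-level data from the emulated study are public, so the
package ships a generator whose defaults *are* the study conditions: 222
nuclear families (~881 individuals), a 231-SNP candidate panel with
minor-allele frequencies uniform on (0.05, 0.5), obesity defined as BMI
>= 30 kg/m2 at ~28% prevalence after ascertainment, and a true additive
score explaining `h2_score = 0.075` of the BMI variance in the
unascertained population.

Founder genotypes are drawn in Hardy-Weinberg proportions; offspring
genotypes by Mendelian transmission. BMI is Gaussian on the natural
scale,

$$\mathrm{BMI} = \mu + \beta_{sex}(\mathrm{female}-\tfrac12)
  + \beta_{age}(\mathrm{age}-\bar a) + S + \varepsilon,$$

with the components scaled so the total variance equals
`bmi_base_sd^2` (default 6.5^2) and the true score $S$ carries exactly
`h2_score` of it. A Gaussian BMI understates the right skew of real BMI
distributions; a heavy-tailed option was considered and deferred, so
passing tests say nothing about robustness to extreme BMI outliers.
Age and sex are drawn independently of genotype (they act only as
covariates downstream), with parents in the upper and offspring in the
lower half of `age_range`.

**Ascertainment.** Families are recruited when at least one parent *and*
one offspring reach BMI >= 32 kg/m2, implemented by rejection sampling of
whole families — simple and exact to the stated rule. One subtlety forced
a modelling decision: applied to the *measured* BMI, the rule guarantees
two currently obese members in a ~4-person family, so the post-
ascertainment prevalence could never fall to the ~28% the emulated cohort
shows. The resolution is that recruitment happened years before
measurement: the rule is applied to a recruitment-time BMI that
correlates `tracking_cor = 0.5` with the measured one (same marginal
distribution). With that tracking the bisection calibration of
`bmi_base_mean` (see `calibrate_base_mean()`, which uses a fast
genotype-free family simulator) lands at 22.85 kg/m2, giving ~28%
measured prevalence and a plausible population mean. The exported
`ascertain_families()` keeps the literal measured-BMI rule; the
recruitment-BMI basis is available via its `on` argument. Ascertainment
also size-biases accepted families, which is why the default
`offspring_mean = 1.7` (not 881/222 - 2) reproduces the ~881-individual
cohort.

**Splits.** The 80/20 discovery/validation split is at the individual
level with obesity stratification (sizes `floor(0.8 n)` and the rest;
`round()` allocation within the obese stratum keeps the prevalence gap
below `1/min(n1, n2)`). Whether the emulated study kept families intact
across partitions is not stated; both options exist (`by_family`), and
individual-level is the default. Family-level splits change the kinship
structure of each partition and are the statistically cleaner choice if
one worries about information leaking between partitions through
relatives; the default mirrors the likelier reading of a random
participant split.

## Genotype QC

Per-SNP filters are the study's inclusion criteria: MAF > 0.01, call
rate > 0.95, Hardy-Weinberg exact P > 2.6e-4, imputation r2 > 0.3 —
strict inequalities exactly as printed, so boundary values fail. The
Hardy-Weinberg test is the standard conditional exact test (two-sided by
summing all heterozygote tables no more probable than the observed one,
not mid-p), computed by a numerically stable recurrence and verified
against full enumeration for every table up to n = 200; a chi-square
variant exists behind a flag. MAF and Hardy-Weinberg statistics are
computed on founders only by default, because including relatives
inflates both; an all-individuals mode exists for parity with naive
pipelines. Which basis the original analysis used is unstated.

## Kinship and the mixed models

Kinship is computed by the recursive tabular method; the random-effect
covariance is $\sigma^2_g \cdot 2\Phi$ (the additive relationship
matrix — the convention of the mixed-model tooling this analysis family
uses, since "kinship matrix" alone is ambiguous by a factor of 2).
Kinship across families is exactly zero, so the package keeps $2\Phi$ in
per-family blocks and the mixed-model solves are blockwise — the dense
n x n matrix is never formed, which is what makes the 10,000-individual
recovery checks cheap. A gene-dropping Monte-Carlo estimator
(`gene_drop_kinship()`) serves as the independent oracle.

The logistic mixed model is fit by penalized quasi-likelihood (PQL):
iterate the working response, a GLS solve in the eigenbasis of
$W^{1/2} G W^{1/2}$, and a restricted-likelihood update of $\sigma^2_g$,
to convergence at 1e-6 or 100 iterations. PQL was chosen over adaptive
quadrature because it is the method family of the established
kinship-GLMM tools and stays tractable with arbitrary dense covariance;
its known attenuation bias for binary outcomes grows with $\sigma^2_g$,
which is why the recovery tests run at a moderate $\sigma^2_g = 0.5$
(where the simulated log-OR of 0.3 is recovered to ~0.03) and why
reported variance components for binary traits should be read as
conservative. Wald tests match common GWAS reporting. Separation is
flagged (|beta| > 20) with estimates still returned. Missing genotypes
are mean-imputed to twice the counted-allele frequency — the same policy
the score uses, keeping the scan and the score consistent. The scan
applies no multiple-testing correction: the analysis deliberately selects
at raw P < 0.05 and then uses *all* SNPs for the score anyway.

The linear mixed model (BMI outcome) is REML via the same blockwise
eigendecomposition, profiling the residual variance over the variance
ratio on a log grid with a boundary guard at $\sigma^2_g = 0$.

## The score and its evaluation

Weights default to the odds ratio itself (`mode = "or"`), which is what
the source analysis literally describes; `"logor"` provides the
field-standard log-odds weighting. Both are first-class because the
printed description and common practice disagree; the default follows
the printed description. Scores are sums of weighted counted-allele
counts; quintiles are rank-based with stable tie-breaking, sizes
differing by at most one, Q1 lowest.

`OR_trend` is the Wald odds ratio on the *continuous* score (per unit by
default, per SD behind a flag — the emulated study's own trend ORs are
only interpretable per unit of an OR-weighted score, and its
abstract/results discrepancy suggests the scale was not fixed there
either; a genuine ordinal trend across quintiles is available).
Quintile ORs enter as four indicator contrasts against Q1.

Discrimination uses rank-based AUC (ties one half; verified against
all-pairs counting) on population-level predicted probabilities (random
effect at zero): whether the original predictions conditioned on the
family random effect is ambiguous, and population-level is the choice
that generalizes to new families. The optimism correction is
Harrell-style with B = 1000 individual resamples by default: refit on
the resample, optimism = AUC(resample fit on resample) - AUC(resample
fit on original), `auc_adj = apparent - mean(optimism)`. Model
comparisons refit both models on the same resamples and report a
bias-corrected (BC, no acceleration) percentile interval of the
difference, significant when it excludes zero. Individual resampling
breaks family structure, so the bootstrap refits use plain logistic
regression — the matching estimator of the population-level fixed
effects; a family-block resampling option (with kinship refits) is the
statistically safer alternative and is available. NRI is category-free
(no risk categories are stated anywhere), IDI is the difference in mean
risk separation; their intervals are bootstrap percentile intervals with
normal-approximation p-values.

Variance explained by the score is the drop in unexplained (residual +
polygenic) variance when the score joins sex and age in the linear mixed
model, as a fraction of the total BMI variance; the squared partial
correlation is reported alongside as the alternative definition. On
10,000-individual synthetic cohorts the first definition recovers the
simulated 0.075 within 0.01.

## Power of the training/target design

The score is trained in one sample and tested in another, so its power
depends on the weight-estimation noise as well as the true signal. For a
binary trait the liability-threshold model with the stated *sample*
prevalences is used (the samples are ascertained; no population-
prevalence correction is attempted because none is described). With
training prevalence $K_1$ ($z_1$ the normal density at its threshold),
target prevalence $K_2$, $m$ SNPs, true liability-scale score variance
$v_g$ (`score_r2_train`), the expected squared correlation between the
*estimated* score and the target outcome is

$$\rho^2 = \frac{(z_1 z_2 v_g)^2}
  {\left(v_g z_1^2 + m K_1(1-K_1)/n_1\right) K_2 (1-K_2)},$$

the per-SNP estimation noise entering through the $m/n_1$ term, and

$$\mathrm{ncp} = n_2 \rho^2 / (1-\rho^2), \qquad
  \mathrm{power} = P(\chi^2_1(\mathrm{ncp}) > \chi^2_{1,1-\alpha}).$$

`mc_power()` is the package's independent oracle: it simulates the
training sample under the liability model, estimates the $m$ weights by
marginal regression, scores an independent target and tests at
$\alpha$; the acceptance suite checks agreement within 0.03 across a
3x3 grid at 2000 replicates per cell (run at reduced sizes,
$n_1 = 200$, $m = 40$, with targets of 100-400 — the plug-in formula is
an expectation and its approximation error is largest when training
noise dominates, so agreement at these harsher sizes implies agreement
at the study scale). `pi_null` redistributes effects over a subset of
SNPs; with no p-value selection and total score variance fixed it
provably does not move the power, and it is exposed only for sensitivity
analyses around the effect distribution.

Under the emulated study's inputs (training n = 704 at prevalence 0.278,
target n = 177 at 0.282, m = 231, $v_g = 0.075$, $\alpha = 0.05$) this
model puts the power near 0.15, and the Monte-Carlo oracle agrees — the
231-SNP weight noise from a 704-person training sample dominates the
signal ($m K_1(1-K_1)/n_1 \approx 0.066$ against
$v_g z_1^2 \approx 0.008$). Removing the estimation noise entirely — the
power to detect a *known* score explaining 7.5% of liability variance in
a 177-person target — gives 0.80 (`analytic_power_error_free()`), which
is also insensitive to $m$ and $n_1$. The published value this design
echoes is far closer to the second reading; the package reports the full
model as its primary answer and the error-free diagnostic alongside,
because only the full model is consistent with its own simulation
oracle.

## Numerical choices and degenerate inputs

* PQL/REML convergence: 1e-6 on the largest parameter change, 100
  iteration cap; variance ratios optimized on the log scale over
  [e^-15, e^15] with a boundary guard at zero.
* Working weights are clamped at 1e-8; relationship blocks have
  eigenvalues clipped at zero (PSD verified to -1e-8).
* Exact-test ties use a 1e-7 relative tolerance when summing tables "as
  extreme as observed" — the convention of the standard exact SNP-HWE
  implementations.
* Degenerate inputs fail loudly: single-class outcomes, rank-deficient
  designs, cycles or missing parents in pedigrees, all-missing genotype
  columns, quintiles of fewer than five values.
* Bootstrap resamples that lose a class are redrawn (bounded); seeds are
  explicit arguments everywhere, and identical config + seeds give
  byte-identical pipeline reports.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to make their Monte-Carlo
error small relative to the tolerance they assert: ~10,000 individuals
for variance-explained recovery (+/-0.01), 20,000 for the generator's
variance targeting, 500 family replicates for log-OR recovery and Wald
coverage, 1000 null replicates for the scan's type-I error, 2000
replicates per cell for power agreement, 2e5 gene drops for kinship
(+/-0.01), and full enumeration (no sampling) for the exact test up to
n = 200.

## Known limitations

* PQL attenuates binary-trait effects when $\sigma^2_g$ is large; an
  adaptive-quadrature or MCMC refit is out of scope.
* The generator simulates independent SNPs (the emulated analysis
  deliberately did not LD-prune), Gaussian BMI, and covariates
  independent of genotype; real cohorts violate all three, so passing
  tests validate the statistical machinery, not robustness to those
  features.
* Imputation is emulated only as an `imputation_r2` column; no dosage
  uncertainty is simulated.
* The optimism bootstrap's default individual resampling understates
  within-family dependence; use the family-block option when that
  matters.
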