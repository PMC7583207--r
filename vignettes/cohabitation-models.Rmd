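---
title: "Cohabitation-dependent familial models for epigenetic age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohabitation-dependent familial models for epigenetic age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicohab)
```

## The scientific question

DNA-methylation (DNAm) age is a biological-age predictor computed from
methylation levels at clock CpG sites; its deviation from chronological
age ("epigenetic age acceleration") predicts mortality and disease risk
in adults. Twin and family studies restricted to narrow age ranges have
reported wildly different heritabilities for DNAm age, from near 0 to
near 100%. A lifespan view changes the question: instead of asking "how
heritable is epigenetic aging at age X?", one asks how the similarity of
relatives *develops* — does it track shared genes (constant with age,
scaled by kinship) or shared households (rising while relatives live
together, fading after they separate)?

`epicohab` implements the statistical machinery for that question: a
multivariate-normal pedigree likelihood over families pooled from many
studies, familial correlation estimation for five pair types (MZ and DZ
twins, siblings, parent–offspring, spouses), a cohabitation-dependent
correlation model across the lifespan, five variance-components model
variants compared by AIC, and a synthetic cohort generator so that every
stage is testable without access-controlled data.

## The phenotype

Epigenetic age acceleration is the residual from an OLS regression of
DNAm age on chronological age, computed within *strata* (one per study
by default; longitudinal waves, generations or age groups should each be
their own stratum, which is why `age_acceleration()` takes a `strata`
argument). Cohorts measured in several biological samples per person are
first reduced by `standardize_multitissue()`: per-tissue z-scores
(sample, n−1 variance convention), averaged within person. The analysis
residual is then further adjusted for sex — and optionally for seven
estimated cell-composition fractions (naive CD8+ T, exhausted CD8+ T,
plasmablasts, CD4+ T, NK, monocytes, granulocytes) as a sensitivity
analysis — by `adjust_covariates()`, per stratum. Adjustment within
rather than across strata is a package choice: the familial models treat
the residual variance as study-specific, so the mean structure should be
removed at the same granularity. Cell fractions summing to one alongside
the intercept are rank-deficient; the trailing collinear column is
dropped automatically and reported.

## The cohabitation clock

Each relative pair carries a clock $(t, t_0)$, with the pair cohabiting
while $t \le t_0$ and separated after:

| pair | $t$ | $t_0$ |
|------|-----|-------|
| MZ/DZ twins | chronological age | `adult_age` (18) |
| siblings | younger sibling's age | younger's age when the older turned `adult_age`, floored at 0 |
| parent–offspring | offspring's age | `adult_age` (18) |
| spouses | mean age − `marriage_age` (24), floored at 0 | separation time if known, else $+\infty$ |

`adult_age` and `marriage_age` are conventions, not data, so they are
configurable constants with the defaults above. Three boundary choices
are deliberate: a sibling pair whose age gap exceeds `adult_age` gets
$t_0 = 0$ and spends its whole observed life "separated"; spouses with
unknown separation are treated as still cohabiting; and adult twins are
switched to the separated regime at `adult_age` regardless of their
actual living arrangements, because the model has no covariate for
those.

## The correlation model

For relatives $i, j$ the familial correlation is modelled as

$$
\rho_{ij} =
\begin{cases}
\theta - e^{-\lambda t} & t \le t_0\\[2pt]
(\theta - e^{-\lambda t_0})\, e^{-\nu (t - t_0)} & t > t_0
\end{cases}
\qquad 0 \le \theta \le 2,\ \lambda, \nu \ge 0 .
$$

The correlation at the start of cohabitation is $\theta - 1$; $\lambda$
(per year) is the rate at which similarity accrues while living
together and $\nu$ the rate at which it dissipates afterwards. The two
branches agree at $t = t_0$, so the curve is continuous. Pairs are
grouped — by default $\{MZ\}$, $\{DZ, \text{sibling}\}$,
$\{\text{parent–offspring}\}$, $\{\text{spouse}\}$ — with $\theta$,
$\lambda$, $\nu$ shareable or free per group. The analysis ladder the
package reproduces is: (i) $\theta$ free per group; (ii) $\theta = 1$
(supported when no group's $\theta$ differs from 1); (iii) tests of
rate heterogeneity, by LRT between shared-rate and per-group-rate
models; (iv) the final model with DZ and siblings merged and a single
shared decay rate.

## The variance-components model

The pairwise covariance combines a constant additive-genetic term with
cohabitation-dependent genetic and shared-environment kernels:

$$
\mathrm{COV}_{ij} =
\begin{cases}
\alpha\sigma^2_A + \beta_A (1 - e^{-\lambda_A t})
  + \beta_C (1 - e^{-\lambda_C t}) & t \le t_0\\[2pt]
\alpha\sigma^2_A + \beta_A (1 - e^{-\lambda_A t_0}) e^{-\nu_A (t-t_0)}
  + \beta_C (1 - e^{-\lambda_C t_0}) e^{-\nu_C (t-t_0)} & t > t_0
\end{cases}
$$

with all parameters non-negative. Five variants are fitted
(`variance_variants()`), encoding the constraint sets:

* **AE** — constant genetic effects only: $\alpha = 2\times$kinship,
  all kernel terms zero, $\sigma^2_A$ free.
* **cohabitation AE** — $\beta_A = 2\times$kinship, $\lambda_A, \nu_A$
  shared over non-spouse pairs (spouse genetic covariance is zero
  through kinship), no C term.
* **cohabitation ACE** — both kernels, $\beta_C = 1$ for all pairs,
  C-rates shared across MZ/DZ/sibling/parent–offspring.
* **cohabitation CE** — shared environment only; $\beta_C = 1$ for DZ,
  sibling and spouse pairs and free for MZ ($\beta_{C,MZ}$) and
  parent–offspring ($\beta_{C,PO}$) pairs. $\beta_{C,MZ}$ is the
  MZ:(DZ, sibling) shared-environment ratio and $1/\beta_{C,PO}$ the
  (DZ, sibling):parent–offspring ratio — the two quantities that
  measure departure from the equal-environment assumption.
* **cohabitation CE + constant A** — the CE model plus
  $\alpha = 2\times$kinship with $\sigma^2_A$ free; $\sigma^2_A$ is the
  constant genetic variance share.

**Scale convention.** The kernels are parameterized on the correlation
scale: the family covariance matrix has the free study variances
$\sigma^2_s$ on its diagonal and $k_{ij}\,\sigma_i\sigma_j$ off it,
where $k_{ij}$ is the kernel value. This is forced by the constraint
$\beta_C = 1$ for DZ pairs: a kernel bounded near 1 can only reproduce
observed correlations of 0.3–0.7 if the phenotype scale per study is
absorbed into $\sigma^2_s$. It makes every fit invariant to rescaling
the phenotype, and it makes $\sigma^2_A$ directly interpretable as a
variance fraction (AE heritability, CE+A genetic share). A consequence
is that the variance-proportion curves
(`variance_proportion_curves()`) are the kernel contributions
themselves; the inverse-variance-weighted mean of the fitted study
variances is attached as the reference for converting back to raw
units.

## Likelihood and numerics

All fits share one engine (`ml_fit()` over `make_model_data()`):

* **Likelihood.** Families are independent; each contributes
  $-\tfrac12\{m\log 2\pi + \log|\Sigma_f| + y^\top\Sigma_f^{-1}y\}$.
  Residual phenotypes are treated as mean-zero (they are residualized
  upstream). Two-member families use a closed-form bivariate path,
  vectorized over all pairs; larger families go through a per-family
  Cholesky. A non-positive-definite $\Sigma_f$ — possible for families
  of three or more, since pairwise kernels do not guarantee joint
  PSD — yields a large penalized objective value rather than an error,
  so the optimizer simply retreats; `psd_violations()` re-checks every
  family at the optimum (must be zero).
* **Constraints by transform.** Rates, variances and multipliers are
  optimized on the log scale, correlations on the atanh (Fisher z)
  scale, and $\theta$ through a logistic map onto $[0, 2]$.
* **Optimization.** BFGS with hand-derived analytic gradients
  (chain rule through the kernel, the $\sigma_i\sigma_j$ scaling and
  the transforms; verified against finite differences in the test
  suite), multi-start (5 jittered starts by default, first start
  unjittered), followed by a polishing restart. Convergence requires a
  gradient norm below $10^{-4}\max(1, |\ell|)$.
* **Uncertainty.** Standard errors come from the observed information
  (numerical Hessian of the transformed-scale likelihood) mapped back
  by the delta method; confidence intervals are Wald intervals on the
  transformed scale mapped through the (monotone) transform — for
  correlations this is exactly the Fisher-z interval. Two-sided
  $\alpha = 0.05$ throughout. Correlations are clamped to
  $(-0.99, 0.99)$ for reporting only, with a boundary flag.
* **Tests.** Nested models are compared by LRT
  ($2\Delta\ell \sim \chi^2_{df}$, statistic clamped at zero, error if
  meaningfully negative). For the CE+A vs CE comparison the tested
  $\sigma^2_A$ sits on its boundary under the null; the naive
  $\chi^2_1$ reference is used deliberately (the convention of the
  analyses this package mirrors), which makes that test mildly
  conservative.
* **AIC** is $-2\ell + 2k$ with $k$ counting all free parameters
  including the study variances; ties in `compare_variants()` go to
  the model with fewer parameters.

Study variances are *estimated jointly* by maximum likelihood rather
than plugged in; this is self-consistent, testable, and makes the AIC
comparison well-defined on a single likelihood surface.

## The synthetic cohort generator

`simulate_cohort()` inverts the models as samplers: per family it
assembles the correlation matrix from the chosen generating kernel,
scales by the study variance, draws the members jointly from the
multivariate normal, and emits DNAm age as
`intercept + slope × age + sex_effect × male + deviate` (slope 1,
intercept 0 by default so the acceleration pipeline recovers the
deviates exactly; a non-unit slope exercises the residualization
non-trivially). Templates cover independent pairs and households (two
parents, children, optional twin pair, optional sibship without
parents); the generator refuses — naming the offending parameters —
any template whose implied correlation matrix is not positive
definite. Spouse separation defaults to "never", the dominant
real-data case.

`paper_like_cohort()` mirrors the pooled ten-study design the analysis
targets: newborn and infant twin blocks, an adolescent family study
with parents and siblings, a large 18-year-old twin study, adult and
elderly twin studies, sister studies, and a spouse study, with block
sizes, age distributions and residual variances modelled on the
published per-study descriptives (variances from the reported
acceleration SDs). At `scale = 1` it contains exactly 4217 individuals;
this count works out once the infant multi-tissue study's children are
counted once across their three tissue blocks. Family composition for
the two family-structured studies is an approximation: the printed
margins (individuals per study, pairs per type) cannot all be matched
jointly, so the generator matches individual counts exactly and pair
counts approximately. Longitudinal waves of the elderly twin study are
generated as separate samples, not as repeated measures of the same
people — within-person trajectories are out of scope.

What the generator does *not* emulate: CpG-level data and clock
computation (DNAm age is consumed, never computed), measurement-batch
effects, assortative mating, age-dependent residual variance within a
study, and non-Gaussian tails. Passing the round-trip tests therefore
shows that the estimation machinery is correct and calibrated under
the model's own assumptions — it does not validate those assumptions
against real methylation data.

## Generating truths and experiment sizes

The recovery experiments regenerate data under the published point
estimates — `correlation_truth()` ($\theta = 1$,
$\lambda_{MZ} = 0.041$, $\lambda_{DZ,SIB} = 0.026$,
$\lambda_{PO} = 0.011$ per year), `ce_truth()`
($\beta_{C,MZ} = 1.41$, $\beta_{C,PO} = 1/2.03$), `ae_truth()`
(heritability 0.52) and `ce_plus_a_truth()` (genetic share 0.13) — and
fit the same model back. Two generating values are not printed as
point estimates anywhere and are package choices, fixed once: the
shared decay rate $\nu = \nu_C = 0.005$/yr (a slow dissipation leaving
most of the accrued similarity intact into late life, consistent with
the reported lifespan curves) and the CE rise rate
$\lambda_C = 0.03$/yr (between the MZ and DZ/sibling correlation-model
rates).

Experiment sizes are chosen so Monte-Carlo error is small relative to
the quantity being recovered, and stated here as the package's own
design: 2000 pairs per group (ages uniform 0–90) for the
correlation-rate recovery — the design under which those rates are
defined — 16 000 pairs for the CE multipliers, 8000 for AE
heritability, and 480 000 for the CE+A genetic share, which is weakly
identified because a constant genetic covariance and a persistent
shared-environment kernel are nearly collinear over adult ages (the
published interval for that share spans −10% to +35% for the same
reason). Calibration experiments use a double-size
(`scale = 2`) pooled cohort for CI coverage and a half-size cohort for
the 50-replicate AIC model-selection check.

## Known limitations

* Pairwise-specified covariances do not guarantee a PSD family matrix
  for households of 3+; the engine penalizes rather than reprojects,
  which is correct at the optimum but means the likelihood surface has
  hard walls a poor start could hit.
* The Wald interval for $1/\beta_{C,PO}$ is obtained by inverting the
  interval for $\beta_{C,PO}$ (log scale); when parent–offspring
  information is thin the interval is strongly asymmetric, and
  profile-likelihood intervals would be preferable.
* Identifiability requires pairs observed on both sides of $t_0$; a
  group observed only at $t = 0$ (newborn-only) leaves its $\lambda$
  at the boundary with an unbounded interval, which is reported, not
  hidden.
* The equal-ages invariant for twins means twin waves measured at
  different ages per member must be recoded or relaxed upstream.
* Spouse pairs share the decay rate of biological relatives in the
  final correlation model; this is a convention (the alternative is a
  config override), not an inference.

## A minimal session

```{r example, eval = FALSE}
cfg <- paper_like_cohort(scale = 0.5)
sim <- simulate_cohort(cfg, seed = 1)
out <- run_pipeline(sim$phenotypes, sim$pairs, out_dir = "results/run")
out$variance_models$comparison
```

The `analysis/` directory of the source repository contains the
numbered scripts that run exactly this ladder — simulation,
descriptives, within-study correlations, the lifespan correlation
model, and the variance-components comparison — writing their tables
under `results/`.
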