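---
title: "Recalibrating multi-study case-control effect sizes with a hierarchical Bayesian model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recalibrating multi-study case-control effect sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case-control neuroimaging studies are routinely run on a few dozen
participants per group. At that size the sampling error of a standardized
mean difference (Cohen's *d*) is large — roughly $2/\sqrt{n}$ — and
published effects, filtered by significance, tend to be inflated. When many
comparable studies exist (for example, site-level cohorts inside a pooling
consortium comparing substance-dependent and non-dependent participants on
regional brain measures), each study's estimate can be *recalibrated* by
borrowing strength from its peers. `hbshrink` implements that recalibration
end to end: per-study effect-size estimation, batch harmonization, tailored
sampling-variance estimation, a conjugate Gibbs sampler for the hierarchy,
and posterior summaries with convergence diagnostics.

## The model

For one regional measure, let $y_i$ be the observed Cohen's *d* of study
$i = 1,\dots,K$ and $\omega_i$ its estimated sampling SD. The hierarchy is

$$
y_i \sim N\!\big(\mu_i,\ \omega_i^2/\tau\big), \qquad
\mu_i \sim N\!\big(M,\ 1/T\big), \qquad
M \sim N(m_0, v_0), \qquad \tau, T \sim \mathrm{Gamma}(a, b),
$$

where precisions are modeled (so $\sigma = 1/\sqrt{\tau}$ is the common
component of the study-level SD and $\Sigma = 1/\sqrt{T}$ the between-study
SD of true effects). The study-level variance is the common component
*weighted by* the study-specific $\omega_i$: a study whose subsampled SD is
small is allowed to speak with more weight. All four full conditionals are
conjugate, so the posterior is approximated by a pure Gibbs sampler
(`gibbsSample()`), written as a small compiled kernel that uses R's RNG
stream and is therefore exactly reproducible under `set.seed()`.

Posterior study means are shrunk toward the overarching mean $M$; the
posterior mode (or mean) of $\mu_i$ is the *Bayesian-adjusted* effect size
of study $i$.

### Priors

Defaults are mildly informative and appropriate when effect sizes live in
roughly $[-1, 1]$: $M \sim N(0, v_0 = 10)$ (variance parameterization), and
both precisions get a Gamma prior specified by **mode 1 and SD 10** and
converted to shape/rate via

$$ b = \frac{\text{mode} + \sqrt{\text{mode}^2 + 4\,\text{sd}^2}}{2\,\text{sd}^2},
\qquad a = 1 + \text{mode}\cdot b, $$

(`gammaModeSdToShapeRate()`), which reproduces the requested mode and SD
exactly. Sensitivity arms use SD 0.1 (more informative) and SD 100 (less
informative); both round-trip through the same conversion.

### Two readings of $\omega$

The notation $N(\mu_i, \omega_i\sigma)$ does not pin down whether
$\omega_i$ multiplies the study-level SD or variance. The default
(`omegaConvention = "sd"`) treats $\omega_i$ as an SD multiplier — the
study-level precision is $\tau/\omega_i^2$, so $\tau = 1$ means the
study-level SD equals the subsampled SD exactly, which is the natural
calibration for an $\omega_i$ that is itself computed as an SD. The
variance reading (precision $\tau/\omega_i$) is available behind the same
switch.

## Stage by stage

**Effect sizes** (`computeEffectSizes()`): per study and region, ordinary
least squares of the measure on diagnosis, age, sex and intracranial volume
(no interactions), and the Rosenthal conversion
$d = t\,(n_1+n_2)/(\sqrt{n_1 n_2}\,\sqrt{df})$ with $df = n - 5$. ICV is
included for all three feature families (thickness, area, volume). Studies
lacking one diagnosis group cannot contribute a group contrast and are
dropped with a warning. Rows with missing values are deleted listwise
before fitting.

**Harmonization** (`combatHarmonize()`): parametric empirical-Bayes ComBat
(via the *sva* package) with `study_id` as batch and diagnosis, age and sex
as protected covariates. ICV is deliberately *not* a harmonization
covariate; it remains a covariate of the downstream regressions.
Harmonization is a stand-alone preprocessing step whose purpose here is to
give the subsampler a pool free of between-study technical offsets.
Because the empirical-Bayes step shrinks per-batch location and scale
estimates, harmonization is only *approximately* idempotent: a second pass
moves values by an order of magnitude less than the first (the tests check
median and 90th-percentile second-pass changes against the first pass),
with the residual concentrated in the smallest batches. It also requires at
least two regions, since the prior is estimated by pooling across features.

**Sampling SD** (`estimateOmega()`): for each study, pseudo-studies with
the study's exact diagnosis-by-sex cell counts are drawn from the pooled
harmonized data, without replacement within each draw; the regression is
refit and *d* recorded; $\omega_i$ is the SD (denominator $n-1$) over 1,000
repetitions by default. Cell counts — not ratios — are matched, because
counts are the lossless encoding of the ratios; age and ICV are not matched
but enter through the refitted regression. One subsample per repetition is
shared across regions (a single multi-response regression), which leaves
each region's marginal distribution of simulated *d* unchanged while making
the computation linear rather than quadratic in the number of regions.
A Lilliefors-corrected Kolmogorov-Smirnov test (via *nortest*) checks the
normality of each simulated distribution, supporting the model's normal
likelihood.

Two systematic effects make the measured scaling of $\omega$ with study
size slightly steeper than the idealized $n^{-1/2}$: the conversion factor
$\sqrt{n/(n-5)}\,\cdot\sqrt{df/(df-2)}$ inflates small-study SDs, and
drawing a 250-subject pseudo-study from a ~1,900-subject pool deflates
large-study SDs by the finite-pool factor $\sqrt{1 - n/N}$. Together they
put the expected log-log slope for the default world near $-0.6$ rather
than $-0.5$; the pure square-root law is recovered when the pool is much
larger than any pseudo-study, and the tests check both regimes.

**Fitting and summaries**: `fitAllRegions()` fits each region
independently, with per-region seeds derived from a master seed via the
sorted region names so results cannot depend on evaluation order. Four
chains of 100,000 iterations with the first half discarded is the
reference setting; chains start from overdispersed draws ($\tau, T$ from
their prior, $M \sim N(m_0, 4v_0)$, $\mu_i \sim N(y_i, 1)$) so that the
Gelman-Rubin diagnostic is meaningful. Summaries report, per parameter:

- the **posterior mode** — argmax of a Gaussian-kernel density estimate
  (Silverman bandwidth, 512-point grid spanning the draw range) on the
  chains pooled after burn-in; the estimator's resolution is on the order
  of the KDE bandwidth, which the tests account for;
- the **95% HDI** — the shortest contiguous interval containing 95% of the
  sorted draws; never wider than the equal-tailed interval for unimodal
  draws;
- **split-chain PSRF** (classic formulation, matching the era of the
  underlying methodology, not the rank-normalized variant): each chain is
  halved and $\hat R = \sqrt{(W(n-1)/n + B/n)/W}$; values may dip below 1
  by $O(1/n)$ for well-mixed chains, so exact-1 assertions are made at two
  decimals;
- **ESS** with Geyer's initial-positive-sequence truncation of the
  autocorrelation sum (computed by FFT), averaged across chains; antithetic
  chains can exceed the raw draw count and are not clipped.

**Adjustment report** (`adjustedEffectSizes()`): per cell, the original
*d*, the Bayesian-adjusted *d* (posterior mode by default; the mean shrinks
at least as much on skewed posteriors), and the absolute adjustment; plus a
one-sided *t*-test of mean adjustment > 0 and Pearson correlations of the
adjustment with study size (expected negative) and with $\omega$ (expected
positive). Correlations pool all study-by-region cells jointly, matching
single-number reporting; degenerate inputs (zero-variance adjustments or
correlates) are flagged rather than silently returned as NaN.

## The synthetic-data generator

Real multi-site subject-level data of this kind are not redistributable, so
`simulateCohort()` generates cohorts with known ground truth. The reference
configuration (`defaultMultistudyConfig()`) mirrors the consortium-scale
shape: 21 studies, 903 cases and 996 controls (1,899 subjects), per-study
sizes from 20 to 250, and 150 regional measures (2 hemispheres x 34
Desikan-Killiany parcels for thickness and surface area, plus 14
subcortical volumes). Per study and region a true standardized effect
$\delta_{i,r} \sim N(M_{true}, \Sigma_{true}^2)$ is drawn (defaults
$-0.1$ and $0.1$: small, mostly negative case deficits) and injected on the
standardized scale ($\delta \cdot \text{residualSd}$), so the truth is
directly comparable to the estimated *d*. Covariates are stand-ins chosen
once — age $\sim U(18, 60)$, ICV $\sim N(1.5\times10^6, (1.5\times10^5)^2)$,
male fraction 0.6 (substance-dependence cohorts skew male), mild age/sex/ICV
coefficients — since no per-study covariate distributions are published for
the real data. Additive site offsets ($\pm 0.12$ on a residual SD of 0.15)
and multiplicative noise factors (0.85-1.2) create the batch structure that
harmonization must remove. Diagnosis-by-sex cells are kept at $\ge 4$
subjects whenever a group has $\ge 8$, so the subsampler's stratification
never degenerates under defaults.

What the generator does *not* emulate: missing data, scanner physics,
non-Gaussian measure distributions, covariate-by-diagnosis interactions,
substance-specific subgroups, and site differences in covariate
distributions. Passing tests therefore demonstrate correctness of the
machinery under the stated generative assumptions, not robustness to every
feature of real multi-site data.

## Numerical choices and test scale

Tolerances in the test-suite oracles are tied to Monte-Carlo standard
errors (via ESS) wherever a closed form exists — e.g. the sampler is
checked against the exact joint-Gaussian posterior obtained by fixing
$\tau$ and $T$, within 3 MCSE. Simulation-based calibration draws all
parameters from the fitting priors and checks 95% HDI coverage for $M$
across 200 replicates. The routine test suite runs reduced problem sizes
chosen to keep the full suite in a couple of minutes — 2-8 regions,
subsampling repetitions in the tens to hundreds, chains of a few thousand
iterations — while the consortium-scale settings (21 studies, 4 x 100,000
iterations, 1,000 repetitions) are exercised where the claim depends on
them (ESS floor, PSRF, the $\omega$ scaling). Degenerate inputs (constant
vectors, single chains, single batches, infeasible subsampling profiles,
rank-deficient designs) raise explicit errors or flags rather than NaN.

## Limitations

Regions are fitted independently (no spatial pooling); the likelihood is
normal (justified empirically by the Lilliefors checks on subsampled
distributions, not guaranteed for arbitrary data); the hierarchy has no
meta-regression structure (covariate-dependent $M$); and the adjustment
correlations are descriptive, not causal decompositions. The
study-specific $\omega_i$ is treated as known in the model — its own
subsampling uncertainty (a few percent at 1,000 repetitions) is not
propagated.
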