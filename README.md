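# hbshrink

Hierarchical Bayesian recalibration of multi-study case-control effect
sizes.

Small case-control studies — the norm in structural neuroimaging — yield
noisy and often inflated Cohen's *d* estimates. When a collection of
comparable studies exists (e.g. site-level cohorts comparing
substance-dependent and non-dependent participants on regional brain
measures), each study's estimate can be recalibrated by partial pooling.
`hbshrink` is for biostatisticians and imaging researchers who want that
recalibration as a reproducible pipeline rather than a one-off analysis.

## The model

For one regional measure, with $y_i$ the observed Cohen's *d* of study
$i = 1,\dots,K$ and $\omega_i$ its empirically estimated sampling SD:

$$
y_i \sim N\!\big(\mu_i,\ \omega_i^2/\tau\big),\qquad
\mu_i \sim N\!\big(M,\ 1/T\big),\qquad
M \sim N(0, 10),\qquad \tau, T \sim \mathrm{Gamma}(a,b),
$$

with the Gamma prior on the precisions specified by mode 1 and SD 10.
Every full conditional is conjugate, so the posterior is approximated by an
exact Gibbs sampler (compiled kernel, reproducible under `set.seed()`).
The posterior mode of $\mu_i$ is the study's *Bayesian-adjusted* effect
size; shrinkage toward the overarching mean $M$ is strongest for small,
noisy studies.

Around the sampler, the package provides:

- per-study effect sizes from OLS of each measure on diagnosis, age, sex
  and intracranial volume, with
  $d = t\,(n_1+n_2)/(\sqrt{n_1 n_2}\sqrt{df})$;
- parametric empirical-Bayes (ComBat) harmonization of study batch effects;
- tailored $\omega_i$ by stratified subsampling of the harmonized pool
  (diagnosis-by-sex cell counts matched, 1,000 repetitions), with
  Lilliefors normality checks;
- posterior mode / mean, 95% highest-density intervals, split-chain
  Gelman-Rubin and Geyer-truncated effective sample sizes;
- adjustment-magnitude analyses (one-sided *t*-test, correlations of the
  adjustment with study size and with $\omega$);
- a synthetic multi-study generator with known ground truth mirroring a
  21-study consortium (903 cases / 996 controls, 150 regional measures).

## Worked example

```r
library(hbshrink)

cfg  <- defaultMultistudyConfig(regions = standardRegionNames()[1:4])
sim  <- simulateCohort(cfg)              # 21 studies, known ground truth
harm <- combatHarmonize(sim$cohort)      # remove study batch effects
es   <- computeEffectSizes(harm)         # 21 x 4 observed Cohen's d
om   <- estimateOmega(harm, studyProfiles(harm), reps = 1000, seed = 2)
fits <- fitAllRegions(es, om, chains = 4, iters = 20000, seed = 3)

posteriorSummary(fits[["lh_bankssts_thickness"]], c("M", "mu[1]", "mu[21]"))
#>                  region parameter    mode    mean hdi_low hdi_high rhat   ess
#> 1 lh_bankssts_thickness         M -0.1743 -0.1762  -0.299  -0.0611    1 24390
#> 2 lh_bankssts_thickness     mu[1]  0.0751  0.0252  -0.335   0.3630    1  6791
#> 3 lh_bankssts_thickness    mu[21] -0.1443 -0.1435  -0.260  -0.0332    1 36385

adjustedEffectSizes(es, fits, om)
#> AdjustmentReport: 84 study x region cells (point estimate: mode)
#>   adjustment range: [7.48e-05, 0.141]
#>   one-sided t-test of mean adjustment > 0: t = 6.898, p = 4.8257e-10
#>   r(adjustment, n) = -0.592; r(adjustment, omega) = 0.767
```

Reading the output: the overarching mean for this region is estimated at
mode $-0.17$ (95% HDI $[-0.30, -0.06]$) — a small case deficit. Study 1
(20 subjects) observed $y_1 = 0.20$; its posterior mode is pulled down to
$0.08$, while study 21 (250 subjects, $y_{21} = -0.14$) barely moves. Across all cells the
adjustment magnitude correlates negatively with study size and positively
with the subsampled sampling SD: small, noisy studies are recalibrated the
most. The `rhat`/`ess` columns confirm converged, well-mixed chains.

`runPipeline(runConfig(...))` chains all stages and writes every table in
its documented CSV schema plus a JSON run log;
`inst/scripts/recalibrate.R` exposes the same stages on the command line
(`simulate`, `validate`, `harmonize`, `effects`, `omega`, `run-all`).

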