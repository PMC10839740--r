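---
title: "Hierarchical Bayesian normative modelling of cortical thickness with transfer to unseen scanners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian normative modelling of cortical thickness with transfer to unseen scanners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Longitudinal developmental MRI studies almost inevitably mix scanners:
hardware is replaced between measurement waves, software is upgraded, and
cohorts are pooled across sites. Raw regional cortical thickness (CT) then
confounds biological change with scanner effects, so the thickness values of
one child measured at three waves on two scanners are not directly
comparable. Normative modelling addresses this by regressing CT on age and
sex across a large reference population and expressing each new scan as a
deviation (z) score relative to the predicted distribution for that
scanner, sex and age. If the scanner effects are modelled well, the z-scores
are free of them and comparable across waves.

`hbrnorm` implements this workflow end to end:

1. a **synthetic cohort generator** with full ground-truth bookkeeping,
   standing in for non-public multi-site reference and longitudinal target
   data;
2. a per-region **hierarchical Bayesian regression (HBR)** normative model
   with batch effects on intercepts, slopes and residual variances;
3. **transfer** of the fitted hyperparameter posterior to unseen scanners as
   informed priors, estimated from small adaptation sets;
4. **deviation scores** and extreme-deviation group contrasts;
5. **evaluation and validation**: explained variance, SMSE and MSLL, an
   adaptation-sample-size sweep, within-subject stability, the
   overlapping-age-window comparison and the wave-vs-scanner batch
   configuration comparison.

## The model

For region $r$ (fitted independently per region; the subscript is dropped),
scan $i$ belonging to batch $b(i)$:

$$y_i = \alpha_{b(i)} + \beta_{b(i)} x_i + \epsilon_i,\qquad
\epsilon_i \sim N(0, \sigma_{b(i)}^2),$$

where $x$ is age standardized by the reference-training mean and SD (the
transform is frozen into the model: prior scales must not depend on the
covariate's units, and the transfer step must see the same covariate
scale). A batch is one cell of site × sex in the reference stage and of
(wave or scanner) × sex in the target stage. Batch parameters are partially
pooled:

$$\alpha_b \sim N(\mu_\alpha, \tau_\alpha^2),\quad
\beta_b \sim N(\mu_\beta, \tau_\beta^2),\quad
\log\sigma_b \sim N(\mu_{\log\sigma}, \tau_{\log\sigma}^2).$$

Parameterizing the noise as $\log\sigma_b$ with a Normal hierarchical prior
guarantees positivity and yields a transferable "variance of the variance"
hyperparameter ($\tau_{\log\sigma}$). The six hyperparameters get Normal
priors (half-normal or zero-truncated Normal for the $\tau$'s).

**Default weak hyperpriors** (cold-start fits): with $m$ and $s$ the sample
mean and SD of the region's thickness values,
$\mu_\alpha \sim N(m, 10s)$, $\mu_\beta \sim N(0, 10s)$,
$\mu_{\log\sigma} \sim N(\log s, 2)$,
$\tau_\alpha, \tau_\beta \sim \mathrm{HalfNormal}(5s)$,
$\tau_{\log\sigma} \sim \mathrm{HalfNormal}(1)$. Every location and scale
(except the unit-free log-SD level) is proportional to $s$, which makes the
whole pipeline — and in particular the deviation scores — exactly invariant
to the measurement unit (mm vs µm); the suite checks this property
directly.

### Sampling

The posterior is explored by Metropolis-within-Gibbs on per-batch
sufficient statistics, so iteration cost is independent of the number of
scans:

- $(\alpha_b, \beta_b)$: jointly conjugate bivariate Normal, vectorized
  across batches;
- $\log\sigma_b$: vectorized random-walk Metropolis (three sub-steps per
  scan; step sizes adapted during warmup toward a 0.44 acceptance rate);
- $\mu_\cdot$: conjugate Normal; $\tau_\cdot$: slice sampling on
  $\log\tau$;
- an ancillarity–sufficiency interweaving step re-draws each
  $(\mu, \tau)$ pair under the non-centered parameterization
  ($\theta_b = \mu + \tau\eta_b$ with $\eta_b$ held fixed), which breaks
  the hierarchical funnel that otherwise makes the $\tau$'s mix slowly.
  For the Gaussian levels this re-draw is an exact truncated bivariate
  Normal; for the log-SD level, $\mu$ and $\log\tau$ are slice-sampled.

Defaults are 2 chains × 1,000 retained draws after 1,000 warmup iterations
with a fixed seed; convergence is gated on split-chain $\hat R < 1.05$ for
every stored parameter, and a model failing the gate is returned with its
convergence flag false and a warning rather than an error. The
sweep/replicate procedures default to 1 chain × 300/300, which these small
conjugate-blocked adaptation fits tolerate well (the suite cross-checks the
sampler against a closed-form single-batch posterior and an independent
JAGS fit).

### Prediction and deviation scores

For a scan with standardized age $x$ in batch $b$:

$$\hat y = \mathbb{E}[\alpha_b + \beta_b x], \qquad
s^2 = \mathrm{Var}(\alpha_b + \beta_b x) + \mathbb{E}[\sigma_b^2],
\qquad z = (y - \hat y)/s .$$

The predictive SD combines posterior parameter uncertainty with the
posterior mean noise variance (a full Gaussian predictive approximation);
with small adaptation sets the parameter term is not negligible for tail
calibration. A noise-only mode (`sd_mode = "noise_only"`) exists for
sensitivity analysis. One consequence worth knowing: because $s$ slightly
exceeds the generative noise SD at finite adaptation size, the fraction of
held-out Gaussian controls with $z > 2$ sits just *below* the plug-in
standard-normal tail of 2.28% (about 2.2% at 100 scans per batch in the
suite's own runs); empirical studies that report ~2.5% are seeing real-data
tail heaviness on top of this.

## Transfer to unseen scanners

`hyperposterior_summary()` reduces the reference posterior to per-region
means and SDs of the six hyperparameters; `transfer_priors()` turns these
into Normal (zero-truncated for $\tau$) priors. Only means and SDs travel —
the approximation that makes the model portable across analysis sites
without sharing subject-level data; full-covariance transfer would be a
natural extension. During adaptation the hyperparameters are re-sampled
under these informed priors jointly with the new-batch parameters, so
reference uncertainty propagates; `freeze_hypers = TRUE` provides the
cheaper point-estimate mode for comparison, and `prior_only = TRUE` scores
batches with no data at all from the hyperprior means.

Adaptation sets are drawn by `sample_adaptation_set()`, which *first*
withholds the validation scans — subjects measured at all three waves, and
wave-1 scans inside the overlapping age window — and excludes
clinical-group scans (the normative model must be adapted on the normative
population), then samples `n_per_batch` scans per batch. The withholding is
built into the sampler rather than left to callers, so validation leakage
is structurally impossible. The `age_uniform` strategy bins each batch's
age range into `n_per_batch` equal-width bins and draws one scan per
nonempty bin, which covers peaked age distributions (like the generator's
triangular wave-2 distribution) more evenly than simple random sampling.

The default batch definition for the target is per wave (× sex), not per
scanner: when two waves on one scanner differ by, e.g., a software upgrade,
a per-scanner batch absorbs the average of the two waves and leaves
opposite-signed median-z offsets in each; per-wave batches absorb each
wave's own shift. `batch_config_comparison()` reproduces exactly this
contrast on synthetic data with a nonzero `wave3_offset`.

## The synthetic cohorts

The generator emulates the statistical structure the analysis assumes,
with the realized truth recorded for recovery and calibration tests:

- **Reference**: 20 sites × 150 subjects (one scan each), 10 regions, site
  age windows of 20–50 years spread so their union covers ages 5–100 and
  site 1 always spans the 6–17 developmental range. Batches are site × sex
  with heterogeneity $\tau_\alpha = 0.08$ mm, $\tau_\beta = 0.0015$
  mm/year, $\tau_{\log\sigma} = 0.12$.
- **Regions**: intercepts 2.9–3.6 mm, slopes −0.008 to −0.018 mm/year
  (cortex thins with age), areas spread geometrically over 150–2500 units
  with residual SD $\sigma_{0}\,(\text{area}/\overline{\text{area}})^{-0.3}$
  around $\sigma_0 = 0.16$ mm — smaller parcels are noisier, so evaluation
  metrics correlate with area. A sex offset of 0.03 mm enters the batch
  intercepts.
- **Target**: three waves of (1600, 2600, 2400) scans — the shape of a
  large longitudinal cohort at desk scale — on two scanners (waves 2 and 3
  share one), age windows [6, 10.7], [8.6, 12] (triangular, peaked near 10)
  and [13, 17], an overlapping window [8.6, 10.7] populated in waves 1 and
  2, 15% of wave-1 subjects measured at all three waves with strictly
  increasing ages, 5.4% preterm subjects with mixed-sign per-region mean
  shifts (±0.12–0.25 mm), and optional deterministic wave-3 and per-scanner
  intercept offsets for controlled experiments.
- **Subject effect**: a random intercept $u_j$ (SD $\omega = 0.08$ mm)
  shared across a subject's waves. It is deliberately *not* in the fitted
  model: cross-sectionally it folds into the residual variance the model
  estimates, while within a subject it is constant — which is precisely
  why deviation scores of one subject are stable across waves even though
  raw thickness declines and jumps between scanners.

What the generator does **not** emulate: non-Gaussian residuals, nonlinear
age trajectories, motion/QA artifacts, spatial correlation between regions,
or dose–response structure in the preterm group. Passing tests therefore
demonstrate correct inference under the stated model, not robustness to
real-data violations of it; in particular the extreme-deviation tail on
real data can sit above the Gaussian expectation.

## Evaluation metrics

All metrics use population (1/n) moments. For observed $y$, predictive
mean $\hat y$ and SD $s$:

- explained variance $= 1 - \mathrm{Var}(y - \hat y)/\mathrm{Var}(y)$
  (mean-removed residual variance);
- SMSE $= \overline{(y - \hat y)^2} / \mathrm{Var}(y)$ — 1 for the trivial
  mean predictor;
- MSLL $=$ mean Gaussian negative log predictive density minus that of a
  trivial Gaussian fitted to the **adaptation/training** targets of the
  same region (never the test targets); negative is better.

The within-window scanner comparison uses a pooled-variance Student t-test
(df $= n_1 + n_2 - 2$), matching how such comparisons are conventionally
reported.

## The adaptation-size sweep

`sweep_adaptation_size()` fixes, per batch, a pool of up to 300 control
scans (after withholding); everything outside the pool is the common fixed
test set, so every sweep cell is scored on identical rows. For each size in
{5, 10, 15, 25, 50, 75, 100, 150, 200, 300} and each of 10 replicates it
samples an adaptation set from the pool, adapts, and evaluates. Two
summaries matter: the smallest size whose mean MSLL is within 0.01 nats of
the size-300 mean (the plateau criterion — an operational definition, since
"plateau" is otherwise qualitative), and the smallest size at which mean
MSLL goes negative (beats the trivial predictor). On the default synthetic
cohorts the plateau is reached by ~100 scans per batch and MSLL is already
negative at the smallest sizes — few-shot transfer works because the
informed priors carry the slope and variance structure, and the adaptation
set mostly localizes the intercept.

## Numerical choices and degenerate inputs

- Hyperposterior SDs are floored at $10^{-6}$ of the corresponding mean
  scale before building transfer priors, so a degenerate draw set can
  never produce a zero-width prior.
- Batches with fewer than 3 scans are rejected at fit time; empty batches
  are legal only in prior-only adaptation.
- Zero-variance targets make explained variance and SMSE undefined; they
  return `NA` with a warning rather than infinities.
- Model JSON stores numbers at 17 significant digits; a reloaded model
  reproduces predictions bit-identically (asserted in the suite).
- All randomness derives from user-visible integer seeds; identical
  config + seed reproduces byte-identical cohorts, draws and reports.

## Problem sizes used by the test suite

The packaged checks run the full pipeline at the default scale above for
tail calibration, parameter recovery and the sweep; the per-seed replicate
checks (site-effect removal across 20 seeds, transfer benefit at 25 scans
per batch across 20 seeds, and the batch-configuration contrast) use a
3-region, 10-site reference and 600-scan waves with reduced sampler
settings — the package's chosen desk-scale conditions for experiments
that are repeated twenty times. The site-effect-removal experiment is a
controlled injection: between-batch intercept heterogeneity is switched
off and a deterministic 0.1 mm scanner offset switched on, so the injected
offset *is* the between-scanner difference being removed.

## Known limitations

- Linear-in-age mean only; no splines or non-Gaussian likelihoods, so the
  model is appropriate for age windows where thickness decline is
  approximately linear.
- Regions are modelled independently; no spatial coupling.
- Transfer carries independent Gaussian approximations of the
  hyperposterior, not its joint shape.
- Extreme-deviation contrasts are descriptive percentages; no
  multiple-testing correction is applied across regions.
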