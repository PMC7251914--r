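---
title: "Modelling aggregate Alzheimer's disease progression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling aggregate Alzheimer's disease progression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`admbma` works on *aggregate* clinical-trial data: one placebo arm per
study, each contributing the reported mean change from baseline in the
11-item ADAS-cog scale (0-70 points, higher = worse) at a handful of
protocol visit times. The placebo response decomposes into natural disease
progression and a transient placebo effect,

$$S(t) = \alpha\,t + \mathrm{Pbo}(t), \qquad
  \mathrm{Pbo}(t) = \frac{\beta\,t}{\mathrm{ET}_{50} + t},$$

with $\alpha$ the linear progression rate (points/week; annualized by
$\times 52$), $\beta$ the maximum placebo extent (points, negative =
transient improvement) and $\mathrm{ET}_{50}$ the half-time of the placebo
effect (weeks). Sigmoid Emax, exponential and inverse-Bateman alternatives
for $\mathrm{Pbo}(t)$ are kept for structural selection by AIC. The
exponential form is parameterized as $\beta(1 - e^{-k_{on}t})$ and the
inverse Bateman as a difference of exponentials rescaled so that $\beta$
remains the extremum of the curve; the literature names these alternatives
without writing them down, and these parameterizations keep $\beta$
interpretable across forms. Failure of the inverse-Bateman offset rate to
converge on short-duration designs is expected behaviour and is reported,
not raised.

Studies differ systematically: a bounded-scale ("inverse-U") factor in the
baseline ADAS-cog score and a power factor in baseline age multiply the
typical rate,

$$\alpha_i^{typ} = \alpha_{typ}
  \left(\frac{A_i}{A_{ref}}\cdot\frac{70 - A_i}{70 - A_{ref}}\right)^{\theta_A}
  \left(\frac{age_i}{age_{ref}}\right)^{\theta_{age}},$$

with reference values $A_{ref} = 24.5$ and $age_{ref} = 73.5$ (the medians
of the emulated literature). The inverse-U kernel $A(70-A)$ peaks at 35
points — mid-scale populations progress fastest — and every covariate form
equals 1 exactly at the reference. The ceiling constant 70 is a named,
overridable `scale_max`.

Study-level heterogeneity beyond the covariates uses proportional random
effects, $\alpha_i = \alpha_i^{typ}(1+\eta_{\alpha,i})$ and
$\beta_i = \beta_{typ}(1+\eta_{\beta,i})$, with
$(\eta_\alpha, \eta_\beta) \sim N(0, \Omega)$. The proportional (rather
than exponential) form deliberately lets individual studies change sign:
placebo arms occasionally worsen beyond the trend (nocebo-like behaviour).
The half-time carries no random effect — its empirical-Bayes shrinkage in
designs of this sparsity is essentially complete, so its inter-study
variance is fixed at zero. A reported mean over $n$ subjects carries
residual noise $\varepsilon/\sqrt{n}$ with
$\varepsilon \sim N(0, \delta^2)$, which is what makes small historical
arms appropriately less informative.

## Estimation

The marginal likelihood integrates the bivariate $\eta$ out of each
study's contribution. Because $\eta$ enters only through $(1+\eta)$
factors on $\alpha$ and $\beta$, the conditional mean is *linear* in
$\eta$; the inner Newton step lands exactly on the conditional mode and
the Laplace approximation equals the exact Gaussian marginal. Two
consequences worth stating:

* FOCE-with-interaction and Laplace coincide here (the interaction term
  exists only for residual models whose variance depends on $\eta$; ours
  is additive), so `method = "foce"` is an alias.
* The independent check is real: `method = "agq"` re-derives the integral
  by generic adaptive Gauss-Hermite tensor quadrature (numeric inner mode
  search, numeric Hessian, 9+ nodes per dimension) without touching the
  linear-algebra shortcut, and the two agree to machine precision on
  randomized instances.

The objective keeps the full $-2\log L$ constant (the $2\pi$ terms are not
dropped, unlike some estimation software); every comparison the package
makes is a difference, so only the recorded convention matters. The 2x2
covariance $\Omega$ is optimized through its Cholesky factor (log
diagonals), guaranteeing positive semidefiniteness; half-times, rate
constants and $\delta$ are log-transformed; $\alpha$, $\beta$ and the
$\theta$s are unconstrained. Default starts come from a pooled weighted
regression (slope), the early-time mean deviation ($\beta$), 8 weeks for
$\mathrm{ET}_{50}$, and 0.2/0.5 for the $\omega$s; optional multi-starts
jitter by factors up to 3 using a deterministic pattern so that fits are
reproducible without touching the global RNG. Convergence uses a relative
objective tolerance of 1e-6 and at most 500 outer iterations. Screening
decisions must keep that tolerance: a warm-started candidate fit begins
with every incumbent parameter at a stationary point and only the new
$\theta$ carrying gradient, and looser settings can stall on that plateau
and understate the OFV drop by several points. Bootstrap replicate fits,
whose start is near the optimum in every coordinate, safely relax to 1e-4.

Standard errors come from the finite-difference observed-information
Hessian on the transformed scale, delta-method-mapped to the natural
scale. The random-effect correlation $\rho$ is reported without a standard
error (it is a derived quantity of the Cholesky parameterization, and the
reference analysis likewise reports it bare). Empirical-Bayes estimates
$\hat\eta_i$ and conditional standard errors fall out of the same per-study
2x2 algebra, with the shrinkage statistic $1 - SD(\hat\eta)/\omega$
attached.

## Covariate screening

Candidates pass a coverage gate first: a covariate reported in fewer than
70% of studies cannot be screened reliably and is excluded with a reason.
Forward inclusion requires an OFV drop strictly greater than 3.84
($\chi^2_1$, $P < 0.05$); backward elimination retains a covariate only if
its removal raises the OFV by more than 6.64 ($P < 0.01$). Each inclusion
costs one degree of freedom (every form here has a single $\theta$).
Forward rounds re-rank all remaining candidates each time (the reference
procedure does not state whether it re-ranked; we do, and say so).

One deliberate deviation from a pure max-drop rule: when *several
functional forms of the same covariate* clear the gate, the
earliest-listed form wins rather than the numerically best one. The
default candidate list puts the inverse-U form of baseline ADAS-cog ahead
of its power form, encoding the prior, boundary-aware preference for
bounded scales ("use the inverse-U when possible"). The two forms are
near-collinear over the observed range of study means (13-40 points), so
their OFV separation is small and noisy — selection between them by OFV
alone is close to a coin flip, while the plausibility preference is stable
and matches how the reference analysis argued its choice. Distinct
covariates still compete by OFV drop, and ties within 1e-6 break by list
order. Candidate fits warm-start from the incumbent optimum for speed; the
final model is refitted cold as a cross-check.

## The synthetic literature

`default_config()` emulates the published literature of 140 placebo arms:

* baseline ADAS-cog $\sim$ truncated $N(24.5, 5^2)$ on [13.1, 39.3],
  baseline age $\sim$ truncated $N(73.5, 4^2)$ on [58.0, 81.7] — medians
  and ranges match the reported cohort; the truncated-normal *shape* and
  the age/ADAS SDs are modelling choices, as no distribution was reported;
* arm size log-normal with median 102, $\sigma_{\log} = 0.8$, truncated to
  [11, 746] (the inclusion rule requires placebo arms larger than 10);
* visit schedules built from the protocol grid {4, 8, 12, 18, 24, 26}
  weeks, optionally extended by {39, 52} or {39, 52, 78, 104} with weights
  0.45/0.35/0.20 — note the real literature *reports* fewer time points
  per publication (about 3.3 on average) than a protocol measures, so the
  synthetic arms are somewhat richer per study than digitized ones;
* region frequencies (56, 56, 15, 5, 5, 3)/140; publication era 64:76
  pre/post-2008 with add-on designs only post-2008 (27/76);
* generating parameters = the published final-model estimates, including
  $\omega_\alpha = 14.8\%$, $\omega_\beta = 72.5\%$, $\rho = -0.717$,
  $\delta = 5.64$ points.

Each study consumes a deterministic substream of the master seed, so
extending `n_studies` never perturbs earlier studies. The generator writes
a truth sidecar (per-study $\eta$ and parameters) for recovery tests.

What the generator does *not* emulate: digitization error from reading
values off figures, dropout-driven drift in per-visit $n$, within-study
patient-level variability, correlated multi-arm publications, and the real
(unreported) joint distribution of visit schedules. Passing tests
therefore demonstrate that the estimation and screening machinery is
correct and calibrated *under the model's own assumptions*, not that the
model is true of any particular literature.

## Evaluation and subgroup analysis

The bootstrap resamples whole study arms with replacement (the study is
the random-effect unit; resampling observations would destroy the
within-study correlation), refits each replicate warm-started at the
original estimates with one jittered fallback, and reports per-parameter
medians and 2.5/97.5 percentile intervals. Failures are counted, never
silently dropped; more than 50% failures flags the result unreliable.

The VPC simulates the observed design (same studies, times, arm sizes,
covariates) from the fitted parameters and compares observed
2.5/50/97.5% quantiles per time bin with the 95% simulation envelope of
each quantile. Aggregate data cluster on protocol weeks, so bins default
to exact nominal times; a width-based binning exists for irregular data.
Residual diagnostics report population and individual predictions,
$\sqrt{n}$-weighted residuals, and conditional weighted residuals from the
first-order expansion about the conditional mode (exact here, again by
linearity; no claim of numerical identity with other software's CWRES).

The subgroup analysis is the two-step procedure: (1) per-study
empirical-Bayes estimates with conditional standard errors; each study's
rate is then rescaled to the reference covariate profile by *dividing out
its covariate factor* ($\alpha^*_i = \alpha_i / C_i$, standard errors
scaled identically) — the reconstruction of "inverse calculation of the
covariate functions", validated by reproducing the published six-month
typical changes; (2) DerSimonian-Laird random-effects pooling of a single
mean per stratum (inverse-variance weights $1/(SE^2+\tau^2)$, Wald 95%
CI), delegated to `metafor::rma(method = "DL")`; REML is available. The
estimator choice is ours — the reference names only "a random effect
meta-analysis of a single mean". $\beta$ pools uncorrected because no
covariate enters the final model on it, and stratum time-course curves use
the global half-time. Typical-curve confidence bands propagate pooled-mean
uncertainty only (not between-study $\tau^2$): the bands answer "where is
the stratum mean", which is how the reference figure reads; a draw-based
flag could re-add $\tau^2$ if predictive bands were wanted.

## Numerical choices and degenerate inputs

* $\omega = 0$ (either or both): the kernel drops the corresponding
  dimension analytically; both zero reduces to the weighted
  least-squares deviance.
* Transformed parameters are box-bounded in $[-12, 12]$ on log scales to
  keep $\Omega^{-1}$ finite near degeneracy.
* Baseline rows ($t = 0$, change 0) are not stored: the change from
  baseline at $t=0$ is identically zero and carries no information under
  the $\sqrt{n}$-weighted residual model.
* Observations beyond 104 weeks are excluded by `filter_modeling_window()`
  before fitting (long-term extrapolation would bias the linear slope);
  the filter is idempotent and logs dropped arms.
* Unknown region labels map to an `"Unlabeled"` stratum instead of
  erroring, so subgrouping is optional metadata.
* The imputation flag (OC/LOCF) is stored but unused analytically,
  mirroring how the source data were collected.
* The reference text states a progression-rate inflection point of 35.5
  ADAS-cog points; the inverse-U function as printed peaks at
  $70/2 = 35$ regardless of $\theta$. The function is implemented as
  printed and the 35.5 treated as an internal inconsistency of the source,
  not a calibration target.

## Problem sizes used by the test suite

Simulation-heavy checks are scaled to keep the suite practical while
leaving the study conditions (140 studies, published variance components)
untouched where they are the point of the check: parameter recovery and
screening calibration use the full 140-study default (20 replicates per
calibration arm); the likelihood oracle uses 100 randomized 5-study
instances; bootstrap-coverage outer replicates use 40-study sets at
B = 100 (20 outer replicates) — the coverage property does not depend on
the study count; the VPC self-consistency check uses one 140-study set
with 400 simulations. The published evaluation used B = 1000 bootstrap
replicates and 1000 VPC simulations; `bootstrap_model()` and `vpc()`
default to 1000 accordingly.

## Known limitations

* The unit of inference is the study arm; nothing here models
  patient-level trajectories.
* ET50 is weakly identified at literature scale (the reference reports
  ~50% RSE; simulation-refit experiments here wander by ±1-2 weeks at
  140 studies) — its recovery checks use correspondingly wide tolerances.
* $\rho$ estimates are noisy and can pin near $\pm 1$ on resampled or
  small datasets; the Cholesky parameterization keeps such fits
  well-defined.
* The screening power results (about 80% exact recovery of the published
  covariate set, about 90-95% empty selections under the null at these
  gates) are properties of the emulated design and the 3.84/6.64
  thresholds, not universal constants.
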