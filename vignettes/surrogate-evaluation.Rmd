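---
title: "Evaluating surrogate endpoints with randomized and real-world evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating surrogate endpoints with randomized and real-world evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surrosyn)
```

## The problem

A surrogate endpoint — here progression-free survival (PFS) — is useful
only if treatment effects on it reliably predict treatment effects on the
final clinical outcome — here overall survival (OS). Trial-level
surrogacy is assessed across studies: each study $i$ contributes a pair
of estimated log hazard ratios $(Y_{1i}, Y_{2i})$ with standard errors
$(\sigma_{1i}, \sigma_{2i})$, and the question is how strongly the *true*
effects $(\delta_{1i}, \delta_{2i})$ are associated across studies. When
few randomized trials exist, the association is estimated imprecisely;
this package implements a workflow for widening the evidence base with
real-world studies — comparative cohorts (cRWE) and matched pairs of
single-arm cohorts (sRWE) — while accounting for their extra risk of
bias.

## Models

All three models share the within-study likelihood

$$\begin{pmatrix} Y_{1i} \\ Y_{2i}\end{pmatrix} \sim
N\!\left(\begin{pmatrix}\mu_{1i}\\ \mu_{2i}\end{pmatrix},
\begin{pmatrix}\sigma_{1i}^2 & \rho_{wi}\sigma_{1i}\sigma_{2i}\\
\rho_{wi}\sigma_{1i}\sigma_{2i} & \sigma_{2i}^2\end{pmatrix}\right),$$

which the implementation factorises as $Y_{1i}$ and $Y_{2i}\mid Y_{1i}$ —
the same joint distribution, but it lets the sampler impute a missing
$Y_{2i}$ directly, which is exactly what take-one-out cross-validation
needs. The within-study correlation $\rho_{wi}$ is rarely published; each
study with unknown $\rho_{wi}$ receives an independent Uniform(0, 1)
prior, and a fixed value (e.g. the bootstrap estimate 0.52) can be
imposed for sensitivity analysis via `prior_config(rho_w_fixed = )`.

**Daniels–Hughes (`model = "dh"`).** True surrogate effects are
independent fixed effects, $\delta_{1i} \sim N(0, 10^4)$, with a linear
conditional model
$\delta_{2i}\mid\delta_{1i} \sim N(\lambda_0 + \lambda_1\delta_{1i}, \psi_2^2)$.
A perfect surrogate satisfies $\lambda_0 = 0$, $\lambda_1 \neq 0$,
$\psi_2^2 = 0$; `evaluate_criteria()` applies the credible-interval
versions of these rules.

**BRMA product normal formulation (`model = "brma"`).** The true effects
are exchangeable: $\delta_{1i} \sim N(\eta_1, \tau_1^2)$ with the same
conditional regression, and the product-normal identities
$$\lambda_1 = \rho\,\tau_2/\tau_1, \qquad
\psi_2^2 = \tau_2^2 - \lambda_1^2\tau_1^2$$
expose the between-studies correlation $\rho$ and $R^2 = \rho^2$.
`transform_brma_params()` is the exact algebraic map, and every fit
satisfies the identities draw by draw. The pooled OS effect is reported
as the derived quantity $d_2 = \lambda_0 + \lambda_1\eta_1$ (the marginal
mean implied by the conditional regression); it is labelled derived
because the reporting convention for the pooled final-outcome effect is
a modelling choice, not part of the likelihood.

**Bias-adjusted BRMA (`model = "brma_bias"`).** Non-randomized designs
get additive study-level bias in the within-study means: cRWE studies
$\alpha_{ji} \sim N(\alpha_j, \sigma_{\alpha j}^2)$ and matched sRWE
studies $\beta_{ji} \sim N(\beta_j, \sigma_{\beta j}^2)$ for outcome
$j \in \{1, 2\}$, with vague normal priors on the means. Priors for the
bias-term standard deviations are not pinned down by convention; the
default Uniform(0, 2) matches the other SD priors and is exposed in
`prior_config(bias_sd_upper = )`.

### Priors and sensitivity switches

Location parameters get $N(0, 10^4)$; standard deviations get
Uniform(0, 2), with Uniform(0, 100) available as a sensitivity switch
(`psi2_upper`, `tau_upper`); $\rho \sim$ Uniform($-1$, 1). All switches
change only the `prior_config`, never the code path, so sensitivity
analyses are guaranteed to run the same model.

### Inference and convergence

Models are fitted by Gibbs sampling in JAGS. The reference configuration
is 150,000 iterations with 50,000 burn-in; two chains are run by default
so that convergence can be assessed automatically by split $\hat R$
(< 1.05) and effective sample size (> 400) on every reported scalar. A
fit failing these checks carries `converged = FALSE` and a warning — it
is flagged, never silently accepted. Point estimates are posterior means
except for right-skewed variance-type parameters ($\psi_2^2$, $R^2$,
$\tau_1$, $\tau_2$, bias SDs), which are reported as medians; the
general rule (`summarize_posterior(style = "auto")`) switches to the
median when $|\text{mean} - \text{median}| > 0.1\,\text{IQR}$. Credible
intervals are equal-tailed empirical 2.5%/97.5% quantiles; a
highest-density variant is deliberately not offered, to keep reported
intervals unambiguous.

## Matching single-arm studies

Single-arm studies provide no comparison, so treatment-like and
control-like cohorts are paired by aggregate similarity. For profiles
$j, k$ the distance is the weighted average of scaled covariate
differences
$$\Delta_{tot}[j,k] = \frac{\sum_c w_c\,\Delta_c[j,k]}{\sum_c w_c},
\qquad \Delta_c = \frac{|x_{cj} - x_{ck}|}{\max_c - \min_c} \in [0,1].$$
The default `covariate_spec()` carries the five covariates reported by
all studies in the colorectal-cancer application — treatment line
(weight 2, range 1–3), median age (2, 18–100), mean ECOG/WHO performance
score (2, 0–3), colon-vs-rectum proportion (2, 0–1), and proportion
female (1, 0–1). The maximum between-arm distance observed in a
reference two-arm design (`derive_threshold()`: RCTs for the primary
analysis, cRWE for sensitivity) serves as the maximum allowable
distance, with a manual override for published round values.
`select_matches()` keeps entries at or below the threshold (inclusive —
the published matrices contain no entry exactly equal to a threshold, so
the convention is observationally irrelevant there, but it is fixed and
documented) and greedily emits globally smallest distances, removing
each matched study (a study may be used once); ties break by (row id,
column id) lexicographic order so the procedure is deterministic.
Distances are compared at full precision and rounded to 3 decimals only
for display; when working from a transcribed published matrix the
3-decimal values themselves are compared.

## Pseudo-IPD reconstruction

Treatment effects for matched single-arm pairs come from digitized
Kaplan–Meier curves. `reconstruct_ipd()` re-implements the standard
iterative curve-inversion algorithm: within each interval between
numbers-at-risk times, the censor count is solved so the at-risk count
at the next published time matches, censoring is spread uniformly within
the interval, and event counts follow from the digitized survival drops
relative to the running product-limit value. Residual single-patient
discrepancies from integer rounding are accepted, as in the reference
implementations. When only the arm size and total event count are
published, the total event count is matched instead and censor times are
placed with density proportional to the digitized curve — a constant
censoring *rate* — because uniform-in-time placement cannot in general
satisfy the arm size and event total simultaneously. Digitized
coordinates are monotonicity-repaired (cumulative minimum, clamped to
[0, 1]) on construction; repairs larger than 0.02 survival — beyond
ordinary read-off noise — trigger a warning. Log hazard ratios are then
estimated by a Cox model with a single treatment-arm covariate
(`cox_loghr()`); Efron's tie correction is the default because
interval-based reconstruction produces heavily tied times (Breslow is
available).

On exponential test arms of 300 patients with roughly 20% censoring and
a risk table at every time unit, the reconstructed curves agree with the
digitized input within 0.02 absolute survival (0.05 with totals only),
and Cox estimation on 2,000-patient arms recovers a true hazard ratio of
0.7 within 0.05 on the log scale; these are the tolerances asserted in
the test suite.

## Cross-validation

`crossvalidate()` removes each study's final-outcome effect in turn,
treats it as missing at random, and refits; the predicted mean is the
posterior mean of that study's true effect and the predictive variance
is $\sigma_{2i}^2 + \mathrm{var}(\hat\delta_{2i}\mid\text{rest})$.
Accuracy is summarised by the median (range) absolute discrepancy
between predicted and observed effects, precision by the median (range)
ratio of the predicted-interval width to the observed Wald CI width
($2 \times 1.96\,\sigma_{2i}$). Two interval constructions are emitted:
the normal approximation mean $\pm\, 1.96\sqrt{\text{variance}}$, whose
width ratio is bounded below by 1 by construction and is the reported
`width_ratio`, and equal-tailed quantiles of posterior-predictive draws
(true-effect draws plus $N(0, \sigma_{2i}^2)$ noise), reported as
`width_ratio_q`. Each refit is seeded as `seed + study index`, so
per-study results are independently reproducible and insensitive to
which other studies are rerun.

## The synthetic-data generator

`simulate_meta_dataset()` generates study tables with exactly the
structure the models assume: latent effects from the product-normal
between-studies model, additive design-specific bias for non-RCT
designs, and correlated bivariate-normal within-study noise. Either
$(\tau_2, \rho)$ or $(\lambda_1, \psi_2)$ may be supplied; the other is
derived through the product-normal identities, and inconsistent
over-specification is rejected. Defaults were chosen once to mirror a
small colorectal-cancer evidence base: 7 RCTs, 4 cRWE, 2 sRWE;
$\eta_1 = -0.36$, $\tau_1 = 0.20$, $\tau_2 = 0.16$, $\rho = 0.74$,
$\lambda_0 = 0$; within-study standard errors uniform on [0.1, 0.3] and
$\rho_w = 0.52$; bias terms centred at zero with SD 0.1 (modest design
bias, of the order seen in adjusted observational comparisons). Each
study draws from its own substream hashed from the master seed, so
datasets with different master seeds are mutually independent and adding
studies never perturbs existing ones.

The generator emulates the models' assumptions — it does not simulate
patient-level confounding mechanisms, non-proportional hazards, or
selective reporting. Passing recovery tests therefore demonstrates that
the samplers estimate the model they claim to estimate, not that the
model is correct for any particular real dataset.

### What recovery tests can and cannot show

One structural property is worth stating explicitly: with flat
independent priors on the $\delta_{1i}$, the Daniels–Hughes likelihood
integrates to a regression of $Y_{2i}$ on the *observed* $Y_{1i}$ with
variance $\psi_2^2 + \sigma_{2i}^2 + \lambda_1^2\sigma_{1i}^2$. Its
slope therefore targets an errors-in-variables (attenuated) quantity
when within-study error on the surrogate is comparable to the
between-studies spread. Under the generator's defaults
($\sigma_{1i} \in [0.1, 0.3]$ against $\tau_1 = 0.25$ in the recovery
harness) the attenuation is visible but small relative to posterior
uncertainty: across 100 independent replicates the 95% CrI for
$\lambda_1$ covers the generating value in 89% of D&H fits and 96% of
BRMA PNF fits (the BRMA model, which treats the $\delta_{1i}$ as
exchangeable, does not attenuate). With very small within-study errors
the D&H posterior mean converges to the ordinary least-squares line, a
limit asserted to 0.01 in the tests.

## Problem sizes and numerical choices

The test suite and acceptance script use deliberately reduced MCMC runs
(typically 5,000–15,000 iterations, 1–2 chains) and simulation sizes
(30-study recovery datasets, 100 replicates, 300–2,000-patient survival
arms); these sizes give stable checks at the stated tolerances while
keeping a full run to a few minutes. Reported analyses should use the
default `mcmc_settings()` (150,000/50,000, 2 chains). Degenerate inputs
are handled explicitly: a study table needs at least 3 rows;
cross-validation at least 4; the bias model refuses all-RCT input
(pointing to `fit_brma_pnf`); all-censored survival arms yield flat
curves and reconstruct as fully censored cohorts; and zero-jitter
covariate profiles produce all-zero distances.

## Known limitations

- Matching uses aggregate covariates only; it cannot adjust for
  within-study patient heterogeneity, and the exchangeability it buys is
  weaker than randomization.
- The proportional-hazards assumption is inherited from the published
  analyses; no non-proportional-hazards modelling is attempted.
- All evidence types are weighted equally given the bias model;
  quality weighting beyond additive bias terms is out of scope.
- The published-table reproduction of the colorectal-cancer case study
  requires the study-level effect tables from the journal's
  supplementary appendix, which are not redistributable with the
  package; the corresponding check documents this rather than
  substituting fabricated data.
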