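---
title: "Assessing empirical calibration of confidence intervals by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing empirical calibration of confidence intervals by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empcalsim)
```

## The problem

Observational estimates of treatment effects carry residual bias:
confounders that were never measured, measured with error, or entered into
the analysis model with the wrong functional form, and cohorts in which
parts of the population can only ever receive one of the two treatments.
*Empirical calibration* tries to quantify that residual bias from data: a
set of **negative control outcomes** — outcomes the treatment cannot
plausibly affect — is analysed with the same estimation pipeline as the
outcome of interest, and their non-null "effects" are read as draws from a
systematic error distribution. Adding **positive controls** — synthetic
outcomes with known non-null effects — lets the error model depend on the
true effect size, and the fitted model is then folded into the confidence
interval of the outcome of interest.

`empcalsim` rebuilds, as a tested pipeline, a simulation study of how well
this calibration works under five bias mechanisms. Everything is synthetic
and fully under the experimenter's control, so coverage and bias of the
calibrated and uncalibrated intervals can be measured against known
truths.

## Data-generating model

Each simulation iteration draws a cohort of $N = 50{,}000$ subjects with
$m = 10$ independent standard-normal confounders $X$. Treatment and
outcomes are binary and logistic:

$$\Pr(Z = 1 \mid X) = \operatorname{logistic}(\alpha_0 + \alpha^\top X
  \;[+\; \alpha_e B]),$$
$$\Pr(Y^\star = 1 \mid X, Z) = \operatorname{logistic}(\beta^\star_0 +
  \beta^\star_z Z + \beta^{\star\top} X \;[+\; \gamma^\star B]),$$
$$\Pr(Y^-_s = 1 \mid X) = \operatorname{logistic}(\beta^-_{s0} +
  \beta^{-\top}_s X \;[+\; \gamma_s B]), \qquad s = 1, \dots, S,$$

where $B$ is the scenario's bias term and every coefficient — intercepts,
slopes, the true conditional effect $\beta^\star_z$, and the bias-term
coefficients — is drawn i.i.d. uniform on $[\log 0.5, \log 2]$, redrawn
every iteration. Negative controls carry no treatment term at all: their
true effect is exactly zero by construction.

The scenarios differ only in $B$ and in what estimation is allowed to see:

* **reference** — no $B$; the estimation model is correct.
* **unmeasured_confounder** — $B = U \sim N(0,1)$, present in generation,
  hidden from estimation.
* **quadratic** / **interaction** — $B = X_1^2$ or $X_1 X_2$; estimation
  stays linear in $X$.
* **non_positivity** — no $B$; after treatment assignment the subjects in
  the lowest decile (`q_lo = 0.1`) of the true propensity are forced to
  $Z = 0$ with propensity exactly zero, a structural overlap violation.
* **measurement_error** — the confounder with the largest $|\beta^\star_j|$
  is observed as $X_j + E$, $E \sim N(\mu_\epsilon, \sigma_\epsilon^2)$
  with $\mu_\epsilon \sim U(0.2, 1)$ and $\sigma_\epsilon \sim U(0.2, 1)$
  per iteration; generation uses the error-free values.

Two design choices here were genuinely open and deserve their rationale:

**The bias term enters the treatment model.** The source description of
the misspecification scenarios places $B$ in the outcome models. But a
term that appears only in the outcome model is not a confounder: with a
correctly specified propensity model, inverse-probability weighting is
consistent for the marginal effect no matter how complex the outcome
surface is, and no bias (and nothing for negative controls to pick up)
would ever arise. For a bias scenario to bias anything, $B$ must also
drive treatment. We therefore include $B$ in the treatment model with a
coefficient from the same uniform range — the same reasoning that forces
the unmeasured confounder $U$ into the treatment model. A consequence
worth knowing: because $\operatorname{Var}(X_1^2) = 2$, the quadratic
scenario induces roughly twice the covariate imbalance of the
unmeasured-confounder scenario and its uncalibrated coverage lands well
below what a milder mechanism would give; the exact mechanism used by the
original study is not recoverable from its description.

**What "ideal" negative controls share.** In the `ideal` variant each
negative control replicates the outcome of interest's bias-term
coefficient ($\gamma_s = \gamma^\star$); intercepts and confounder slopes
stay independent (`ideal_copy = "bias_term"`, the default). The
alternative reading — copying all confounder slopes too — is available as
`ideal_copy = "all"`, but it makes the five controls' biases essentially
identical within an iteration, which collapses the fitted systematic-error
spread; and it would make `ideal` and `random` differ even in scenarios
without a bias term, where the study design treats them as
interchangeable. With the default, `ideal` and `random` coincide exactly
in the scenarios that have no bias term.

## Estimation

The estimation pipeline is deliberately "standard": a logistic propensity
model on the observed confounders (main effects only), stabilized
ATE weights
$w_i = \bar p Z_i / \hat e_i + (1 - \bar p)(1 - Z_i)/(1 - \hat e_i)$, and
a weighted logistic regression of each outcome on treatment alone. The
treatment coefficient of that marginal regression is the estimate
$\hat\theta$ (a log odds ratio) and its variance is the survey-style
sandwich $A^{-1} B A^{-1}$ with the weights treated as fixed
($A = \sum_i w_i p_i (1-p_i) x_i x_i^\top$,
$B = \sum_i w_i^2 (y_i - p_i)^2 x_i x_i^\top$); uncertainty in the
estimated propensities is not propagated. Fitted propensities are clipped
to $[10^{-6}, 1 - 10^{-6}]$ so that structural positivity violations
cannot produce infinite weights; no further trimming is applied.

Because a marginal regression of a binary outcome on treatment alone is
saturated, the package computes it in closed form (weighted per-arm
outcome proportions); the result is identical to the IRLS fit and is
cross-checked against one in the test suite.

**The evaluation truth is the marginal log odds ratio**, computed by
plug-in counterfactual averaging over the simulated cohort:
$\operatorname{logit}(\overline{\operatorname{logistic}(\eta_i +
\beta^\star_z)}) - \operatorname{logit}(\overline{\operatorname{logistic}
(\eta_i)})$ with $\eta_i$ the full no-treatment linear predictor. The
odds ratio is non-collapsible, so this marginal truth is closer to the
null than $\beta^\star_z$; it is the estimand of the weighted marginal
regression, which is what makes the reference scenario unbiased. The
conditional $\beta^\star_z$ is recorded alongside and selectable in every
summary.

## Positive controls by coefficient reuse

Each negative control is first modelled by unweighted maximum-likelihood
logistic regression on intercept, observed confounders and treatment. The
fitted treatment coefficient $\hat b_z$ is the control's apparent —
bias-driven — effect. A positive control with target $\theta_t > 0$ is
then generated from the fitted model with its treatment coefficient set to
an adjusted value $c$.

The adjustment is solved on the estimand scale. With
$M(x) = \operatorname{logit}(\overline{\operatorname{logistic}(\hat\eta_i
+ x)}) - \operatorname{logit}(\overline{\operatorname{logistic}
(\hat\eta_i)})$ the marginal contrast implied by the fitted linear
predictor, $c$ solves $M(c) = \theta_t + M(\hat b_z)$. The synthesized
control's clean estimable effect is then exactly the target plus the
control's marginal bias, so the calibration model sees the same systematic
error at $\theta_t$ as at the null. When the fitted confounder effects
vanish, $M$ is the identity and the rule reduces to the additive
$c = \theta_t + \hat b_z$. A purely additive adjustment on the conditional
scale, by contrast, hands every positive control a spurious
non-collapsibility error of roughly $-15\%$ of its target in this design,
which the systematic error model dutifully learns as a slope and then
wrongly "corrects" in the outcome of interest — measurably destroying
reference-scenario coverage. The default targets are
$\{\log 1.5, \log 2, \log 4\}$ per negative control.

## The calibration models

From the control pairs $(\theta_i, \hat\theta_i, \hat\tau_i)$ the package
fits, by maximum likelihood with multi-start BFGS:

* the **null distribution** (negative controls only):
  $\hat\theta_i \sim N(\mu, \sigma^2 + \hat\tau_i^2)$, optimized over
  $(\mu, \log\sigma)$ with $\sigma$ started at $0.01$ and at the sample SD
  of the estimates. Boundary solutions $\sigma \to 0$ are legitimate and
  kept ($\log\sigma$ floored at $-20$).
* the **systematic error model** (all controls):
  $\hat\theta_i \sim N(\theta_i + a + b\,\theta_i,
  (c + d\,|\theta_i|)^2 + \hat\tau_i^2)$, optimized over
  $(a, b, \log c, \log d)$ so the SD components stay non-negative. At
  $\theta = 0$ it reduces to a null distribution with $\mu = a$,
  $\sigma = c$.

Calibrated intervals invert tail probabilities: under candidate truth
$\theta$ the estimate is $N(\operatorname{mean}(\theta),
\operatorname{sd}(\theta)^2 + \hat\tau^2)$, and the 95% bounds are the
values of $\theta$ at which the observed estimate sits at the 2.5% upper
and lower tails (monotone root-finding, bracket expanded geometrically
from the estimate, tolerance $10^{-8}$); the calibrated point estimate is
the median root. With a zero-error model this reproduces the Wald interval
to numerical tolerance. Calibrated $p$-values use the null distribution:
$p = 2 \min\{\Phi, 1 - \Phi\}$ of $\hat\theta$ under
$N(\mu, \sigma^2 + \hat\tau^2)$.

Both fits are cross-checked in the test suite against dense grid-search
oracles, and interval endpoints against their defining tail-probability
identities.

## Per-iteration versus experiment-level calibration

By default every iteration is self-contained: its five negative controls
(and 15 synthesized positive controls) are fitted and the calibration
models estimated from them, exactly as a real single study would do. This
is the contract of `run_iteration()`.

A second mode, `pooled_calibration()`, fits one error model to the control
estimates pooled across all iterations of a scenario. Because the
generating coefficients are redrawn each iteration, the pooled model
absorbs the across-iteration spread of the bias mechanism and its fitted
SD is typically an order of magnitude larger than any single iteration's
(in the unmeasured-confounding scenario, calibrated widths of about 0.42
against 0.10 per-iteration at these settings). We report it as a
diagnostic of bias heterogeneity across coefficient draws — it is not a
procedure available to a real study, which sees only its own controls —
and note that published width tables of this study design are consistent
with experiment-level pooling rather than per-iteration fitting.

## Evaluation metrics

For each scenario cell (scenario × control suitability × coefficient
variant) and each estimator (uncalibrated; systematic-model calibrated;
null-model calibrated):

* **coverage** — fraction of iterations whose 95% interval contains the
  truth;
* **mean standardized absolute bias** — mean of
  $|\hat\theta - \theta| / \widehat{\operatorname{se}}$, each estimator
  standardized by its own standard error (a config switch gives the raw
  absolute bias);
* **mean interval width**;

plus funnel tables (bias against standard error with the
$|\text{bias}| = 1.96\,\mathrm{se}$ wedge). `run_study()` assembles the
comparison blocks — no calibration vs systematic calibration, systematic
vs null, and optionally 5 vs 30 negative controls — with delta columns
recomputed from unrounded components. Iterations with non-convergent fits
are excluded and counted; a scenario fails if more than 5% are lost.

## Problem sizes, reproducibility, degenerate inputs

The full study profile is 500 iterations of 50,000 subjects per scenario
cell. The package's default configuration runs a scaled-down profile (100
iterations of 20,000 subjects) suitable for interactive use; the shipped
acceptance script and the scenario-level tests use 100 iterations at the
full cohort size of 50,000, where a coverage estimate carries a
Monte-Carlo standard error of $\sqrt{p(1-p)/100}$ (about 0.046 at
$p = 0.3$) and all scenario-level checks are read with a 3-MC-SE
tolerance.

Cohorts are a pure function of `(spec, iteration_seed)`; per-iteration
seeds derive from the scenario's master seed so any iteration can be
replayed in isolation. Outcome vectors consume exactly one uniform per
subject, which is what makes the negative-control
treatment-independence property (`Z` relabelling leaves `Y^-` unchanged)
exact rather than distributional.

Degenerate cases are errors, not silent results: outcomes that are all-0,
all-1, or single-armed; propensities at 0 or 1 after clipping; fewer than
two control estimates for the null fit; a single truth level handed to the
systematic error model (redirected to `fit_null()`); an unbracketed
calibration root after 50 expansions. Perfect separation is flagged by the
logistic fitter and the affected control or iteration is dropped and
logged.

## What the generator does and does not emulate

The generator reproduces the study conditions: independent Gaussian
confounders, logistic treatment and outcome models, uniform log-OR
coefficients, and one bias mechanism at a time. Real observational data
differ in ways that matter for external validity: confounders are
correlated and non-Gaussian, several bias mechanisms act at once,
negative controls are scarce and their suitability unknown, and outcome
prevalences are often far lower than the 33–67% range this coefficient
distribution implies. Passing tests therefore demonstrate that the
calibration machinery behaves as specified under these controlled
mechanisms — not that calibrated intervals attain nominal coverage on any
particular real dataset.

## Known limitations

* The treatment-side bias-term coefficient range is a reconstruction (see
  above); scenario-level coverage under the misspecification scenarios is
  sensitive to it.
* Only log odds ratios are supported; rate and hazard scales are out of
  scope, as are doubly robust estimators and propagation of
  propensity-estimation uncertainty into the sandwich variance.
* The calibration model treats its fitted parameters as known when
  inverting the interval; with five negative controls their sampling
  error is appreciable and is one reason calibrated coverage can stay
  short of nominal even when the model family is correct.
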