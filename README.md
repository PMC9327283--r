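# empcalsim

Simulation assessment of **empirical calibration of 95% confidence
intervals** in observational treatment-effect estimation.

Observational effect estimates carry residual bias from unmeasured
confounding, model misspecification, positivity violations and covariate
measurement error. Empirical calibration estimates that bias from
*negative control outcomes* (outcomes the treatment cannot affect, whose
non-null estimates expose the systematic error) and synthetic *positive
controls* (outcomes with known effects), and widens/shifts the confidence
interval of the outcome of interest accordingly. `empcalsim` rebuilds a
full simulation study of this procedure — synthetic cohort generation
with known ground truth under five bias mechanisms, stabilized-IPW effect
estimation with sandwich standard errors, positive-control synthesis by
coefficient reuse, maximum-likelihood systematic-error and null models,
tail-probability interval calibration, and coverage/bias/width
evaluation — for biostatisticians studying when calibration helps and
when it does not.

## The model in brief

Cohorts of *N* = 50,000 subjects carry *m* = 10 standard-normal
confounders X. Treatment and outcomes are logistic:

    Pr(Z = 1 | X)       = logistic(α₀ + αᵀX [+ α_e B])
    Pr(Y* = 1 | X, Z)   = logistic(β₀* + β_z* Z + β*ᵀX [+ γ* B])
    Pr(Y⁻_s = 1 | X)    = logistic(β₀s⁻ + β_s⁻ᵀX [+ γ_s B])   (no Z term)

with every coefficient ~ U(log 0.5, log 2), redrawn each iteration, and B
the scenario's bias term (an unmeasured U, X₁², X₁X₂, a structural
positivity violation, or measurement error on the most influential
confounder). Estimation sees only the observed confounders: logistic
propensity model, stabilized ATE weights, weighted marginal logistic
regression, sandwich variance. Control estimates (θᵢ, θ̂ᵢ, τ̂ᵢ) feed the
systematic error model

    θ̂ᵢ ~ N(θᵢ + a + b·θᵢ, (c + d·|θᵢ|)² + τ̂ᵢ²)

(the null distribution N(μ, σ² + τ̂²) when only negative controls are
used), and calibrated intervals invert the implied tail probabilities.
Performance is scored by coverage of the true marginal log odds ratio,
standardized absolute bias and interval width, calibrated versus not.

## Worked example

```r
library(empcalsim)

spec <- scenario_spec("unmeasured_confounder", group = "suitable",
                      variant = "ideal", n_subjects = 20000,
                      n_iterations = 50, seed = 42)
sr <- run_scenario(spec)
summarize_scenario(sr)[, c("coverage_uncal", "coverage_cal",
                           "width_uncal", "width_cal")]
#>   coverage_uncal coverage_cal width_uncal width_cal
#> 1            0.5         0.98   0.1451577 0.1547531
```

With an unmeasured confounder driving both treatment and outcomes, the
uncalibrated 95% interval covers the true marginal log odds ratio in only
50% of iterations at this cohort size; calibrating against the five
negative controls (and 15 synthesized positive controls) restores
coverage to 98%, mostly by re-centering — each iteration's controls pin
down the iteration's own bias — at the price of a slightly wider
interval. A single iteration is fully inspectable:

```r
r <- run_iteration(spec, iteration_seeds(spec)[1])
r$uncal;  r$cal_systematic;  r$null_model
#> outcome_of_interest: log OR -0.0868 (sandwich SE 0.0364), 95% CI [-0.1580, -0.0155]
#> Calibrated (systematic model): log OR 0.0138, 95% CI [-0.0582, 0.0859]
#> Empirical null distribution: mu = -0.1025, sigma = 0.0000
```

Here the truth is `r$truth_marginal` = -0.0207: the raw interval misses
it, the controls reveal a systematic error of about -0.10, and the
calibrated interval covers. `run_study()` iterates scenario cells from a
configuration (see `default_config()` / `read_config()`) and emits the
comparison tables and funnel data; `write_study()` saves them as CSV plus
a JSON manifest. `inst/scripts/empcalsim-run` wraps this for shell use.

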