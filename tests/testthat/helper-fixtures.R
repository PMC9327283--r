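# Small scenario builders shared across tests. Sizes are deliberately small
# for unit tests; the scenario-level statistical checks use larger cohorts.

tiny_spec <- function(scenario = "reference", group = "suitable",
                      variant = "random", n = 2000L, m = 4L, S = 3L,
                      iters = 5L, seed = 101L, ...) {
  scenario_spec(scenario, group = group, variant = variant,
                n_subjects = n, n_confounders = m,
                n_negative_controls = S, n_iterations = iters,
                seed = seed, ...)
}

big_spec <- function(scenario = "reference", group = "suitable",
                     variant = "random", n = 50000L, seed = 202L, ...) {
  scenario_spec(scenario, group = group, variant = variant,
                n_subjects = n, n_iterations = 3L, seed = seed, ...)
}

# Weighted logistic fit of y on (1, Z) via glm, as an independent route for
# cross-checking the closed-form estimate and the hand-rolled sandwich.
glm_route <- function(y, z, w) {
  stats::glm(y ~ z, family = stats::quasibinomial(), weights = w)
}
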