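#' Draw the generating coefficients for one simulation iteration
#'
#' Every coefficient of the treatment model, the outcome-of-interest model
#' and the negative-control models — intercepts, confounder slopes, the true
#' conditional treatment effect, and any scenario-specific bias-term
#' coefficient — is drawn i.i.d. uniform on `[coef_low, coef_high]`
#' (defaults `log(0.5)` to `log(2)`).
#'
#' Under the `ideal` variant the outcome of interest's bias-term
#' coefficient is replicated in every negative control (and, when the
#' scenario spec sets `ideal_copy = "all"`, its confounder slopes as well);
#' intercepts remain independently drawn so the controls keep distinct base
#' rates. Under the `unsuitable` group the negative controls carry no
#' bias-term coefficient (only the outcome of interest does), and in the
#' non-positivity scenario's unsuitable group they carry no confounder
#' slopes at all.
#'
#' @param spec A [scenario_spec()].
#' @return A list of class `coefficient_set` with components `alpha`
#'   (treatment intercept + slopes), `alpha_extra` (treatment coefficient on
#'   the scenario's bias term, or `NULL`), `beta_star` (outcome intercept +
#'   slopes), `beta_z_star` (true conditional treatment effect),
#'   `extra_star` (outcome bias-term coefficient or `NULL`), `beta_neg`
#'   (S x (m+1) matrix, first column intercepts) and `extra_neg` (length-S
#'   vector or `NULL`).
#' @export
draw_coefficients <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  m <- spec$n_confounders
  S <- spec$n_negative_controls
  runifc <- function(k) stats::runif(k, spec$coef_low, spec$coef_high)

  alpha <- runifc(m + 1L)
  beta_star <- runifc(m + 1L)
  beta_z_star <- runifc(1L)

  extra <- has_extra_term(spec)
  alpha_extra <- if (extra) runifc(1L) else NULL
  extra_star <- if (extra) runifc(1L) else NULL

  beta_neg <- matrix(runifc(S * (m + 1L)), nrow = S)
  extra_neg <- NULL
  if (extra && spec$group == "suitable")
    extra_neg <- runifc(S)
  if (spec$variant == "ideal") {
    if (!is.null(extra_neg)) extra_neg[] <- extra_star
    if (identical(spec$ideal_copy, "all"))
      beta_neg[, -1L] <- matrix(beta_star[-1L], nrow = S, ncol = m,
                                byrow = TRUE)
  }
  if (spec$scenario == "non_positivity" && spec$group == "unsuitable")
    beta_neg[, -1L] <- 0  # unsuitable controls depend on no confounder

  structure(list(alpha = alpha, alpha_extra = alpha_extra,
                 beta_star = beta_star, beta_z_star = beta_z_star,
                 extra_star = extra_star, beta_neg = beta_neg,
                 extra_neg = extra_neg),
            class = "coefficient_set")
}

#' Generate the measured confounders
#'
#' @param n Number of subjects.
#' @param m Number of confounders.
#' @return An `n x m` matrix of i.i.d. standard-normal entries, columns
#'   named `X1..Xm`.
#' @export
generate_confounders <- function(n, m) {
  stopifnot(n >= 1, m >= 1)
  X <- matrix(stats::rnorm(n * m), nrow = n, ncol = m)
  colnames(X) <- paste0("X", seq_len(m))
  X
}

#' Assign treatment from a logistic model
#'
#' Computes the true propensity score as the logistic transform of a linear
#' combination of confounders (plus, where the scenario has one, the bias
#' term), then samples treatment as Bernoulli with that probability.
#'
#' @param X `n x m` confounder matrix.
#' @param alpha Length `m + 1` coefficient vector (intercept first).
#' @param extra Optional length-`n` vector of the scenario's bias term
#'   (`U`, `X1^2` or `X1*X2`).
#' @param alpha_extra Coefficient of `extra` (ignored if `extra` is NULL).
#' @return List with `Z` (0/1 integer vector) and `true_ps` (the generating
#'   propensities).
#' @export
assign_treatment <- function(X, alpha, extra = NULL, alpha_extra = 0) {
  stopifnot(length(alpha) == ncol(X) + 1L)
  eta <- alpha[1L] + drop(X %*% alpha[-1L])
  if (!is.null(extra)) eta <- eta + alpha_extra * extra
  ps <- stats::plogis(eta)
  Z <- as.integer(stats::runif(nrow(X)) < ps)
  list(Z = Z, true_ps = ps)
}

#' Generate a binary outcome from a logistic model
#'
#' Generates the outcome of interest (with a treatment term) or a negative
#' control (without one: negative controls are treatment-independent by
#' construction) from the logistic model
#' `logit P(Y = 1) = beta0 + beta_z Z + sum_j beta_j X_j + gamma * extra`.
#'
#' One uniform deviate is consumed per subject, so regenerating from the
#' same random state with `beta_z = 0` and any relabelling of `Z` yields an
#' identical outcome vector.
#'
#' @param X `n x m` confounder matrix.
#' @param beta Length `m + 1` coefficient vector (intercept first).
#' @param Z Optional treatment vector; required when `beta_z != 0`.
#' @param beta_z Treatment coefficient (log odds ratio); 0 for negative
#'   controls.
#' @param extra Optional length-`n` bias-term vector.
#' @param gamma Coefficient of `extra`.
#' @return Integer 0/1 vector of length `n`.
#' @export
generate_outcome <- function(X, beta, Z = NULL, beta_z = 0,
                             extra = NULL, gamma = 0) {
  stopifnot(length(beta) == ncol(X) + 1L)
  eta <- outcome_linear_predictor(X, beta, extra, gamma)
  if (beta_z != 0) {
    stopifnot(!is.null(Z), length(Z) == nrow(X))
    eta <- eta + beta_z * Z
  }
  as.integer(stats::runif(nrow(X)) < stats::plogis(eta))
}

outcome_linear_predictor <- function(X, beta, extra = NULL, gamma = 0) {
  eta <- beta[1L] + drop(X %*% beta[-1L])
  if (!is.null(extra)) eta <- eta + gamma * extra
  eta
}

#' Inject a structural positivity violation
#'
#' Forces the subjects whose baseline true propensity falls in the lowest
#' `q_lo` fraction of the cohort to the untreated arm: their treatment
#' probability becomes exactly 0 (a structural, not random, violation of
#' the overlap assumption). Optionally the symmetric upper-tail region is
#' forced to treated.
#'
#' @param Z Treatment vector sampled from the baseline propensities.
#' @param true_ps Baseline true propensities.
#' @param q_lo Fraction of subjects in the violation region, in [0, 0.5);
#'   `q_lo = 0` is the identity.
#' @param upper_tail Also force the top `q_lo` fraction to treated.
#' @return List with modified `Z` and `true_ps`; exactly `floor(q_lo * n)`
#'   subjects (per tail) are modified.
#' @export
inject_non_positivity <- function(Z, true_ps, q_lo = 0.1,
                                  upper_tail = FALSE) {
  if (q_lo < 0 || q_lo >= 0.5)
    stop("q_lo must lie in [0, 0.5)", call. = FALSE)
  n <- length(true_ps)
  k <- floor(q_lo * n)
  if (k >= 1) {
    ord <- order(true_ps)
    lo <- ord[seq_len(k)]
    Z[lo] <- 0L
    true_ps[lo] <- 0
    if (upper_tail) {
      hi <- ord[seq.int(n - k + 1L, n)]
      Z[hi] <- 1L
      true_ps[hi] <- 1
    }
  }
  list(Z = Z, true_ps = true_ps)
}

#' Inject measurement error into the most influential confounder
#'
#' Adds i.i.d. Gaussian error `E ~ N(mu_e, sd_e^2)` to the confounder with
#' the largest absolute outcome effect, producing the observed confounder
#' matrix handed to estimation; generation keeps using the error-free
#' values. The error mean (strictly positive, i.e. a systematic component)
#' and standard deviation are drawn once per iteration from the configured
#' ranges.
#'
#' @param X_true Error-free confounder matrix.
#' @param beta_star Outcome-of-interest coefficients (intercept first); the
#'   column with the largest `|beta|` receives the error.
#' @param mu_range,sd_range Ranges for the error mean and SD;
#'   `mu_range[1]` must be > 0.
#' @return List with `X_obs`, the affected `column`, and the drawn
#'   `mu_e`, `sd_e`.
#' @export
inject_measurement_error <- function(X_true, beta_star,
                                     mu_range = c(0.2, 1),
                                     sd_range = c(0.2, 1)) {
  if (mu_range[1] <= 0)
    stop("measurement-error mean range must be strictly positive",
         call. = FALSE)
  j <- which.max(abs(beta_star[-1L]))
  mu_e <- stats::runif(1L, mu_range[1], mu_range[2])
  sd_e <- stats::runif(1L, sd_range[1], sd_range[2])
  X_obs <- X_true
  X_obs[, j] <- X_obs[, j] + stats::rnorm(nrow(X_true), mu_e, sd_e)
  list(X_obs = X_obs, column = j, mu_e = mu_e, sd_e = sd_e)
}

#' Simulate one cohort under a scenario
#'
#' Runs the three generation steps — confounders, treatment, outcomes — for
#' one simulation iteration, applying the scenario's bias mechanism, and
#' records the generating coefficients and the true conditional and
#' marginal treatment effects. Deterministic given `(spec, iteration_seed)`.
#'
#' @param spec A [scenario_spec()].
#' @param iteration_seed Seed for this iteration (see [iteration_seeds()]).
#' @return An object of class `empcal_cohort`: a list with `X_true`,
#'   `X_obs`, `U` (or `NULL`), `Z`, `true_ps`, `Y_star`, `Y_neg`
#'   (`n x S` matrix), `coefs`, `eta_star_base` (outcome linear predictor
#'   without the treatment term) and `truth` (list with
#'   `conditional_log_or` and `marginal_log_or`).
#' @export
simulate_cohort <- function(spec, iteration_seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(iteration_seed)
  n <- spec$n_subjects
  bp <- spec$bias_params

  coefs <- draw_coefficients(spec)
  X <- generate_confounders(n, spec$n_confounders)
  U <- if (spec$scenario == "unmeasured_confounder") stats::rnorm(n) else NULL

  extra <- switch(spec$scenario,
                  unmeasured_confounder = U,
                  quadratic = X[, 1L]^2,
                  interaction = X[, 1L] * X[, 2L],
                  NULL)

  trt <- assign_treatment(X, coefs$alpha, extra = extra,
                          alpha_extra = coefs$alpha_extra %||% 0)
  if (spec$scenario == "non_positivity")
    trt <- inject_non_positivity(trt$Z, trt$true_ps, q_lo = bp$q_lo,
                                 upper_tail = bp$upper_tail)

  Y_star <- generate_outcome(X, coefs$beta_star, Z = trt$Z,
                             beta_z = coefs$beta_z_star,
                             extra = extra, gamma = coefs$extra_star %||% 0)
  S <- spec$n_negative_controls
  Y_neg <- matrix(0L, nrow = n, ncol = S,
                  dimnames = list(NULL, paste0("neg", seq_len(S))))
  for (s in seq_len(S))
    Y_neg[, s] <- generate_outcome(X, coefs$beta_neg[s, ],
                                   extra = extra,
                                   gamma = coefs$extra_neg[s] %||% 0)

  X_obs <- X
  me <- NULL
  if (spec$scenario == "measurement_error") {
    me <- inject_measurement_error(X, coefs$beta_star,
                                   mu_range = bp$me_mu_range,
                                   sd_range = bp$me_sd_range)
    X_obs <- me$X_obs
  }

  eta_base <- outcome_linear_predictor(X, coefs$beta_star, extra = extra,
                                       gamma = coefs$extra_star %||% 0)
  truth <- list(conditional_log_or = coefs$beta_z_star,
                marginal_log_or = true_marginal_effect(coefs$beta_z_star,
                                                       eta_base))

  structure(list(spec = spec, iteration_seed = iteration_seed,
                 X_true = X, X_obs = X_obs, U = U, extra = extra,
                 Z = trt$Z, true_ps = trt$true_ps,
                 Y_star = Y_star, Y_neg = Y_neg,
                 coefs = coefs, eta_star_base = eta_base,
                 measurement_error = me, truth = truth),
            class = "empcal_cohort")
}

#' @export
print.empcal_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d subjects, %d confounders, %d negative controls\n",
              nrow(x$X_true), ncol(x$X_true), ncol(x$Y_neg)))
  cat(sprintf("  scenario %s (%s/%s); treated fraction %.3f; P(Y*=1) = %.3f\n",
              x$spec$scenario, x$spec$group, x$spec$variant,
              mean(x$Z), mean(x$Y_star)))
  cat(sprintf("  truth: conditional log OR %.4f, marginal log OR %.4f\n",
              x$truth$conditional_log_or, x$truth$marginal_log_or))
  invisible(x)
}

#' Export a cohort as a subject-level data frame
#'
#' One row per subject with the observed confounders, treatment, outcome of
#' interest and negative controls — the estimation-time view of the data
#' (no true propensities, no unmeasured confounder). Intended for debugging
#' dumps; the pipeline itself never needs it.
#'
#' @param cohort An `empcal_cohort`.
#' @return A data frame with `n_subjects` rows.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "empcal_cohort"))
  data.frame(cohort$X_obs, Z = cohort$Z, Y_star = cohort$Y_star,
             cohort$Y_neg, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
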