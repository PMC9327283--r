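#' Maximum-likelihood logistic regression
#'
#' Thin wrapper around [stats::glm.fit()] with a logit link that accepts
#' optional (possibly non-integer) case weights, used for the propensity
#' model, the negative-control outcome models and the weighted marginal
#' effect model. Convergence follows the IRLS deviance criterion with a
#' relative tolerance of 1e-10 and at most 100 iterations.
#'
#' @param design `n x p` design matrix including an intercept column.
#' @param y Binary response vector.
#' @param weights Optional positive case weights (likelihood weights).
#' @return List with `coefficients`, `fitted` (probabilities), `converged`
#'   and `n_iterations`. Perfect separation shows up as `converged = FALSE`
#'   or fitted probabilities at the clipping bounds; callers exclude such
#'   fits.
#' @export
fit_logistic <- function(design, y, weights = NULL) {
  stopifnot(nrow(design) == length(y), ncol(design) < nrow(design))
  if (!is.null(weights) && any(weights <= 0))
    stop("weights must be strictly positive", call. = FALSE)
  fit <- suppressWarnings(stats::glm.fit(
    x = design, y = y, weights = weights,
    family = stats::quasibinomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  converged <- isTRUE(fit$converged) && all(is.finite(fit$coefficients)) &&
    all(abs(fit$coefficients) < 30)  # blown-up coefficients flag separation
  list(coefficients = unname(fit$coefficients), fitted = fit$fitted.values,
       converged = converged, n_iterations = fit$iter)
}

#' Fit the estimation propensity model
#'
#' Logistic regression of treatment on the observed confounders (main
#' effects plus intercept only — the "standard" estimation model, which is
#' deliberately blind to any unmeasured confounder or non-linear term the
#' generating process may contain). Fitted propensities are clipped to
#' `[clip, 1 - clip]` so downstream weights stay finite even under
#' structural positivity violations.
#'
#' @param X_obs Observed confounder matrix.
#' @param Z Treatment vector.
#' @param clip Clipping bound for fitted propensities (default 1e-6).
#' @return List with `coefficients`, `fitted_ps` (clipped), `converged`,
#'   `n_iterations`.
#' @export
fit_propensity <- function(X_obs, Z, clip = 1e-6) {
  fit <- fit_logistic(cbind(1, X_obs), Z)
  ps <- pmin(pmax(fit$fitted, clip), 1 - clip)
  list(coefficients = fit$coefficients, fitted_ps = ps,
       converged = fit$converged, n_iterations = fit$n_iterations)
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' `w_i = pbar * Z_i / ps_i + (1 - pbar) * (1 - Z_i) / (1 - ps_i)` with
#' `pbar = mean(Z)`: the ATE-targeting stabilized weight, whose mean is
#' close to 1 when the propensity model is adequate.
#'
#' @param ps_hat Estimated propensities, strictly inside (0, 1).
#' @param Z Treatment vector.
#' @return Positive weight vector.
#' @export
stabilized_weights <- function(ps_hat, Z) {
  if (any(ps_hat <= 0 | ps_hat >= 1))
    stop("propensity scores must lie strictly in (0, 1); clip before ",
         "weighting", call. = FALSE)
  pbar <- mean(Z)
  pbar * Z / ps_hat + (1 - pbar) * (1 - Z) / (1 - ps_hat)
}

#' Weighted treatment-effect estimate with sandwich standard error
#'
#' Fits the weighted logistic regression of a binary outcome on intercept
#' and treatment (the weights carry the confounding adjustment) and returns
#' the treatment log odds ratio with its model-robust sandwich standard
#' error `A^-1 B A^-1`, where `A = sum_i w_i p_i (1 - p_i) x_i x_i'` is the
#' weighted Fisher information and `B = sum_i w_i^2 (y_i - p_i)^2 x_i x_i'`
#' accumulates squared weighted scores. Weights are treated as fixed
#' (survey-style HC0); propensity-estimation uncertainty is not propagated.
#'
#' @param Y Binary outcome vector.
#' @param Z Treatment vector.
#' @param weights Positive weights (typically [stabilized_weights()]).
#' @param outcome_label Identifier used in messages and result tables.
#' @return An object of class `effect_estimate`: list with `log_or`, `se`,
#'   `ci_lo`, `ci_hi` (Wald 95%), `outcome_label`, `converged`.
#' @export
estimate_effect <- function(Y, Z, weights, outcome_label = "outcome") {
  if (length(unique(Y)) < 2L)
    stop("outcome '", outcome_label, "' is degenerate (all ",
         Y[1L], ")", call. = FALSE)
  if (any(weights <= 0))
    stop("weights must be strictly positive", call. = FALSE)
  # The model Y ~ 1 + Z is saturated, so the weighted ML solution is the
  # pair of weighted outcome proportions per arm (identical to the IRLS
  # fixed point, in closed form).
  w1 <- sum(weights[Z == 1])
  w0 <- sum(weights[Z == 0])
  p1 <- sum(weights[Z == 1] * Y[Z == 1]) / w1
  p0 <- sum(weights[Z == 0] * Y[Z == 0]) / w0
  if (any(c(p0, p1) <= 0 | c(p0, p1) >= 1))
    stop("outcome '", outcome_label, "' is degenerate in one treatment arm",
         call. = FALSE)
  log_or <- stats::qlogis(p1) - stats::qlogis(p0)

  design <- cbind(1, Z)
  p <- ifelse(Z == 1, p1, p0)
  A <- crossprod(design * (weights * p * (1 - p)), design)
  B <- crossprod(design * (weights * (Y - p)))
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  se <- sqrt(V[2L, 2L])
  z975 <- stats::qnorm(0.975)
  structure(list(log_or = log_or, se = se,
                 ci_lo = log_or - z975 * se, ci_hi = log_or + z975 * se,
                 outcome_label = outcome_label, converged = TRUE),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: log OR %.4f (sandwich SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$outcome_label, x$log_or, x$se, x$ci_lo, x$ci_hi))
  invisible(x)
}

#' True marginal log odds ratio of the generating model
#'
#' Plug-in counterfactual marginal effect on the simulated cohort: with
#' `eta_i` the full outcome linear predictor without the treatment term
#' (confounders, unmeasured confounder and any bias term included), the
#' marginal log OR is `logit(mean(plogis(eta + beta_z))) -
#' logit(mean(plogis(eta)))`. Because the odds ratio is non-collapsible,
#' this is generally closer to the null than the conditional `beta_z`; it
#' is the estimand of the weighted marginal regression and therefore the
#' default evaluation truth.
#'
#' @param beta_z Conditional treatment log odds ratio.
#' @param eta_base Length-`n` outcome linear predictor without treatment.
#' @return The marginal log odds ratio (scalar).
#' @export
true_marginal_effect <- function(beta_z, eta_base) {
  p1 <- mean(stats::plogis(eta_base + beta_z))
  p0 <- mean(stats::plogis(eta_base))
  stats::qlogis(p1) - stats::qlogis(p0)
}
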