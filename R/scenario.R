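#' Scenario specification for a simulation experiment
#'
#' A scenario specification bundles everything that defines one simulation
#' experiment: which bias mechanism is active, whether the negative controls
#' share that mechanism with the outcome of interest ("suitable") or not
#' ("unsuitable"), whether their confounder coefficients are copied from the
#' outcome of interest ("ideal") or drawn independently ("random"), and the
#' sizes and seeds of the run.
#'
#' The available bias scenarios are:
#' \describe{
#'   \item{`reference`}{No bias mechanism. Treatment and all outcomes depend
#'     linearly on the measured confounders; the estimation model is
#'     correctly specified.}
#'   \item{`unmeasured_confounder`}{An extra standard-normal confounder `U`
#'     affects treatment assignment and the outcome of interest (and, in the
#'     suitable group, the negative controls) but is hidden from
#'     estimation.}
#'   \item{`quadratic`}{Treatment and outcome generation include a
#'     `X1^2` term that the (linear) estimation model omits.}
#'   \item{`interaction`}{As `quadratic`, with an `X1*X2` term.}
#'   \item{`non_positivity`}{A structural positivity violation: subjects in
#'     the lower tail of the true propensity distribution are never
#'     treated.}
#'   \item{`measurement_error`}{The confounder with the largest outcome
#'     effect is observed with additive Gaussian error (random positive mean
#'     and random standard deviation per iteration).}
#' }
#'
#' @param scenario One of `"reference"`, `"unmeasured_confounder"`,
#'   `"quadratic"`, `"interaction"`, `"non_positivity"`,
#'   `"measurement_error"`.
#' @param group `"suitable"` (negative controls share the bias mechanism of
#'   the outcome of interest) or `"unsuitable"` (they do not). The reference
#'   and measurement-error scenarios only have a suitable group.
#' @param variant `"ideal"` (negative controls replicate the outcome of
#'   interest's bias-term coefficient — and, with `ideal_copy = "all"`, its
#'   confounder slopes too; intercepts stay independent) or `"random"` (all
#'   coefficients drawn independently). `"ideal"` is only meaningful for
#'   suitable controls.
#' @param ideal_copy What the ideal variant replicates from the outcome of
#'   interest into each negative control: `"bias_term"` (default; only the
#'   coefficient of the scenario's bias term, so ideal and random coincide
#'   in scenarios without one) or `"all"` (bias term and every confounder
#'   slope).
#' @param n_subjects Cohort size per iteration (default 50000).
#' @param n_confounders Number of measured standard-normal confounders
#'   (default 10).
#' @param n_negative_controls Number of negative-control outcomes (default
#'   5; the sensitivity analysis uses 30).
#' @param coef_low,coef_high Bounds of the uniform distribution from which
#'   every generating coefficient is drawn, on the log odds ratio scale
#'   (defaults `log(0.5)` and `log(2)`).
#' @param n_iterations Number of simulation iterations (default 500).
#' @param seed Master seed for the scenario; per-iteration seeds are derived
#'   from it so single iterations can be replayed.
#' @param bias_params Named list of bias-injector parameters, see Details.
#'
#' @details `bias_params` recognises:
#' \describe{
#'   \item{`q_lo`}{Non-positivity: fraction of subjects (by lowest true
#'     propensity) forced to the untreated arm, in (0, 0.5); default 0.1.}
#'   \item{`upper_tail`}{Non-positivity: also force the symmetric upper-tail
#'     region to treated; default `FALSE`.}
#'   \item{`me_mu_range`}{Measurement error: range from which the error mean
#'     is drawn each iteration; default `c(0.2, 1)`; lower bound must be
#'     positive.}
#'   \item{`me_sd_range`}{Measurement error: range for the error standard
#'     deviation; default `c(0.2, 1)`.}
#' }
#'
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("unmeasured_confounder", group = "suitable",
#'               variant = "ideal", n_subjects = 5000, n_iterations = 10,
#'               seed = 42)
#' @export
scenario_spec <- function(scenario = c("reference", "unmeasured_confounder",
                                       "quadratic", "interaction",
                                       "non_positivity", "measurement_error"),
                          group = c("suitable", "unsuitable"),
                          variant = c("random", "ideal"),
                          ideal_copy = c("bias_term", "all"),
                          n_subjects = 50000L,
                          n_confounders = 10L,
                          n_negative_controls = 5L,
                          coef_low = log(0.5),
                          coef_high = log(2),
                          n_iterations = 500L,
                          seed = 1L,
                          bias_params = list()) {
  scenario <- match.arg(scenario)
  group <- match.arg(group)
  variant <- match.arg(variant)
  ideal_copy <- match.arg(ideal_copy)

  counts <- c(n_subjects = n_subjects, n_confounders = n_confounders,
              n_negative_controls = n_negative_controls,
              n_iterations = n_iterations)
  if (any(!is.finite(counts)) || any(counts < 1))
    stop("all counts (n_subjects, n_confounders, n_negative_controls, ",
         "n_iterations) must be >= 1", call. = FALSE)
  if (!is.finite(coef_low) || !is.finite(coef_high) || coef_low >= coef_high)
    stop("coef_low must be strictly less than coef_high", call. = FALSE)
  if (variant == "ideal" && group == "unsuitable")
    stop("variant = 'ideal' requires suitable negative controls: an ",
         "unsuitable control cannot copy the outcome's bias-term ",
         "coefficients it lacks", call. = FALSE)
  if (scenario %in% c("reference", "measurement_error") &&
      group == "unsuitable")
    stop("scenario '", scenario, "' has no unsuitable group", call. = FALSE)

  bp <- utils::modifyList(
    list(q_lo = 0.1, upper_tail = FALSE,
         me_mu_range = c(0.2, 1), me_sd_range = c(0.2, 1)),
    bias_params)
  if (!is.numeric(bp$q_lo) || bp$q_lo < 0 || bp$q_lo >= 0.5)
    stop("bias_params$q_lo must lie in [0, 0.5)", call. = FALSE)
  if (bp$me_mu_range[1] <= 0)
    stop("measurement-error mean range must be strictly positive ",
         "(systematic error component)", call. = FALSE)
  if (bp$me_sd_range[1] < 0)
    stop("measurement-error sd range must be non-negative", call. = FALSE)

  structure(
    list(scenario = scenario, group = group, variant = variant,
         ideal_copy = ideal_copy,
         n_subjects = as.integer(n_subjects),
         n_confounders = as.integer(n_confounders),
         n_negative_controls = as.integer(n_negative_controls),
         coef_low = coef_low, coef_high = coef_high,
         n_iterations = as.integer(n_iterations),
         seed = as.integer(seed), bias_params = bp),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Simulation scenario:", x$scenario,
      sprintf("(%s controls, %s coefficients)\n", x$group, x$variant))
  cat(sprintf("  N = %d subjects, m = %d confounders, S = %d negative controls\n",
              x$n_subjects, x$n_confounders, x$n_negative_controls))
  cat(sprintf("  coefficients ~ U(%.4f, %.4f); %d iterations; seed %d\n",
              x$coef_low, x$coef_high, x$n_iterations, x$seed))
  invisible(x)
}

# TRUE when the scenario adds an extra term (U, X1^2 or X1*X2) to the
# generating models
has_extra_term <- function(spec) {
  spec$scenario %in% c("unmeasured_confounder", "quadratic", "interaction")
}

#' Per-iteration seeds for a scenario
#'
#' Derives one reproducible sub-seed per iteration from the scenario's
#' master seed, so individual iterations can be replayed in isolation.
#'
#' @param spec A [scenario_spec()].
#' @return Integer vector of length `spec$n_iterations`.
#' @export
iteration_seeds <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  sample.int(.Machine$integer.max - 1L, spec$n_iterations)
}

#' Read a study configuration file
#'
#' Reads a YAML (or JSON) configuration describing the scenarios to run and
#' the generator/calibration parameters, and normalises it against package
#' defaults. Every generator default is overridable from the file.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A named list with class `empcal_config`, suitable for
#'   [run_study()].
#' @seealso [default_config()]
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), raw)
  class(cfg) <- "empcal_config"
  cfg
}

#' Default study configuration
#'
#' The defaults run every scenario cell of the study design (each bias
#' scenario crossed with suitable-ideal, suitable-random and, where defined,
#' unsuitable-random controls) at a scaled-down profile of 100 iterations of
#' 20000 subjects. The full-scale profile of the study design (500
#' iterations of 50000 subjects) is obtained by overriding `n_iterations`
#' and `n_subjects`.
#'
#' @return Named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    scenarios = c("reference", "unmeasured_confounder", "quadratic",
                  "interaction", "non_positivity", "measurement_error"),
    n_subjects = 20000L,
    n_confounders = 10L,
    n_negative_controls = 5L,
    n_iterations = 100L,
    coef_low = log(0.5),
    coef_high = log(2),
    seed = 1L,
    targets = c(log(1.5), log(2), log(4)),
    truth = "marginal",
    standardized_bias = TRUE,
    calibration = "both",       # systematic | null | both
    compare_n_controls = NULL,  # e.g. 30L to add the sensitivity block
    bias_params = list())
}
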