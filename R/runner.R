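#' Run one simulation iteration end-to-end
#'
#' Simulates a cohort, fits the propensity model and stabilized weights,
#' estimates the treatment effect on the outcome of interest and on every
#' control, fits the systematic-error and null calibration models, and
#' calibrates the outcome-of-interest estimate under both. Deterministic
#' given `(spec, iteration_seed)`.
#'
#' @param spec A [scenario_spec()].
#' @param iteration_seed Seed for this iteration.
#' @param targets Positive-control target log odds ratios.
#' @return An object of class `iteration_result`: list with `iteration_seed`,
#'   `truth_marginal`, `truth_conditional`, `uncal` (`effect_estimate`),
#'   `cal_systematic`, `cal_null` (`calibrated_estimate`s), `controls`
#'   (the (truth, estimate) table), `null_model`, `systematic_model`,
#'   `mean_weight` and `flags` (character vector of notes).
#' @export
run_iteration <- function(spec, iteration_seed,
                          targets = c(log(1.5), log(2), log(4))) {
  cohort <- simulate_cohort(spec, iteration_seed)
  flags <- character()

  ps <- fit_propensity(cohort$X_obs, cohort$Z)
  if (!ps$converged) stop("propensity model did not converge", call. = FALSE)
  w <- stabilized_weights(ps$fitted_ps, cohort$Z)

  uncal <- estimate_effect(cohort$Y_star, cohort$Z, w,
                           outcome_label = "outcome_of_interest")
  if (!uncal$converged)
    stop("outcome-of-interest effect model did not converge", call. = FALSE)

  controls <- build_control_set(cohort, w, targets = targets)
  if (nrow(controls) < spec$n_negative_controls * (1L + length(targets)))
    flags <- c(flags, "some control fits excluded (non-convergence)")

  neg <- controls[controls$truth == 0, ]
  null_model <- fit_null(neg$log_or, neg$se)
  systematic_model <- if (length(targets) > 0L)
    fit_systematic_error_model(controls$truth, controls$log_or, controls$se)
  else NULL

  cal_systematic <- if (!is.null(systematic_model))
    calibrate_ci(uncal, systematic_model) else NULL
  cal_null <- calibrate_ci(uncal, null_model)

  structure(list(iteration_seed = iteration_seed,
                 truth_marginal = cohort$truth$marginal_log_or,
                 truth_conditional = cohort$truth$conditional_log_or,
                 uncal = uncal, cal_systematic = cal_systematic,
                 cal_null = cal_null, controls = controls,
                 null_model = null_model,
                 systematic_model = systematic_model,
                 mean_weight = mean(w), flags = flags),
            class = "iteration_result")
}

#' Run all iterations of one scenario
#'
#' Executes [run_iteration()] for every per-iteration seed of the scenario.
#' Iterations whose fits fail (non-convergence, degenerate outcomes) are
#' excluded and logged; the scenario errors out if more than `max_excluded`
#' of its iterations are lost.
#'
#' @param spec A [scenario_spec()].
#' @param targets Positive-control targets.
#' @param max_excluded Maximum tolerated exclusion fraction (default 0.05).
#' @param progress Print a dot per iteration.
#' @return An object of class `scenario_results`: list with `spec`,
#'   `results` (list of `iteration_result`), `exclusions` (data frame of
#'   seed + reason).
#' @export
run_scenario <- function(spec, targets = c(log(1.5), log(2), log(4)),
                         max_excluded = 0.05, progress = FALSE) {
  seeds <- iteration_seeds(spec)
  results <- vector("list", length(seeds))
  excl <- list()
  for (i in seq_along(seeds)) {
    r <- tryCatch(run_iteration(spec, seeds[i], targets = targets),
                  error = function(e) conditionMessage(e))
    if (is.character(r)) {
      excl[[length(excl) + 1L]] <- data.frame(seed = seeds[i], reason = r)
      results[i] <- list(NULL)
    } else results[[i]] <- r
    if (progress) cat(if (i %% 50 == 0) sprintf("[%d]\n", i) else ".")
  }
  excl <- if (length(excl)) do.call(rbind, excl)
          else data.frame(seed = integer(), reason = character())
  if (nrow(excl) > max_excluded * length(seeds))
    stop(sprintf("scenario %s: %d of %d iterations excluded (limit %.0f%%)",
                 spec$scenario, nrow(excl), length(seeds),
                 100 * max_excluded), call. = FALSE)
  structure(list(spec = spec, results = Filter(Negate(is.null), results),
                 exclusions = excl),
            class = "scenario_results")
}

extract_interval <- function(result, estimator) {
  switch(estimator,
         uncal = result$uncal,
         systematic = result$cal_systematic,
         null = result$cal_null,
         systematic_pooled = result$cal_systematic_pooled,
         null_pooled = result$cal_null_pooled,
         stop("unknown estimator '", estimator, "'", call. = FALSE))
}

#' Experiment-level (pooled) calibration
#'
#' By default every iteration is calibrated with models fitted to its own
#' controls — the procedure as it would be applied to a single
#' observational study. This helper instead fits one systematic-error
#' model and one null distribution to the control estimates pooled across
#' all iterations of the scenario and re-calibrates every iteration's
#' estimate with them. Because the generating coefficients are redrawn
#' each iteration, the pooled models absorb the across-iteration spread of
#' the systematic error, which typically inflates the fitted error SD well
#' above any single iteration's: a diagnostic of how heterogeneous the
#' bias mechanism is across coefficient draws, not a procedure available
#' to a real single study.
#'
#' @param scenario_results A [run_scenario()] result.
#' @return The same object with `cal_systematic_pooled` and
#'   `cal_null_pooled` added to every iteration result, and the pooled
#'   models attached as `pooled_models`.
#' @export
pooled_calibration <- function(scenario_results) {
  stopifnot(inherits(scenario_results, "scenario_results"))
  controls <- do.call(rbind, lapply(scenario_results$results,
                                    `[[`, "controls"))
  neg <- controls[controls$truth == 0, ]
  null_p <- fit_null(neg$log_or, neg$se)
  sys_p <- if (length(unique(controls$truth)) > 1L)
    fit_systematic_error_model(controls$truth, controls$log_or,
                               controls$se)
  else NULL
  scenario_results$results <- lapply(scenario_results$results, function(r) {
    r$cal_null_pooled <- calibrate_ci(r$uncal, null_p)
    if (!is.null(sys_p))
      r$cal_systematic_pooled <- calibrate_ci(r$uncal, sys_p)
    r
  })
  scenario_results$pooled_models <- list(null = null_p,
                                         systematic = sys_p)
  scenario_results
}

iteration_rows <- function(results, truth = c("marginal", "conditional"),
                           estimators = c("uncal", "systematic", "null")) {
  truth <- match.arg(truth)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    tr <- if (truth == "marginal") r$truth_marginal else r$truth_conditional
    do.call(rbind, lapply(estimators, function(est) {
      e <- extract_interval(r, est)
      if (is.null(e)) return(NULL)
      se <- if (est == "uncal") e$se else e$se_cal
      data.frame(iteration = i, estimator = est, truth = tr,
                 log_or = e$log_or, se = se,
                 ci_lo = e$ci_lo, ci_hi = e$ci_hi)
    }))
  })
  do.call(rbind, rows)
}

#' Summarize a scenario: coverage, bias and interval width
#'
#' Computes, over the non-excluded iterations, the coverage of the 95%
#' interval (fraction of iterations whose interval contains the truth),
#' the mean standardized absolute bias (`|estimate - truth| / SE`, each
#' estimator standardized by its own standard error; optionally the raw
#' `|estimate - truth|`), and the mean interval width — uncalibrated and
#' calibrated, plus their differences.
#'
#' @param scenario_results A [run_scenario()] result (or bare list of
#'   `iteration_result`s).
#' @param truth `"marginal"` (default: the estimand of the weighted
#'   marginal regression) or `"conditional"` (the generating `beta_z`).
#' @param calibration Which calibrated estimator to summarize against the
#'   uncalibrated one: `"systematic"` (default), `"null"`, or — after
#'   [pooled_calibration()] — `"systematic_pooled"` / `"null_pooled"`.
#' @param standardized Standardize the absolute bias by the estimator's SE
#'   (default TRUE).
#' @return A one-row data frame of class `scenario_summary` with columns
#'   `coverage_uncal`, `coverage_cal`, `delta_coverage`, `msab_uncal`,
#'   `msab_cal`, `delta_msab`, `width_uncal`, `width_cal`, `delta_width`,
#'   `n_iterations_used`.
#' @export
summarize_scenario <- function(scenario_results,
                               truth = c("marginal", "conditional"),
                               calibration = c("systematic", "null",
                                               "systematic_pooled",
                                               "null_pooled"),
                               standardized = TRUE) {
  truth <- match.arg(truth)
  calibration <- match.arg(calibration)
  results <- if (inherits(scenario_results, "scenario_results"))
    scenario_results$results else scenario_results
  if (length(results) == 0L) stop("no iteration results", call. = FALSE)

  tab <- iteration_rows(results, truth = truth,
                        estimators = c("uncal", calibration))
  one <- function(est) {
    d <- tab[tab$estimator == est, ]
    bias <- abs(d$log_or - d$truth)
    if (standardized) bias <- bias / d$se
    c(coverage = mean(d$truth >= d$ci_lo & d$truth <= d$ci_hi),
      msab = mean(bias), width = mean(d$ci_hi - d$ci_lo))
  }
  u <- one("uncal")
  cal <- one(calibration)
  out <- data.frame(coverage_uncal = u["coverage"],
                    coverage_cal = cal["coverage"],
                    delta_coverage = cal["coverage"] - u["coverage"],
                    msab_uncal = u["msab"], msab_cal = cal["msab"],
                    delta_msab = cal["msab"] - u["msab"],
                    width_uncal = u["width"], width_cal = cal["width"],
                    delta_width = cal["width"] - u["width"],
                    n_iterations_used = length(results),
                    row.names = NULL)
  class(out) <- c("scenario_summary", class(out))
  out
}

#' Funnel-plot table
#'
#' One row per iteration per estimator with the quantities needed to draw a
#' funnel plot: bias (`estimate - truth`) on the horizontal axis, standard
#' error on the vertical axis, and an indicator of whether the point falls
#' outside the 95% significance wedge `|bias| > 1.959964 * se`.
#'
#' @param scenario_results A [run_scenario()] result (or list of
#'   `iteration_result`s).
#' @param truth `"marginal"` or `"conditional"`.
#' @return Data frame with `iteration`, `estimator`, `bias`, `se`,
#'   `calibrated`, `outside_wedge`.
#' @export
funnel_table <- function(scenario_results,
                         truth = c("marginal", "conditional")) {
  truth <- match.arg(truth)
  results <- if (inherits(scenario_results, "scenario_results"))
    scenario_results$results else scenario_results
  if (length(results) == 0L) stop("no iteration results", call. = FALSE)
  tab <- iteration_rows(results, truth = truth)
  z <- stats::qnorm(0.975)
  data.frame(iteration = tab$iteration, estimator = tab$estimator,
             bias = tab$log_or - tab$truth, se = tab$se,
             calibrated = tab$estimator != "uncal",
             outside_wedge = abs(tab$log_or - tab$truth) > z * tab$se)
}

scenario_cells <- function(scenario) {
  if (scenario == "reference")
    return(data.frame(scenario = scenario, group = "suitable",
                      variant = "random"))
  cells <- data.frame(scenario = scenario,
                      group = c("suitable", "suitable", "unsuitable"),
                      variant = c("ideal", "random", "random"))
  if (scenario == "measurement_error") cells <- cells[1:2, ]
  cells
}

#' Run the full simulation study
#'
#' Iterates over every requested scenario cell (scenario crossed with
#' suitable-ideal, suitable-random and, where defined, unsuitable-random
#' controls), runs the scenario, and assembles the study's three comparison
#' blocks: no calibration vs systematic-error calibration, systematic vs
#' null-model calibration, and (when `compare_n_controls` is set, e.g. 30)
#' the default number of negative controls vs the larger one. Coverage and
#' width tables for every cell are emitted alongside.
#'
#' @param config A configuration list ([default_config()]; file-based via
#'   [read_config()]). Unknown entries are ignored.
#' @param progress Print progress per cell.
#' @return An object of class `empcal_study`: list with `config`, `cells`
#'   (data frame keyed by scenario/group/variant with one
#'   [summarize_scenario()] row each, for systematic and null calibration),
#'   `comparisons` (named list of the comparison blocks), `funnel` (per-cell
#'   funnel tables) and `exclusions`.
#' @export
run_study <- function(config = default_config(), progress = FALSE) {
  config <- utils::modifyList(default_config(), unclass(config))
  cells <- do.call(rbind, lapply(config$scenarios, scenario_cells))
  targets <- config$targets
  truth <- config$truth

  run_cell <- function(cell, S, seed_shift = 0L) {
    spec <- scenario_spec(cell$scenario, group = cell$group,
                          variant = cell$variant,
                          n_subjects = config$n_subjects,
                          n_confounders = config$n_confounders,
                          n_negative_controls = S,
                          coef_low = config$coef_low,
                          coef_high = config$coef_high,
                          n_iterations = config$n_iterations,
                          seed = config$seed + seed_shift,
                          bias_params = config$bias_params)
    run_scenario(spec, targets = targets)
  }

  rows <- list()
  funnels <- list()
  exclusions <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    key <- paste(cell$scenario, cell$group, cell$variant, sep = "/")
    if (progress) message("running ", key)
    sr <- run_cell(cell, config$n_negative_controls)
    for (calib in c("systematic", "null")) {
      sm <- summarize_scenario(sr, truth = truth, calibration = calib,
                               standardized = config$standardized_bias)
      rows[[length(rows) + 1L]] <-
        cbind(cell, calibration = calib, n_negative_controls =
                config$n_negative_controls, sm, row.names = NULL)
    }
    if (!is.null(config$compare_n_controls)) {
      sr30 <- run_cell(cell, config$compare_n_controls)
      sm30 <- summarize_scenario(sr30, truth = truth,
                                 calibration = "systematic",
                                 standardized = config$standardized_bias)
      rows[[length(rows) + 1L]] <-
        cbind(cell, calibration = "systematic", n_negative_controls =
                config$compare_n_controls, sm30, row.names = NULL)
    }
    funnels[[key]] <- funnel_table(sr, truth = truth)
    exclusions[[key]] <- sr$exclusions
  }
  cell_tab <- do.call(rbind, rows)
  structure(list(config = config, cells = cell_tab,
                 comparisons = study_comparisons(cell_tab, config),
                 funnel = funnels, exclusions = exclusions),
            class = "empcal_study")
}

# Assemble the three comparison blocks (delta columns recomputed from the
# unrounded cell values).
study_comparisons <- function(cells, config) {
  sys5 <- cells[cells$calibration == "systematic" &
                cells$n_negative_controls == config$n_negative_controls, ]
  nul5 <- cells[cells$calibration == "null" &
                cells$n_negative_controls == config$n_negative_controls, ]
  key <- c("scenario", "group", "variant")
  blocks <- list(
    uncal_vs_systematic = data.frame(
      sys5[key], delta_coverage = sys5$delta_coverage,
      delta_msab = sys5$delta_msab, row.names = NULL))
  if (nrow(nul5) > 0) {
    m <- merge(sys5, nul5, by = key, suffixes = c("_sys", "_null"))
    blocks$systematic_vs_null <- data.frame(
      m[key],
      delta_coverage = m$coverage_cal_null - m$coverage_cal_sys,
      delta_msab = m$msab_cal_null - m$msab_cal_sys, row.names = NULL)
  }
  if (!is.null(config$compare_n_controls)) {
    big <- cells[cells$calibration == "systematic" &
                 cells$n_negative_controls == config$compare_n_controls, ]
    m <- merge(sys5, big, by = key, suffixes = c("_5", "_30"))
    blocks$more_negative_controls <- data.frame(
      m[key],
      delta_coverage = m$coverage_cal_30 - m$coverage_cal_5,
      delta_msab = m$msab_cal_30 - m$msab_cal_5, row.names = NULL)
  }
  blocks
}

#' Write study outputs to a directory
#'
#' Writes the per-cell summary table, the comparison blocks, the funnel
#' tables and a JSON manifest (configuration, exclusions) as plain-text
#' delimited files.
#'
#' @param study A [run_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "empcal_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$cells, file.path(dir, "summary_cells.csv"),
                   row.names = FALSE)
  for (nm in names(study$comparisons))
    utils::write.csv(study$comparisons[[nm]],
                     file.path(dir, paste0("comparison_", nm, ".csv")),
                     row.names = FALSE)
  funnel <- do.call(rbind, Map(function(key, tab)
    cbind(cell = key, tab, row.names = NULL),
    names(study$funnel), study$funnel))
  utils::write.csv(funnel, file.path(dir, "funnel.csv"), row.names = FALSE)
  manifest <- list(config = study$config,
                   exclusions = lapply(study$exclusions, nrow),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.empcal_study <- function(x, ...) {
  cat("Empirical-calibration simulation study\n")
  cat(sprintf("  %d scenario cells, %d iterations of %d subjects each\n",
              length(unique(paste(x$cells$scenario, x$cells$group,
                                  x$cells$variant))),
              x$config$n_iterations, x$config$n_subjects))
  print(x$cells[x$cells$calibration == "systematic" &
                x$cells$n_negative_controls == x$config$n_negative_controls,
                c("scenario", "group", "variant", "coverage_uncal",
                  "coverage_cal", "width_uncal", "width_cal")],
        digits = 3, row.names = FALSE)
  invisible(x)
}
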