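#' Analysis scenarios: the four missing-data decisions
#'
#' A scenario bundles the four decisions that define how missing and
#' partially observed days are handled, plus the MNAR adjustment size:
#' whether to use day-substitution, whether to impute partial days as
#' censored (or discard them as missing), whether to assume MAR (or apply
#' a delta adjustment), and whether to include auxiliary variables in the
#' imputation model.
#'
#' Five named presets are provided (see [scenario_presets()]):
#'
#' | name | substitution | censored | MAR | auxiliaries |
#' |------|:---:|:---:|:---:|:---:|
#' | `plausible` (primary analysis) | no | yes | yes | yes |
#' | `suspicious` (key sensitivity) | no | yes | no, delta = 0.95 | yes |
#' | `plausible_no_aux` | no | yes | yes | no |
#' | `replace_days` | yes | yes | yes | yes |
#' | `dismissive` | no | no | no, delta = 0.95 | yes |
#'
#' @param name scenario label.
#' @param use_day_substitution replace missing/partial in-window days from
#'   the following week before imputation?
#' @param impute_partial_as_censored keep partial days as right-censored
#'   (otherwise they are discarded as missing)?
#' @param assume_mar if `FALSE`, [apply_delta()] is run after imputation.
#' @param use_auxiliaries include BMI and weather in the imputation model?
#' @param delta MNAR log-scale multiplier, used when `assume_mar = FALSE`.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(name = "custom", use_day_substitution = FALSE,
                            impute_partial_as_censored = TRUE,
                            assume_mar = TRUE, use_auxiliaries = TRUE,
                            delta = 0.95) {
  if (!assume_mar) check_delta(delta)
  structure(list(name = name,
                 use_day_substitution = isTRUE(use_day_substitution),
                 impute_partial_as_censored =
                   isTRUE(impute_partial_as_censored),
                 assume_mar = isTRUE(assume_mar),
                 use_auxiliaries = isTRUE(use_auxiliaries), delta = delta),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @export
scenario_presets <- function() {
  list(
    plausible = scenario_config("plausible"),
    suspicious = scenario_config("suspicious", assume_mar = FALSE),
    plausible_no_aux = scenario_config("plausible_no_aux",
                                       use_auxiliaries = FALSE),
    replace_days = scenario_config("replace_days",
                                   use_day_substitution = TRUE),
    dismissive = scenario_config("dismissive",
                                 impute_partial_as_censored = FALSE,
                                 assume_mar = FALSE))
}

#' @rdname scenario_config
#' @param x a scenario name (partial matching against the presets) or a
#'   `scenario_config`.
#' @export
as_scenario <- function(x) {
  if (inherits(x, "scenario_config")) return(x)
  presets <- scenario_presets()
  nm <- match.arg(gsub("-", "_", tolower(x)), names(presets))
  presets[[nm]]
}

#' Run a scenario end to end
#'
#' Pipeline: optional [day_substitute()]; [chained_impute()] (with partial
#' days censored or demoted per the scenario, auxiliaries included or
#' not); [apply_delta()] when MAR is not assumed; [week_average()];
#' [fit_primary()] on each imputation; [pool_rubin()]; [arm_contrasts()].
#' Substitution happens before bound construction so substituted partial
#' records carry their censoring bounds.
#'
#' @param dataset a classified [trial_dataset()] (with week-2 records if
#'   the scenario substitutes days).
#' @param scenario a `scenario_config` or preset name.
#' @param spec an [imputation_spec()]; its seed fixes all randomness, and
#'   the run manifest suffices to reproduce the result bit for bit.
#' @param keep_imputations return the `imputed_set` as well?
#' @return object of class `scenario_result`: `pooled`, `contrasts`,
#'   `manifest` and (optionally) `imputed`.
#' @export
run_scenario <- function(dataset, scenario = "plausible",
                         spec = imputation_spec(),
                         keep_imputations = FALSE) {
  scenario <- as_scenario(scenario)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("scenario '", scenario$name, "', stage ", what, ": ",
           conditionMessage(e), call. = FALSE))
  }
  if (scenario$use_day_substitution)
    dataset <- stage("day_substitute", day_substitute(dataset))
  imputed <- stage("chained_impute", chained_impute(
    dataset, spec, use_auxiliaries = scenario$use_auxiliaries,
    impute_partial_as_censored = scenario$impute_partial_as_censored))
  if (!scenario$assume_mar)
    imputed <- stage("apply_delta",
                     apply_delta(imputed, delta = scenario$delta))
  pooled <- stage("analysis", analyze_imputed(imputed))
  contrasts <- arm_contrasts(pooled)
  manifest <- list(scenario = unclass(scenario), M = spec$M,
                   cycles = spec$cycles, seed = spec$seed,
                   log_offset = spec$log_offset,
                   upper_mult = spec$upper_mult,
                   pool_arms = spec$pool_arms,
                   package_version = as.character(packageVersion("accelmi")))
  out <- list(pooled = pooled, contrasts = contrasts, manifest = manifest)
  if (keep_imputations) out$imputed <- imputed
  structure(out, class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario '%s' (M = %d, cycles = %d, seed = %d)\n",
              x$manifest$scenario$name, x$manifest$M, x$manifest$cycles,
              x$manifest$seed))
  cat("contrasts vs usual care (steps/day):\n")
  tab <- x$contrasts
  tab[3:7] <- lapply(tab[3:7], function(v) round(v, 1))
  print(tab, row.names = FALSE)
  invisible(x)
}
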