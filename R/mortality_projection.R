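# Mortality cost of carbon: the published estimate that every 4400
# metric tons (4.4e9 g) of CO2eq added to the 2020 baseline causes one
# temperature-related excess death globally by 2100. Dividing that budget
# by a model's per-use emission gives the number of inferences a region's
# grid can support before one statistical excess death.

#' Mortality-cost configuration
#'
#' @param mcc_grams_per_death CO2eq mass associated with one
#'   temperature-related excess death; default 4.4e9 g (4400 t).
#' @param prevalence optional named numeric vector of per-class positive
#'   rates in \[0, 1\], used to convert usage budgets into expected
#'   positive predictions.
#' @return list of class `mortality_config`.
#' @export
mortality_config <- function(mcc_grams_per_death = 4.4e9, prevalence = NULL) {
  if (mcc_grams_per_death <= 0) stop("mcc must be positive", call. = FALSE)
  if (!is.null(prevalence) &&
      (any(prevalence < 0) || any(prevalence > 1))) {
    stop("prevalence rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(mcc_grams_per_death = mcc_grams_per_death,
                 prevalence = prevalence),
            class = "mortality_config")
}

#' Usage budget before one excess death
#'
#' Number of model inferences a region can run before the cumulative
#' CO2eq reaches the mortality cost of carbon:
#' `floor(mcc / (energy_Wh / 1000 * intensity))`. Returns `Inf` (an
#' unbounded budget, with a warning) when the per-use emission is zero,
#' rather than crashing on the division.
#'
#' @param energy_wh_per_use per-inference energy in Wh (facility level).
#' @param intensity_g_per_kwh regional carbon intensity.
#' @param cfg a [mortality_config()].
#' @return whole number of usages (possibly `Inf`).
#' @export
usages_until_one_death <- function(energy_wh_per_use, intensity_g_per_kwh,
                                   cfg = mortality_config()) {
  if (any(energy_wh_per_use < 0) || any(intensity_g_per_kwh < 0)) {
    stop("energy and intensity must be non-negative", call. = FALSE)
  }
  g_per_use <- energy_wh_per_use / 1000 * intensity_g_per_kwh
  out <- ifelse(g_per_use == 0, Inf, floor(cfg$mcc_grams_per_death / g_per_use))
  if (any(is.infinite(out))) {
    warning("zero per-use emission: usage budget is unbounded", call. = FALSE)
  }
  out
}

#' Expected positive predictions over a usage budget
#'
#' @param usages number of inferences (from [usages_until_one_death()]).
#' @param cfg a [mortality_config()] with `prevalence` set.
#' @param class_name class whose prevalence to apply.
#' @return `floor(usages * prevalence[class_name])`.
#' @export
positive_predictions <- function(usages, cfg, class_name) {
  if (is.null(cfg$prevalence) || is.na(match(class_name, names(cfg$prevalence)))) {
    stop("no prevalence defined for class '", class_name, "'", call. = FALSE)
  }
  floor(usages * cfg$prevalence[[class_name]])
}

#' Country-by-model usage budget comparison
#'
#' Crosses every model in a series with every region in an intensity
#' table: per-use emission at the region's carbon intensity, the usage
#' budget before one excess death, and (when prevalences are configured)
#' expected positive predictions per class. The within-country model
#' ordering is identical in every country, since intensity enters every
#' model's budget as the same multiplicative factor.
#'
#' @param series a [benchmark_series()] with `infer_energy_wh` present.
#' @param intensity_table an [load_intensity_table()] result.
#' @param cfg a [mortality_config()].
#' @return tibble: `country`, `model_id`, `g_per_use`, `usages_budget`,
#'   and one `positives_<class>` column per configured prevalence class.
#' @export
country_comparison <- function(series, intensity_table,
                               cfg = mortality_config()) {
  stopifnot(inherits(series, "benchmark_series"))
  if (nrow(intensity_table) == 0) stop("empty intensity table", call. = FALSE)
  if (is.null(series[["infer_energy_wh"]]) || anyNA(series$infer_energy_wh)) {
    stop("per-use inference energy (infer_energy_wh) required for every model",
         call. = FALSE)
  }
  regions <- unique(intensity_table$region)
  rows <- lapply(regions, function(rg) {
    intensity <- intensity_lookup(intensity_table, rg)
    g_per_use <- series$infer_energy_wh / 1000 * intensity
    budget <- usages_until_one_death(series$infer_energy_wh, intensity, cfg)
    out <- tibble::tibble(country = rg, model_id = series$model_id,
                          g_per_use = g_per_use, usages_budget = budget)
    for (cl in names(cfg$prevalence)) {
      out[[paste0("positives_", cl)]] <- positive_predictions(budget, cfg, cl)
    }
    out
  })
  do.call(rbind, rows)
}
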