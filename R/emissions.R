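# Energy -> CO2eq conversion and emission accumulation. Energies are in
# Wh, intensities in g CO2eq per kWh, emissions in g CO2eq. Values are
# stored at full precision; rounding happens only in rendered reports.

#' Emission configuration
#'
#' @param intensity_g_per_kwh regional carbon intensity (g CO2eq per kWh
#'   of electricity produced), a non-negative scalar.
#' @param pue power usage effectiveness of the facility: total facility
#'   energy divided by IT-device energy, >= 1. Applied only to
#'   measurements whose meter did not already include it.
#' @return list of class `emission_config`.
#' @export
emission_config <- function(intensity_g_per_kwh, pue = 1.58) {
  stopifnot(is.numeric(intensity_g_per_kwh), intensity_g_per_kwh >= 0)
  if (pue < 1) stop("pue must be >= 1 (facility/IT energy ratio)", call. = FALSE)
  structure(list(intensity_g_per_kwh = intensity_g_per_kwh, pue = pue),
            class = "emission_config")
}

#' Convert measured energy to CO2eq emissions
#'
#' grams = energy_Wh / 1000 * intensity_g_per_kWh, after multiplying
#' device-level measurements by the facility PUE. The derivation (energy,
#' intensity, pue factor) is attached as an attribute for report
#' serialization.
#'
#' @param energy_wh measured energy in Wh (vectorized), >= 0.
#' @param cfg an [emission_config()].
#' @param pue_applied if `TRUE` (default) the measurement already reflects
#'   facility-level draw and `cfg$pue` is not applied again; set `FALSE`
#'   for raw device readings.
#' @return emissions in g CO2eq, with a `derivation` attribute.
#' @export
energy_to_co2eq <- function(energy_wh, cfg, pue_applied = TRUE) {
  stopifnot(inherits(cfg, "emission_config"))
  if (any(energy_wh < 0)) stop("negative energy", call. = FALSE)
  eff_wh <- if (pue_applied) energy_wh else energy_wh * cfg$pue
  g <- eff_wh / 1000 * cfg$intensity_g_per_kwh
  attr(g, "derivation") <- list(energy_wh = eff_wh,
                                intensity_g_per_kwh = cfg$intensity_g_per_kwh,
                                pue_factor = if (pue_applied) 1 else cfg$pue)
  g
}

#' Mean per-slide emission over replicate measurements
#'
#' @param replicates numeric vector of per-slide emissions (g CO2eq), one
#'   per replicate run.
#' @return arithmetic mean with attribute `n_replicates` (kept for the
#'   bootstrap in [esper_ci()]).
#' @export
mean_per_slide_emission <- function(replicates) {
  if (length(replicates) == 0) stop("no replicates supplied", call. = FALSE)
  if (any(replicates < 0)) stop("negative emission replicate", call. = FALSE)
  structure(mean(replicates), n_replicates = length(replicates))
}

#' Combined training + usage emission
#'
#' Total operational footprint after a number of inferences:
#' train + n_usage * (per-use inference + per-use overhead). Affine and
#' non-decreasing in `n_usage`.
#'
#' @param train_g training emission in g CO2eq (vectorized over models).
#' @param infer_g_per_use per-inference emission in g CO2eq.
#' @param n_usage number of inferences, >= 0.
#' @param overhead_g_per_use additive per-use emission (e.g. a gradient
#'   class-activation heatmap adds ~0.013 g per slide); default 0.
#' @return combined emission in g CO2eq.
#' @export
combined_emission <- function(train_g, infer_g_per_use, n_usage,
                              overhead_g_per_use = 0) {
  if (any(n_usage < 0)) stop("n_usage must be >= 0", call. = FALSE)
  if (any(train_g < 0) || any(infer_g_per_use < 0) || any(overhead_g_per_use < 0)) {
    stop("negative emission", call. = FALSE)
  }
  train_g + n_usage * (infer_g_per_use + overhead_g_per_use)
}

#' Format an emission for human-readable reports
#'
#' Chooses g or kg by magnitude and rounds to 3 decimals, the convention
#' of published benchmark tables. Stored values are never rounded.
#'
#' @param grams emission in g CO2eq.
#' @return character scalar like `"4.065 kg"` or `"0.046 g"`.
#' @export
format_emission <- function(grams) {
  ifelse(grams >= 1000,
         sprintf("%.3f kg", grams / 1000),
         sprintf("%.3f g", grams))
}
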