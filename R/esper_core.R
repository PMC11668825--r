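# The ESPer scores. For model i in a comparison series with performance
# metric M_i in [0,1] and emission E_i:
#
#   score_i = M_i^2 / exp(w * norm(E_i)),   norm(x) = (x - min E) / (max E - min E)
#
# The square rewards highly accurate models; the exponential penalizes
# high emissions while avoiding a zero division at the series minimum.
# iESPer uses per-inference emissions; fpESPer uses training emissions
# plus projected cumulative inference emissions. Scores are
# series-relative: normalization bounds are the min and max emission of
# the series, so adding or removing a model changes every score.

#' Range-normalize a vector of emissions
#'
#' Maps the series minimum to 0 and maximum to 1. A degenerate series
#' (all values equal, including a single value) maps everything to 0:
#' with no emission spread there is no information to discriminate on,
#' and the score reduces to the squared metric, consistent with the
#' `w = 0` limit.
#'
#' @param values non-negative numeric vector.
#' @return values scaled to \[0, 1\].
#' @export
range_normalize <- function(values) {
  if (length(values) == 0) stop("cannot normalize an empty series", call. = FALSE)
  if (any(values < 0)) stop("negative emission in series", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' ESPer configuration
#'
#' @param w weighting factor in \[0, 1\] scaling the emission penalty:
#'   `w = 1` is the default full weighting, `w = 0` scores performance
#'   only.
#' @param metric one of `auroc`, `balanced_accuracy`, `precision`,
#'   `recall`, `f1`.
#' @return list of class `esper_config`.
#' @export
esper_config <- function(w = 1, metric = "auroc") {
  if (!is.numeric(w) || w < 0 || w > 1) {
    stop("weighting factor w must lie in [0, 1]", call. = FALSE)
  }
  metric <- match.arg(metric, METRIC_NAMES)
  structure(list(w = w, metric = metric), class = "esper_config")
}

series_metric <- function(series, metric) {
  col <- paste0("metric_", metric)
  if (is.null(series[[col]])) {
    stop("metric '", metric, "' not present in series", call. = FALSE)
  }
  v <- series[[col]]
  if (anyNA(v)) {
    stop(sprintf("model %s is missing metric '%s'",
                 series$model_id[which(is.na(v))[1]], metric), call. = FALSE)
  }
  v
}

esper_from_values <- function(model_id, metric_value, emissions, w) {
  norm <- range_normalize(emissions)
  penalty <- exp(w * norm)
  tibble::tibble(
    model_id = model_id,
    value = metric_value^2 / penalty,
    metric_value = metric_value,
    metric_squared = metric_value^2,
    emission_g = emissions,
    normalized_emission = norm,
    penalty = penalty,
    w = w
  )
}

#' Inference ESPer (iESPer) scores for a benchmark series
#'
#' Scores every model by its squared metric divided by the exponential
#' penalty on range-normalized per-inference emissions.
#'
#' @param series a [benchmark_series()].
#' @param cfg an [esper_config()] (or pass `w`/`metric` directly).
#' @param w,metric shortcut arguments used when `cfg` is missing.
#' @return tibble with one row per model: `model_id`, `value`,
#'   `metric_value`, `metric_squared`, `emission_g`,
#'   `normalized_emission`, `penalty`, `w`, `rank`.
#' @export
iesper <- function(series, cfg = esper_config(w, metric), w = 1,
                   metric = "auroc") {
  stopifnot(inherits(series, "benchmark_series"), inherits(cfg, "esper_config"))
  m <- series_metric(series, cfg$metric)
  scores <- esper_from_values(series$model_id, m, series$infer_co2eq_g, cfg$w)
  scores$rank <- rank_scores(scores$value, scores$emission_g, scores$model_id)
  scores
}

#' Future-projection ESPer (fpESPer) scores
#'
#' Scores the series on combined emissions after `n_usage` inferences:
#' training emission plus `n_usage` times the per-use (inference +
#' overhead) emission. The normalization bounds are recomputed over the
#' combined emissions at this `n_usage`, which is what lets model
#' rankings change over a usage horizon.
#'
#' @inheritParams iesper
#' @param n_usage projected number of inferences, >= 0.
#' @return tibble as in [iesper()], with an extra `n_usage` column.
#' @export
fpesper <- function(series, cfg = esper_config(w, metric), n_usage = 0,
                    w = 1, metric = "auroc") {
  stopifnot(inherits(series, "benchmark_series"), inherits(cfg, "esper_config"))
  m <- series_metric(series, cfg$metric)
  comb <- combined_emission(series$train_co2eq_g, series$infer_co2eq_g,
                            n_usage, series$overhead_co2eq_g)
  scores <- esper_from_values(series$model_id, m, comb, cfg$w)
  scores$n_usage <- n_usage
  scores$rank <- rank_scores(scores$value, scores$emission_g, scores$model_id)
  scores
}

# Deterministic ranking: higher score first; ties broken by lower
# emission, then lexicographic model_id.
rank_scores <- function(value, emission, model_id) {
  ord <- order(-value, emission, model_id)
  rk <- integer(length(value))
  rk[ord] <- seq_along(ord)
  rk
}

#' fpESPer projection curves over a usage horizon
#'
#' Evaluates [fpesper()] on a uniform time grid with
#' `n_usage(t) = round(annual_usage * t)` (usages are whole inferences).
#'
#' @inheritParams iesper
#' @param annual_usage projected inferences per year, >= 0.
#' @param years horizon length in years, > 0.
#' @param grid_points number of evaluation points (including both ends).
#' @return long tibble: `model_id`, `years`, `n_usage`, `fpesper`,
#'   plus the component columns of [fpesper()].
#' @export
projection_curve <- function(series, cfg = esper_config(w, metric),
                             annual_usage, years = 5, grid_points = 101,
                             w = 1, metric = "auroc") {
  if (years <= 0) stop("projection horizon must be positive", call. = FALSE)
  if (annual_usage < 0) stop("annual_usage must be >= 0", call. = FALSE)
  if (grid_points < 2) stop("need at least 2 grid points", call. = FALSE)
  t_grid <- seq(0, years, length.out = grid_points)
  rows <- lapply(t_grid, function(t) {
    sc <- fpesper(series, cfg, n_usage = round(annual_usage * t))
    sc$years <- t
    sc
  })
  out <- do.call(rbind, rows)
  out$fpesper <- out$value
  out[, c("model_id", "years", "n_usage", "fpesper", "metric_value",
          "metric_squared", "emission_g", "normalized_emission", "penalty",
          "w", "rank")]
}

# fpESPer for two named models as a continuous function of (real-valued)
# n_usage, used to refine crossings located on the sampled grid.
fpesper_pair_diff <- function(series, cfg, model_a, model_b) {
  m <- series_metric(series, cfg$metric)
  ia <- match(model_a, series$model_id)
  ib <- match(model_b, series$model_id)
  if (is.na(ia) || is.na(ib)) stop("model not found in series", call. = FALSE)
  function(n) {
    comb <- combined_emission(series$train_co2eq_g, series$infer_co2eq_g, n,
                              series$overhead_co2eq_g)
    norm <- range_normalize(comb)
    m[ia]^2 / exp(cfg$w * norm[ia]) - m[ib]^2 / exp(cfg$w * norm[ib])
  }
}

#' Locate fpESPer crossings between two models
#'
#' Finds the usage counts at which two models' fpESPer curves cross:
#' sign changes of their score difference are located on a sampled grid
#' and refined by bisection on the continuous formula (real-valued
#' `n_usage`) to relative tolerance 1e-6. Curves that merely touch or are
#' identical yield an empty result.
#'
#' @inheritParams projection_curve
#' @param model_a,model_b model ids present in the series.
#' @return tibble with columns `n_usage` and `years` (empty when the
#'   curves never cross on the horizon).
#' @export
find_crossings <- function(series, model_a, model_b,
                           cfg = esper_config(w, metric), annual_usage,
                           years = 5, grid_points = 512,
                           w = 1, metric = "auroc") {
  if (years <= 0) stop("projection horizon must be positive", call. = FALSE)
  diff_fn <- fpesper_pair_diff(series, cfg, model_a, model_b)
  n_grid <- seq(0, annual_usage * years, length.out = grid_points)
  d <- vapply(n_grid, diff_fn, numeric(1))
  sgn <- sign(d)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  n_cross <- vapply(flips, function(i) {
    stats::uniroot(diff_fn, lower = n_grid[i], upper = n_grid[i + 1],
                   tol = max(1e-8 * n_grid[i + 1], 1e-10))$root
  }, numeric(1))
  # grid nodes that are exact zeros between opposite signs
  zero_nodes <- which(d == 0)
  zero_nodes <- zero_nodes[zero_nodes > 1 & zero_nodes < length(d) &
                             sgn[pmax(zero_nodes - 1, 1)] *
                               sgn[pmin(zero_nodes + 1, length(d))] < 0]
  n_cross <- sort(unique(c(n_cross, n_grid[zero_nodes])))
  tibble::tibble(
    n_usage = n_cross,
    years = if (annual_usage > 0) n_cross / annual_usage else rep(NA_real_, length(n_cross))
  )
}

#' Ranking sensitivity to the weighting factor
#'
#' Recomputes iESPer scores and rankings over a grid of weighting
#' factors. Ties are broken by lower emission, then model id.
#'
#' @param series a [benchmark_series()].
#' @param metric metric name.
#' @param w_grid numeric vector of weighting factors, all in \[0, 1\].
#' @return long tibble: `w`, `model_id`, `value`, `rank`.
#' @export
weight_sweep <- function(series, metric = "auroc",
                         w_grid = seq(0, 1, by = 0.05)) {
  if (any(w_grid < 0 | w_grid > 1)) {
    stop("all weighting factors must lie in [0, 1]", call. = FALSE)
  }
  rows <- lapply(w_grid, function(wv) {
    sc <- iesper(series, esper_config(w = wv, metric = metric))
    tibble::tibble(w = wv, model_id = sc$model_id, value = sc$value,
                   rank = sc$rank)
  })
  do.call(rbind, rows)
}

#' Bootstrap confidence intervals for iESPer scores
#'
#' Percentile bootstrap (2.5/97.5) propagating both sources of sampling
#' noise: per-case predictions are resampled with replacement to vary the
#' performance metric, and per-replicate emission measurements are
#' resampled to vary the mean per-use emission. Scores are recomputed on
#' the full series at every draw, so the interval reflects the
#' series-relative normalization.
#'
#' @param series a [benchmark_series()].
#' @param predictions named list (by model_id) of prediction tables.
#' @param emission_replicates named list (by model_id) of numeric vectors
#'   of per-slide emission replicates (g CO2eq).
#' @param cfg an [esper_config()].
#' @param n_boot bootstrap draws; fewer than 100 triggers a warning.
#' @param seed integer seed; the run is reproducible given the seed.
#' @return tibble: `model_id`, `value` (point score from the series as
#'   given), `ci_low`, `ci_high`.
#' @export
esper_ci <- function(series, predictions, emission_replicates,
                     cfg = esper_config(), n_boot = 1000, seed = 1) {
  stopifnot(inherits(series, "benchmark_series"))
  ids <- series$model_id
  if (!all(ids %in% names(predictions))) {
    stop("missing prediction table for model(s): ",
         paste(setdiff(ids, names(predictions)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(ids %in% names(emission_replicates))) {
    stop("missing emission replicates for model(s): ",
         paste(setdiff(ids, names(emission_replicates)), collapse = ", "),
         call. = FALSE)
  }
  if (n_boot < 100) {
    warning("n_boot < 100 gives unstable percentile intervals", call. = FALSE)
  }
  point <- iesper(series, cfg)
  metric_fun <- function(preds) {
    if (cfg$metric == "auroc") macro_auroc(preds) else
      classification_report(preds)[[cfg$metric]]
  }
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      m_b <- vapply(ids, function(id) {
        preds <- predictions[[id]]
        idx <- sample.int(nrow(preds), replace = TRUE)
        res <- tryCatch(metric_fun(validate_predictions(preds[idx, ])),
                        error = function(e) NA_real_)
        res
      }, numeric(1))
      e_b <- vapply(ids, function(id) {
        reps <- emission_replicates[[id]]
        mean(reps[sample.int(length(reps), replace = TRUE)])
      }, numeric(1))
      if (anyNA(m_b)) return(rep(NA_real_, length(ids)))
      esper_from_values(ids, m_b, e_b, cfg$w)$value
    }, numeric(length(ids)))
  })
  boot <- matrix(boot, nrow = length(ids))
  ci <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  tibble::tibble(model_id = ids, value = point$value,
                 ci_low = ci[1, ], ci_high = ci[2, ])
}
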