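# Deterministic stand-ins for GPU energy metering and real cohorts, so
# the whole pipeline runs at a desk without slides or hardware counters:
# a mock energy meter driven by a tile-count cost model, a model-zoo
# generator producing series with realistic emission magnitudes
# (training of a few to a few tens of kg CO2eq, inference of a fraction
# of a gram per slide), and a binormal prediction simulator whose
# two-class macro AUROC has the closed form pnorm(d_prime / sqrt(2)).

#' Cost model for the mock energy meter
#'
#' @param wh_per_tile_inference facility-level energy per tile inference
#'   (Wh/tile), > 0.
#' @param train_multiplier backpropagation overhead: training energy per
#'   tile pass relative to inference, > 0.
#' @param epochs training epochs, default 300.
#' @param n_train_slides slides in the training set, default 1000.
#' @param pue facility power usage effectiveness, >= 1; set 1 when
#'   `wh_per_tile_inference` is already facility-level.
#' @param noise_cv coefficient of variation of multiplicative replicate
#'   noise, >= 0.
#' @return list of class `cost_model`.
#' @export
cost_model <- function(wh_per_tile_inference, train_multiplier = 0.3,
                       epochs = 300, n_train_slides = 1000, pue = 1,
                       noise_cv = 0) {
  stopifnot(wh_per_tile_inference > 0, train_multiplier > 0, epochs >= 1,
            n_train_slides >= 1, pue >= 1, noise_cv >= 0)
  structure(list(wh_per_tile_inference = wh_per_tile_inference,
                 train_multiplier = train_multiplier, epochs = epochs,
                 n_train_slides = n_train_slides, pue = pue,
                 noise_cv = noise_cv),
            class = "cost_model")
}

#' Mock energy meter
#'
#' Deterministic replacement for hardware power measurement. Inference
#' energy for one slide of `n_tiles` tiles is
#' `n_tiles * wh_per_tile * pue * (1 + eps)` with
#' `eps ~ Normal(0, noise_cv)` truncated at -0.99; training energy is
#' additionally multiplied by `epochs * train_multiplier * n_train_slides`.
#' Fixed seeds give identical readings.
#'
#' @param n_tiles tiles processed per slide, >= 0.
#' @param cost a [cost_model()].
#' @param phase `"inference"` or `"training"`.
#' @param seed integer seed (required when `noise_cv > 0`).
#' @param n_replicates number of replicate readings to return.
#' @return numeric vector of energies in Wh, length `n_replicates`.
#' @export
mock_meter <- function(n_tiles, cost, phase = c("inference", "training"),
                       seed = 1, n_replicates = 1) {
  phase <- match.arg(phase)
  if (n_tiles < 0) stop("n_tiles must be >= 0", call. = FALSE)
  stopifnot(inherits(cost, "cost_model"))
  base <- n_tiles * cost$wh_per_tile_inference * cost$pue
  if (phase == "training") {
    base <- base * cost$epochs * cost$train_multiplier * cost$n_train_slides
  }
  eps <- if (cost$noise_cv > 0) {
    withr::with_seed(seed, pmax(stats::rnorm(n_replicates, 0, cost$noise_cv), -0.99))
  } else {
    rep(0, n_replicates)
  }
  base * (1 + eps)
}

#' Simulate per-case class-probability predictions of known skill
#'
#' Binormal score model. For two classes, each case carries a latent
#' discriminant `x ~ Normal(d_prime * 1[label = 1], 1)` and the class-1
#' probability is a strictly increasing logistic map of `x`, so the
#' one-vs-rest AUROC of either class is exactly
#' `pnorm(d_prime / sqrt(2))`. For K > 2 classes, the true class's score
#' is drawn from `Normal(d_prime, 1)` and the others from `Normal(0, 1)`,
#' with a softmax map to probabilities; the per-class AUROC then has no
#' simple closed form and the two-class expression is only an
#' approximation.
#'
#' @param d_prime separation parameter, >= 0.
#' @param n_cases number of cases; must be >= `n_classes`.
#' @param n_classes K >= 2.
#' @param seed integer seed.
#' @return a validated prediction table (tibble).
#' @export
simulate_predictions <- function(d_prime, n_cases, n_classes = 2, seed = 1) {
  stopifnot(d_prime >= 0, n_classes >= 2, n_cases >= n_classes)
  tbl <- withr::with_seed(seed, {
    # guarantee every class is observed: one case per class, rest uniform
    y <- c(seq_len(n_classes) - 1L,
           sample.int(n_classes, n_cases - n_classes, replace = TRUE) - 1L)
    y <- sample(y)
    if (n_classes == 2) {
      x <- stats::rnorm(n_cases, mean = d_prime * (y == 1), sd = 1)
      p1 <- stats::plogis(x - d_prime / 2)
      tibble::tibble(case_id = sprintf("case_%05d", seq_len(n_cases)),
                     true_label = y, prob_0 = 1 - p1, prob_1 = p1)
    } else {
      s <- matrix(stats::rnorm(n_cases * n_classes), n_cases, n_classes)
      s[cbind(seq_len(n_cases), y + 1L)] <-
        s[cbind(seq_len(n_cases), y + 1L)] + d_prime
      p <- exp(s - apply(s, 1, max))
      p <- p / rowSums(p)
      out <- tibble::tibble(case_id = sprintf("case_%05d", seq_len(n_cases)),
                            true_label = y)
      for (k in seq_len(n_classes)) out[[paste0("prob_", k - 1)]] <- p[, k]
      out
    }
  })
  validate_predictions(tbl)
}

#' Generate a synthetic model zoo
#'
#' Draws per-model cost models and skill levels from seeded ranges chosen
#' to emulate published whole-slide-image benchmark magnitudes: per-slide
#' inference around 0.04--0.5 Wh (0.015--0.18 g CO2eq at 361 g/kWh) and
#' training emissions confined to 1--50 kg CO2eq by construction. Metrics
#' are computed end-to-end from simulated predictions through
#' [all_metrics()], and emissions from the mock meter through
#' [energy_to_co2eq()].
#'
#' @param n_models number of models, >= 2.
#' @param seed integer seed; fixed seeds give byte-identical series.
#' @param intensity_g_per_kwh carbon intensity for the emission
#'   conversion; default 361 (German grid).
#' @param n_cases evaluation cohort size per model.
#' @param n_classes classes in the simulated task.
#' @param n_tiles tiles per slide in the cost model.
#' @param noise_cv replicate noise of the mock meter.
#' @param keep_predictions if `TRUE`, attach the per-model prediction
#'   tables (attribute `predictions`, a named list) and per-model
#'   inference-emission replicates (attribute `emission_replicates`) for
#'   downstream bootstrap use.
#' @return a [benchmark_series()] with energy and emission columns.
#' @export
generate_model_zoo <- function(n_models, seed = 1, intensity_g_per_kwh = 361,
                               n_cases = 300, n_classes = 3, n_tiles = 1000,
                               noise_cv = 0.05, keep_predictions = FALSE) {
  if (n_models < 2) stop("a comparison series needs at least 2 models", call. = FALSE)
  cfg <- emission_config(intensity_g_per_kwh, pue = 1.58)
  draws <- withr::with_seed(seed, {
    list(
      wh_per_tile = exp(stats::runif(n_models, log(4e-5), log(5e-4))),
      train_mult = stats::runif(n_models, 0.25, 0.9),
      d_prime = stats::runif(n_models, 0.5, 3.5),
      sub_seeds = sample.int(.Machine$integer.max %/% 2, 2 * n_models)
    )
  })
  infer_replicates <- list()
  prediction_tables <- list()
  entries <- lapply(seq_len(n_models), function(i) {
    cm <- cost_model(draws$wh_per_tile[i], train_multiplier = draws$train_mult[i],
                     epochs = 300, n_train_slides = 1000, pue = 1,
                     noise_cv = noise_cv)
    reps_wh <- mock_meter(n_tiles, cm, "inference",
                          seed = draws$sub_seeds[2 * i - 1],
                          n_replicates = 15)
    infer_wh <- mean(reps_wh)
    # training is a single run (no replicate averaging), metered without
    # noise so the generated training emissions stay in 1-50 kg by
    # construction
    cm_train <- cost_model(draws$wh_per_tile[i],
                           train_multiplier = draws$train_mult[i],
                           epochs = 300, n_train_slides = 1000, pue = 1,
                           noise_cv = 0)
    train_wh <- mock_meter(n_tiles, cm_train, "training", n_replicates = 1)
    preds <- simulate_predictions(draws$d_prime[i], n_cases, n_classes,
                                  seed = draws$sub_seeds[2 * i])
    id <- sprintf("model_%02d", i)
    infer_replicates[[id]] <<- as.numeric(energy_to_co2eq(reps_wh, cfg))
    prediction_tables[[id]] <<- preds
    m <- all_metrics(preds)
    tibble::tibble(
      model_id = sprintf("model_%02d", i),
      metric_auroc = m[["auroc"]],
      metric_balanced_accuracy = m[["balanced_accuracy"]],
      metric_precision = m[["precision"]],
      metric_recall = m[["recall"]],
      metric_f1 = m[["f1"]],
      train_energy_wh = train_wh,
      infer_energy_wh = infer_wh,
      train_co2eq_g = as.numeric(energy_to_co2eq(train_wh, cfg)),
      infer_co2eq_g = as.numeric(energy_to_co2eq(infer_wh, cfg))
    )
  })
  zoo <- benchmark_series(do.call(rbind, entries), task_label = "synthetic_zoo")
  if (keep_predictions) {
    attr(zoo, "predictions") <- prediction_tables
    attr(zoo, "emission_replicates") <- infer_replicates
  }
  zoo
}
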