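# Canonical internal units: energy in Wh, emissions in grams CO2eq.
# Interface files use the mixed units of published benchmark tables
# (kWh/kg for training, Wh/g for inference); conversion happens once,
# at load time, so no 10^3 factor can slip in downstream.

METRIC_NAMES <- c("auroc", "balanced_accuracy", "precision", "recall", "f1")

#' Construct a benchmark series
#'
#' A benchmark series is the set of models over which ESPer scores are
#' computed. ESPer is series-relative: emissions are range-normalized over
#' the members of one series, so adding or removing a model changes every
#' score. A series is stored as a tibble with one row per model and
#' canonical units (energy in Wh, emissions in g CO2eq).
#'
#' @param entries data frame with columns `model_id`, one or more
#'   `metric_<name>` columns (`name` in `auroc`, `balanced_accuracy`,
#'   `precision`, `recall`, `f1`; values in \[0, 1\]), `train_co2eq_g`,
#'   `infer_co2eq_g` (per use), and optionally `train_energy_wh`,
#'   `infer_energy_wh`, `overhead_co2eq_g` (a per-use additive emission,
#'   e.g. a heatmap-visualization add-on).
#' @param task_label short label for the classification task.
#' @return object of class `benchmark_series`: a tibble with attribute
#'   `task_label`.
#' @examples
#' benchmark_series(
#'   data.frame(
#'     model_id = c("A", "B"),
#'     metric_auroc = c(0.9, 0.8),
#'     train_co2eq_g = c(4000, 9000),
#'     infer_co2eq_g = c(0.05, 0.07)
#'   ),
#'   task_label = "toy"
#' )
#' @export
benchmark_series <- function(entries, task_label = "") {
  entries <- tibble::as_tibble(entries)
  validate_series_frame(entries)
  if (is.null(entries[["overhead_co2eq_g"]])) entries$overhead_co2eq_g <- 0
  structure(entries,
            class = c("benchmark_series", class(entries)),
            task_label = task_label)
}

#' @export
print.benchmark_series <- function(x, ...) {
  cat(sprintf("<benchmark_series> task '%s', %d models\n",
              attr(x, "task_label"), nrow(x)))
  NextMethod()
}

validate_series_frame <- function(df) {
  if (nrow(df) == 0) {
    stop("benchmark series is empty: at least one model entry is required",
         call. = FALSE)
  }
  if (is.null(df[["model_id"]])) {
    stop("missing required column 'model_id'", call. = FALSE)
  }
  dup <- df$model_id[duplicated(df$model_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate model_id: %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  metric_cols <- intersect(paste0("metric_", METRIC_NAMES), names(df))
  if (length(metric_cols) == 0) {
    stop("no metric columns found (expected at least one of metric_",
         paste(METRIC_NAMES, collapse = ", metric_"), ")", call. = FALSE)
  }
  for (col in metric_cols) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad) > 0) {
      stop(sprintf(
        "row %d, field %s: value %g outside the metric range [0,1]",
        bad[1], col, v[bad[1]]), call. = FALSE)
    }
  }
  for (col in intersect(c("train_co2eq_g", "infer_co2eq_g", "train_energy_wh",
                          "infer_energy_wh", "overhead_co2eq_g"), names(df))) {
    v <- df[[col]]
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0) {
      stop(sprintf("row %d, field %s: negative value %g",
                   bad[1], col, v[bad[1]]), call. = FALSE)
    }
  }
  invisible(df)
}

#' Load a benchmark series from CSV or JSON
#'
#' Reads the tabular interchange format: columns `model_id`,
#' `metric_auroc`, `metric_balanced_accuracy`, `metric_precision`,
#' `metric_recall`, `metric_f1` (any subset of the metric columns),
#' `train_energy_kwh`, `train_co2eq_kg`, `infer_energy_wh`,
#' `infer_co2eq_g`, optional `overhead_co2eq_g`. Units are canonicalized
#' on load (kWh to Wh, kg to g); row order is preserved. If the emission
#' columns are absent they are derived from the energy columns and
#' `intensity` (g CO2eq per kWh).
#'
#' @param path CSV (`.csv`) or JSON (`.json`) file.
#' @param task_label task label for the series; defaults to the file stem.
#' @param intensity optional carbon intensity in g/kWh used to derive
#'   missing emission columns from energy columns.
#' @return a [benchmark_series()].
#' @export
load_series <- function(path, task_label = NULL, intensity = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_table_auto(path)
  if (is.null(task_label)) {
    task_label <- sub("\\.[^.]+$", "", basename(path))
  }
  if (nrow(df) == 0) stop("empty benchmark file: ", path, call. = FALSE)

  out <- tibble::tibble(model_id = as.character(df$model_id))
  for (m in METRIC_NAMES) {
    col <- paste0("metric_", m)
    if (!is.null(df[[col]])) out[[col]] <- as.numeric(df[[col]])
  }
  if (!is.null(df[["train_energy_kwh"]])) {
    out$train_energy_wh <- as.numeric(df$train_energy_kwh) * 1000
  }
  if (!is.null(df[["infer_energy_wh"]])) {
    out$infer_energy_wh <- as.numeric(df$infer_energy_wh)
  }
  out$train_co2eq_g <- if (!is.null(df[["train_co2eq_kg"]])) {
    as.numeric(df$train_co2eq_kg) * 1000
  } else if (!is.null(out[["train_energy_wh"]]) && !is.null(intensity)) {
    out$train_energy_wh / 1000 * intensity
  } else {
    stop("missing column 'train_co2eq_kg' (or train_energy_kwh + intensity)",
         call. = FALSE)
  }
  out$infer_co2eq_g <- if (!is.null(df[["infer_co2eq_g"]])) {
    as.numeric(df$infer_co2eq_g)
  } else if (!is.null(out[["infer_energy_wh"]]) && !is.null(intensity)) {
    out$infer_energy_wh / 1000 * intensity
  } else {
    stop("missing column 'infer_co2eq_g' (or infer_energy_wh + intensity)",
         call. = FALSE)
  }
  if (!is.null(df[["overhead_co2eq_g"]])) {
    out$overhead_co2eq_g <- as.numeric(df$overhead_co2eq_g)
  }
  benchmark_series(out, task_label = task_label)
}

#' Write a benchmark series to CSV or JSON
#'
#' Inverse of [load_series()]: emits the interchange units (kWh/kg for
#' training, Wh/g for inference) at full stored precision, so a
#' load/write/load round trip reproduces every numeric field exactly.
#'
#' @param series a [benchmark_series()].
#' @param path output `.csv` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "benchmark_series"))
  df <- as.data.frame(series)
  out <- data.frame(model_id = df$model_id)
  for (m in METRIC_NAMES) {
    col <- paste0("metric_", m)
    if (!is.null(df[[col]])) out[[col]] <- df[[col]]
  }
  if (!is.null(df[["train_energy_wh"]])) {
    out$train_energy_kwh <- df$train_energy_wh / 1000
  }
  out$train_co2eq_kg <- df$train_co2eq_g / 1000
  if (!is.null(df[["infer_energy_wh"]])) out$infer_energy_wh <- df$infer_energy_wh
  out$infer_co2eq_g <- df$infer_co2eq_g
  if (any(df$overhead_co2eq_g != 0)) out$overhead_co2eq_g <- df$overhead_co2eq_g
  write_table_auto(out, path)
  invisible(path)
}

#' Load a carbon-intensity table
#'
#' @param path CSV with columns `region`, `year`, `g_per_kwh`.
#' @return tibble of class `intensity_table`, one row per (region, year).
#' @export
load_intensity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("region", "year", "g_per_kwh")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(df$g_per_kwh < 0)
  if (length(bad) > 0) {
    stop(sprintf("row %d, field g_per_kwh: negative intensity %g",
                 bad[1], df$g_per_kwh[bad[1]]), call. = FALSE)
  }
  if (anyDuplicated(df[c("region", "year")])) {
    stop("duplicate (region, year) pair in intensity table", call. = FALSE)
  }
  class(df) <- c("intensity_table", class(df))
  df
}

#' Look up a regional carbon intensity
#'
#' @param table an [load_intensity_table()] result.
#' @param region region code.
#' @param year optional year; the most recent available year is used when
#'   omitted.
#' @return intensity in g CO2eq per kWh.
#' @export
intensity_lookup <- function(table, region, year = NULL) {
  rows <- table[table$region == region, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("region not found in intensity table: ", region, call. = FALSE)
  }
  if (is.null(year)) {
    rows$g_per_kwh[which.max(rows$year)]
  } else {
    hit <- rows[rows$year == year, , drop = FALSE]
    if (nrow(hit) == 0) {
      stop(sprintf("no intensity for region %s in year %d", region, year),
           call. = FALSE)
    }
    hit$g_per_kwh[1]
  }
}

read_table_auto <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    tibble::as_tibble(df)
  }
}

write_table_auto <- function(df, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
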