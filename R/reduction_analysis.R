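# Data-reduction strategies: whole-slide images are processed as square
# tiles defined by a physical edge length (um) and an output pixel
# resolution. Coarser tiles or a random tile subsample reduce per-slide
# inference cost; each candidate configuration is scored by iESPer with
# the sweep itself as the comparison series (its min/max emissions set
# the normalization bounds).

#' Tiles needed to cover a tissue area
#'
#' `ceiling(area_um2 / edge_um^2)`: partial tiles at the border are still
#' processed tiles. Halving the edge length quadruples the count (up to
#' the ceiling).
#'
#' @param tissue_area_mm2 tissue area in mm^2, > 0.
#' @param edge_um physical tile edge length in micrometres, > 0.
#' @return whole number of tiles.
#' @export
tiles_per_slide <- function(tissue_area_mm2, edge_um) {
  if (any(tissue_area_mm2 <= 0)) stop("tissue area must be positive", call. = FALSE)
  if (any(edge_um <= 0)) stop("tile edge length must be positive", call. = FALSE)
  ceiling(tissue_area_mm2 * 1e6 / edge_um^2)
}

score_sweep <- function(labels, performance, emission_g, w) {
  norm <- range_normalize(emission_g)
  tibble::tibble(
    config = labels,
    metric_value = performance,
    emission_g = emission_g,
    normalized_emission = norm,
    penalty = exp(w * norm),
    iesper = performance^2 / exp(w * norm)
  )
}

best_row <- function(scored) {
  ord <- order(-scored$iesper, scored$emission_g, scored$config)
  scored[ord[1], , drop = FALSE]
}

#' Score a tile-size/resolution sweep by iESPer
#'
#' Each (pixels, edge length) configuration of one architecture is a
#' point with a measured performance and per-slide emission; the sweep is
#' scored as its own comparison series and the argmax configuration is
#' returned (ties broken toward lower emission).
#'
#' @param points data frame with columns `pixels`, `edge_um`,
#'   `metric_auroc` (or a `performance` column), `infer_co2eq_g`.
#' @param w weighting factor in \[0, 1\].
#' @return list with `scores` (tibble, one row per config, column
#'   `iesper`) and `best` (the argmax row).
#' @export
resolution_sweep <- function(points, w = 1) {
  points <- tibble::as_tibble(points)
  if (nrow(points) < 2) stop("a sweep needs at least 2 points", call. = FALSE)
  need <- c("pixels", "edge_um", "infer_co2eq_g")
  miss <- setdiff(need, names(points))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "),
                             call. = FALSE)
  perf <- points[["metric_auroc"]] %||% points[["performance"]]
  if (is.null(perf)) stop("missing performance column (metric_auroc)", call. = FALSE)
  if (any(perf < 0 | perf > 1)) stop("performance outside [0, 1]", call. = FALSE)
  labels <- sprintf("%dpx/%dum", points$pixels, points$edge_um)
  if (anyDuplicated(labels)) {
    stop("duplicate tile configuration: ", labels[duplicated(labels)][1],
         call. = FALSE)
  }
  scored <- score_sweep(labels, perf, points$infer_co2eq_g, w)
  scored$pixels <- points$pixels
  scored$edge_um <- points$edge_um
  list(scores = scored, best = best_row(scored))
}

#' Score a tile-fraction sweep by iESPer
#'
#' Scores random-subsample fractions of the available tiles. Fractions
#' must be strictly increasing, end at 1.0 (the full-data reference), and
#' emissions must increase strictly with the fraction (more tiles cost
#' more energy; violated input indicates a corrupted sweep). Besides the
#' argmax fraction, reports the smallest fraction whose performance is
#' within `plateau_tol` of the 100% value.
#'
#' @param points data frame with columns `fraction` (in (0, 1\]),
#'   `metric_auroc` (or `performance`), `infer_co2eq_g`.
#' @param w weighting factor.
#' @param plateau_tol absolute performance tolerance for the plateau
#'   fraction (default 0.005).
#' @return list with `scores`, `best` (argmax row), `optimal_fraction`,
#'   and `plateau_fraction`.
#' @export
fraction_sweep <- function(points, w = 1, plateau_tol = 0.005) {
  points <- tibble::as_tibble(points)
  if (nrow(points) < 2) stop("a sweep needs at least 2 points", call. = FALSE)
  f <- points$fraction
  if (is.null(f)) stop("missing column 'fraction'", call. = FALSE)
  if (any(f <= 0 | f > 1)) stop("fractions must lie in (0, 1]", call. = FALSE)
  if (any(diff(f) <= 0)) stop("fractions must be strictly increasing", call. = FALSE)
  if (f[length(f)] != 1) stop("sweep must include the full-data point (fraction 1.0)",
                              call. = FALSE)
  perf <- points[["metric_auroc"]] %||% points[["performance"]]
  if (is.null(perf)) stop("missing performance column (metric_auroc)", call. = FALSE)
  e <- points$infer_co2eq_g
  if (any(diff(e) <= 0)) {
    stop("emissions must increase strictly with the tile fraction", call. = FALSE)
  }
  labels <- sprintf("frac=%g", f)
  scored <- score_sweep(labels, perf, e, w)
  scored$fraction <- f
  full_perf <- perf[length(perf)]
  plateau_idx <- which(perf >= full_perf - plateau_tol)
  list(scores = scored,
       best = best_row(scored),
       optimal_fraction = scored$fraction[which.max(scored$iesper)],
       plateau_fraction = f[min(plateau_idx)])
}

#' Random tile subsample
#'
#' Draws `floor(fraction * n)` tiles uniformly without replacement,
#' reproducibly under a fixed seed. The returned order is the sampling
#' order, not the input order.
#'
#' @param tile_ids vector of tile identifiers.
#' @param fraction fraction in (0, 1].
#' @param seed integer seed.
#' @return subsampled tile ids.
#' @export
random_tile_subsample <- function(tile_ids, fraction, seed = 1) {
  if (length(tile_ids) == 0) stop("no tiles to subsample", call. = FALSE)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]", call. = FALSE)
  n_keep <- floor(fraction * length(tile_ids))
  withr::with_seed(seed, sample(tile_ids, n_keep, replace = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
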