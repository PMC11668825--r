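test_that("range normalization maps min to 0, max to 1, degenerate to 0", {
  out <- range_normalize(c(0.025, 0.138, 0.383, 1.87))
  expect_equal(out, c(0, 0.113 / 1.845, 0.358 / 1.845, 1))
  expect_equal(range_normalize(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(range_normalize(3), 0)
  withr::with_seed(1, {
    for (i in 1:10) {
      x <- runif(sample(2:10, 1), 0, 100)
      nx <- range_normalize(x)
      expect_equal(nx[which.min(x)], 0)
      expect_equal(nx[which.max(x)], 1)
      expect_true(all(nx >= 0 & nx <= 1))
    }
  })
  expect_error(range_normalize(numeric(0)), "empty")
})

test_that("iESPer reproduces the published resolution-series scores", {
  ser <- benchmark_series(data.frame(
    model_id = c("224px/1024um", "224px/256um", "512px/256um", "224px/128um"),
    metric_auroc = c(0.702, 0.762, 0.678, 0.640),
    train_co2eq_g = 0,
    infer_co2eq_g = c(0.025, 0.138, 0.383, 1.87)))
  sc <- iesper(ser, esper_config(w = 1))
  expect_true(all(abs(sc$value - c(0.493, 0.542, 0.377, 0.151)) <= 0.005))
  # the normalization-bound rows are exact squared-metric / M^2/e values
  expect_equal(round(sc$value[1], 3), 0.493)
  expect_equal(round(sc$value[4], 3), 0.151)
  expect_equal(sc$value, brute_force_esper(sc$metric_value, sc$emission_g, 1))
})

test_that("w = 0 reduces every score to the squared metric", {
  ser <- toy_series()
  sc <- iesper(ser, esper_config(w = 0))
  expect_equal(sc$value, ser$metric_auroc^2)
  fp <- fpesper(ser, esper_config(w = 0), n_usage = 12345)
  expect_equal(fp$value, ser$metric_auroc^2)
})

test_that("the series-minimum-emission model scores exactly its squared metric", {
  withr::with_seed(7, {
    for (i in 1:10) {
      n <- sample(2:8, 1)
      ser <- toy_series(ids = paste0("m", 1:n),
                       auroc = runif(n, 0.5, 1),
                       train_g = runif(n, 10, 1000),
                       infer_g = runif(n, 0.01, 1))
      sc <- iesper(ser)
      i_min <- which.min(ser$infer_co2eq_g)
      expect_equal(sc$value[i_min], ser$metric_auroc[i_min]^2)
      expect_true(all(sc$value <= sc$metric_squared + 1e-12))
      expect_true(all(sc$value >= 0 & sc$value <= 1))
    }
  })
})

test_that("scores are invariant under affine rescaling of emissions", {
  withr::with_seed(21, {
    for (i in 1:10) {
      ser <- toy_series(auroc = runif(3, 0.4, 1), train_g = runif(3, 1, 50),
                        infer_g = runif(3, 0.01, 2))
      ref <- iesper(ser)$value
      a <- runif(1, 0.1, 1000); b <- runif(1, 0, 50)
      ser2 <- ser
      ser2$infer_co2eq_g <- a * ser$infer_co2eq_g + b
      expect_equal(iesper(ser2)$value, ref)
    }
  })
})

test_that("scores are monotone: worse emission lowers, better metric raises", {
  ser <- toy_series()
  base <- iesper(ser)$value
  worse <- ser; worse$infer_co2eq_g[1] <- ser$infer_co2eq_g[1] * 3
  expect_lt(iesper(worse)$value[1], base[1])
  better <- ser; better$metric_auroc[2] <- min(1, ser$metric_auroc[2] + 0.05)
  expect_gt(iesper(better)$value[2], base[2])
})

test_that("fpESPer matches hand arithmetic on the two-model toy", {
  ser <- toy_series(ids = c("A", "B"), auroc = c(0.9, 0.8),
                    train_g = c(100, 50), infer_g = c(0.1, 0.2))
  sc <- fpesper(ser, n_usage = 1000)
  # combined: A 200 g, B 250 g -> norms 0, 1
  expect_equal(sc$emission_g, c(200, 250))
  expect_equal(sc$value, c(0.81, 0.64 / exp(1)))
  # n = 0 with equal training emissions degenerates to squared metrics
  eq <- toy_series(ids = c("A", "B"), auroc = c(0.9, 0.8),
                   train_g = c(70, 70), infer_g = c(0.1, 0.2))
  expect_equal(fpesper(eq, n_usage = 0)$value, c(0.81, 0.64))
})

test_that("the minimum-training-emission model scores M^2 at n_usage = 0", {
  ser <- load_series(extdata("benchmark_ktx.csv"))
  sc <- fpesper(ser, n_usage = 0)
  i_min <- which.min(ser$train_co2eq_g)
  expect_equal(ser$model_id[i_min], "InceptionV3")
  expect_equal(sc$value[i_min], ser$metric_auroc[i_min]^2)
})

test_that("projection curves agree with direct fpESPer calls at the endpoints", {
  ser <- load_series(extdata("benchmark_ktx.csv"))
  cur <- projection_curve(ser, annual_usage = 28189, years = 5,
                          grid_points = 21)
  start <- cur[cur$years == 0, ]
  end <- cur[cur$years == 5, ]
  expect_equal(start$fpesper, fpesper(ser, n_usage = 0)$value)
  expect_equal(end$fpesper, fpesper(ser, n_usage = 140945)$value)
  # zero usage: constant curves
  flat <- projection_curve(ser, annual_usage = 0, years = 5, grid_points = 5)
  spread <- tapply(flat$fpesper, flat$model_id, function(v) max(v) - min(v))
  expect_true(all(spread == 0))
  expect_error(projection_curve(ser, annual_usage = 10, years = 0), "positive")
})

test_that("crossing detection recovers a closed-form crossing to 1e-6", {
  # A overtakes B exactly where combined emissions cross:
  # 100 + 0.1 n = 50 + 0.2 n  =>  n* = 500
  ser <- toy_series(ids = c("A", "B"), auroc = c(0.7, 0.75),
                    train_g = c(100, 50), infer_g = c(0.1, 0.2))
  cr <- find_crossings(ser, "A", "B", annual_usage = 1000, years = 5)
  expect_equal(nrow(cr), 1)
  expect_equal(cr$n_usage, 500, tolerance = 1e-6)
  # brute-force dense scan agrees on the sign-change location
  diffs <- vapply(0:2000, function(n) {
    v <- fpesper(ser, n_usage = n)$value
    v[1] - v[2]
  }, numeric(1))
  flip <- which(diff(sign(diffs)) != 0)
  expect_true(abs(flip - 500) <= 1)
})

test_that("smooth three-model crossing is refined onto the brute-force scan", {
  ser <- toy_series(ids = c("A", "B", "C"), auroc = c(0.80, 0.77, 0.9),
                    train_g = c(5000, 1000, 100), infer_g = c(0.02, 0.08, 0.30))
  cr <- find_crossings(ser, "A", "B", annual_usage = 20000, years = 5)
  expect_gte(nrow(cr), 1)
  # independent dense scan at unit resolution
  ns <- seq(0, 1e5, by = 25)
  d <- vapply(ns, function(n) {
    v <- fpesper(ser, n_usage = n)$value; v[1] - v[2]
  }, numeric(1))
  flips <- ns[which(d[-1] * d[-length(d)] < 0)]
  expect_equal(length(flips), nrow(cr))
  expect_true(all(abs(cr$n_usage - flips) <= 25))
})

test_that("non-crossing and identical curves yield an empty crossing list", {
  dominated <- toy_series(ids = c("A", "B"), auroc = c(0.9, 0.7),
                          train_g = c(50, 100), infer_g = c(0.05, 0.2))
  expect_equal(nrow(find_crossings(dominated, "A", "B", annual_usage = 1000,
                                   years = 5)), 0)
  twin <- toy_series(ids = c("A", "B"), auroc = c(0.8, 0.8),
                     train_g = c(100, 100), infer_g = c(0.1, 0.1))
  expect_equal(nrow(find_crossings(twin, "A", "B", annual_usage = 1000,
                                   years = 5)), 0)
})

test_that("weight sweep: w = 0 ranks by metric, flip point matches brute scan", {
  ser <- load_series(extdata("benchmark_ktx.csv"))
  sw <- weight_sweep(ser, w_grid = c(0, 1))
  at0 <- sw[sw$w == 0, ]
  expect_equal(at0$model_id[order(at0$rank)],
               ser$model_id[order(-ser$metric_auroc^2,
                                  ser$infer_co2eq_g, ser$model_id)])
  expect_error(weight_sweep(ser, w_grid = c(0, 1.2)), "\\[0, 1\\]")

  # trade-off pair: A (M=0.9, max emission) vs B (M=0.85, min emission)
  # flips where 0.81/exp(w) = 0.7225 => w* = log(0.81/0.7225)
  pair <- toy_series(ids = c("A", "B"), auroc = c(0.9, 0.85),
                     train_g = c(1, 1), infer_g = c(1, 0))
  w_star <- log(0.81 / 0.7225)
  grid <- seq(0, 1, by = 1e-4)
  sw2 <- weight_sweep(pair, w_grid = grid)
  first_b <- min(sw2$w[sw2$model_id == "B" & sw2$rank == 1])
  expect_lt(abs(first_b - w_star), 2e-4)
})

test_that("monotone skill-emission scenario keeps the ranking constant in w", {
  ser <- toy_series(ids = c("A", "B", "C"), auroc = c(0.95, 0.85, 0.75),
                    train_g = c(1, 2, 3), infer_g = c(0.01, 0.1, 0.5))
  sw <- weight_sweep(ser, w_grid = seq(0, 1, by = 0.1))
  ranks <- tapply(sw$rank, sw$model_id, function(r) length(unique(r)))
  expect_true(all(ranks == 1))
})

test_that("bootstrap intervals are deterministic, collapse at zero variance, and widen with fewer cases", {
  zoo <- generate_model_zoo(3, seed = 5, n_cases = 120,
                            keep_predictions = TRUE)
  preds <- attr(zoo, "predictions")
  reps <- attr(zoo, "emission_replicates")
  ci1 <- esper_ci(zoo, preds, reps, n_boot = 150, seed = 42)
  ci2 <- esper_ci(zoo, preds, reps, n_boot = 150, seed = 42)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$ci_low <= ci1$ci_high))

  # zero-variance: single-probability predictions and constant replicates
  ser <- toy_series(ids = c("A", "B"), auroc = c(1, 1), train_g = c(1, 1),
                    infer_g = c(0.1, 0.2))
  sep <- data.frame(case_id = paste0("c", 1:4), true_label = c(0, 0, 1, 1),
                    prob_0 = c(1, 1, 0, 0), prob_1 = c(0, 0, 1, 1))
  const_preds <- list(A = sep, B = sep)
  const_reps <- list(A = rep(0.1, 5), B = rep(0.2, 5))
  expect_warning(
    ci0 <- esper_ci(ser, const_preds, const_reps, n_boot = 99, seed = 1),
    "n_boot")
  expect_equal(ci0$ci_low, ci0$value)
  expect_equal(ci0$ci_high, ci0$value)

  # sampling spread: fewer cases widen the interval
  small <- generate_model_zoo(3, seed = 5, n_cases = 30,
                              keep_predictions = TRUE)
  ci_small <- esper_ci(small, attr(small, "predictions"),
                       attr(small, "emission_replicates"),
                       n_boot = 150, seed = 42)
  expect_gt(mean(ci_small$ci_high - ci_small$ci_low),
            mean(ci1$ci_high - ci1$ci_low))
})

test_that("missing metric values are reported with the model name", {
  df <- data.frame(model_id = c("A", "B"), metric_auroc = c(0.9, NA),
                   train_co2eq_g = c(1, 2), infer_co2eq_g = c(0.1, 0.2))
  ser <- benchmark_series(df)
  expect_error(iesper(ser), "B.*auroc")
  expect_error(iesper(toy_series(), metric = "f1"), "not present")
})
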