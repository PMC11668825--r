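# Shared fixtures and independent brute-force oracles. Oracles are kept
# deliberately naive (pair enumeration, nested loops, dense scans) so
# they stay independent of the implementation paths they check.

extdata <- function(name) system.file("extdata", name, package = "esper")

toy_series <- function(ids = c("A", "B", "C"),
                       auroc = c(0.9, 0.8, 0.7),
                       train_g = c(100, 50, 200),
                       infer_g = c(0.1, 0.2, 0.05),
                       infer_wh = NULL) {
  df <- data.frame(model_id = ids, metric_auroc = auroc,
                   train_co2eq_g = train_g, infer_co2eq_g = infer_g)
  if (!is.null(infer_wh)) df$infer_energy_wh <- infer_wh
  benchmark_series(df, task_label = "toy")
}

# exhaustive positive-negative pair counting with 0.5 credit for ties
brute_force_auroc <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# prediction table realizing a given confusion matrix (true x predicted):
# the predicted class gets probability 0.7, the rest split the remainder
confusion_to_predictions <- function(cm) {
  k <- nrow(cm)
  rows <- list()
  idx <- 0
  for (t in seq_len(k)) for (p in seq_len(k)) {
    for (r in seq_len(cm[t, p])) {
      idx <- idx + 1
      probs <- rep(0.3 / (k - 1), k)
      probs[p] <- 0.7
      rows[[idx]] <- c(idx, t - 1, probs)
    }
  }
  m <- do.call(rbind, rows)
  df <- data.frame(case_id = paste0("c", m[, 1]), true_label = m[, 2])
  for (k_i in seq_len(k)) df[[paste0("prob_", k_i - 1)]] <- m[, 2 + k_i]
  df
}

# direct per-point evaluation of the score formula, bypassing the package
brute_force_esper <- function(metric, emissions, w) {
  rng <- range(emissions)
  norm <- if (rng[1] == rng[2]) rep(0, length(emissions)) else
    (emissions - rng[1]) / (rng[2] - rng[1])
  metric^2 / exp(w * norm)
}
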