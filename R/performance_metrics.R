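# Classification metrics computed from per-case predicted class
# probabilities. A prediction table has one row per case: case_id,
# true_label (integer class index starting at 0), prob_0 ... prob_{K-1}.

#' Load a prediction table
#'
#' @param path CSV with columns `case_id`, `true_label`, `prob_0` ...
#'   `prob_{K-1}`.
#' @return validated tibble (see [validate_predictions()]).
#' @export
load_predictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_predictions(df)
}

#' Validate a prediction table
#'
#' Checks K >= 2 probability columns, non-negative probabilities summing
#' to 1 within 1e-6 per case, and labels inside `[0, K)`.
#'
#' @param preds data frame with `case_id`, `true_label`, `prob_*` columns.
#' @return the table as a tibble, invisibly classed `prediction_table`.
#' @export
validate_predictions <- function(preds) {
  preds <- tibble::as_tibble(preds)
  if (nrow(preds) == 0) stop("prediction table is empty", call. = FALSE)
  prob_cols <- grep("^prob_[0-9]+$", names(preds), value = TRUE)
  k <- length(prob_cols)
  if (k < 2) stop("need at least 2 probability columns (prob_0, prob_1, ...)",
                  call. = FALSE)
  ord <- paste0("prob_", seq_len(k) - 1)
  if (!all(ord %in% prob_cols)) {
    stop("probability columns must be prob_0 ... prob_", k - 1, call. = FALSE)
  }
  p <- as.matrix(preds[ord])
  if (any(p < 0)) stop("negative class probability", call. = FALSE)
  s <- rowSums(p)
  bad <- which(abs(s - 1) > 1e-6)
  if (length(bad) > 0) {
    stop(sprintf("row %d: class probabilities sum to %.8f, not 1",
                 bad[1], s[bad[1]]), call. = FALSE)
  }
  y <- preds$true_label
  if (any(y < 0 | y >= k | y != round(y))) {
    stop("true_label must be an integer class index in [0, ", k - 1, "]",
         call. = FALSE)
  }
  if (!inherits(preds, "prediction_table")) {
    class(preds) <- c("prediction_table", class(preds))
  }
  preds
}

n_classes <- function(preds) {
  length(grep("^prob_[0-9]+$", names(preds)))
}

prob_matrix <- function(preds) {
  k <- n_classes(preds)
  as.matrix(preds[paste0("prob_", seq_len(k) - 1)])
}

# One-vs-rest AUROC via the midrank Mann-Whitney statistic: tied scores
# contribute 0.5 per positive-negative pair, so permuting equal scores
# never changes the value.
auroc_binary <- function(scores, is_pos) {
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Macro-averaged one-vs-rest AUROC
#'
#' Computes a one-vs-rest AUROC for every class observed in `true_label`
#' (ranking cases by that class's predicted probability) and returns the
#' unweighted mean over classes. Tie handling follows the midrank
#' convention. Every observed class must have at least one positive and
#' one negative case.
#'
#' @param preds a prediction table (see [validate_predictions()]).
#' @return macro AUROC in \[0, 1\].
#' @export
macro_auroc <- function(preds) {
  preds <- validate_predictions(preds)
  p <- prob_matrix(preds)
  y <- preds$true_label
  classes <- sort(unique(y))
  per_class <- vapply(classes, function(cl) {
    is_pos <- y == cl
    if (sum(is_pos) == nrow(p)) {
      stop("class ", cl, " has no negative cases; AUROC undefined",
           call. = FALSE)
    }
    auroc_binary(p[, cl + 1], is_pos)
  }, numeric(1))
  if (length(classes) < 2) {
    stop("only one class present in true_label; AUROC undefined",
         call. = FALSE)
  }
  mean(per_class)
}

#' Classification report: balanced accuracy, macro precision/recall/F1
#'
#' Predicted labels come from the argmax decision rule on the class
#' probabilities, with ties resolved toward the lowest class index.
#' Balanced accuracy is the mean of per-class recalls. Precision, recall
#' and F1 are macro-averaged over all K classes; a class that is never
#' predicted contributes precision 0 (with a warning), and a class with
#' precision + recall = 0 contributes F1 = 0.
#'
#' @param preds a prediction table.
#' @return named list with elements `balanced_accuracy`, `precision`,
#'   `recall`, `f1`, each in \[0, 1\], plus the `confusion` matrix
#'   (true classes in rows, predicted in columns).
#' @export
classification_report <- function(preds) {
  preds <- validate_predictions(preds)
  p <- prob_matrix(preds)
  k <- ncol(p)
  y <- preds$true_label
  pred <- max.col(p, ties.method = "first") - 1L

  cm <- matrix(0L, k, k, dimnames = list(true = 0:(k - 1), pred = 0:(k - 1)))
  for (i in seq_along(y)) cm[y[i] + 1L, pred[i] + 1L] <- cm[y[i] + 1L, pred[i] + 1L] + 1L

  tp <- diag(cm)
  row_tot <- rowSums(cm)   # actual cases per class
  col_tot <- colSums(cm)   # predicted cases per class

  observed <- row_tot > 0
  recall_c <- ifelse(observed, tp / row_tot, NA_real_)
  precision_c <- numeric(k)
  never_pred <- col_tot == 0
  precision_c[!never_pred] <- tp[!never_pred] / col_tot[!never_pred]
  if (any(never_pred & observed)) {
    warning("class(es) ", paste(which(never_pred & observed) - 1, collapse = ", "),
            " never predicted; precision set to 0", call. = FALSE)
  }
  f1_c <- ifelse(precision_c + recall_c > 0 & !is.na(recall_c),
                 2 * precision_c * recall_c / (precision_c + recall_c), 0)

  obs <- which(observed)
  list(
    balanced_accuracy = mean(recall_c[obs]),
    precision = mean(precision_c[obs]),
    recall = mean(recall_c[obs]),
    f1 = mean(f1_c[obs]),
    confusion = cm
  )
}

#' All five reported metrics from a prediction table
#'
#' @param preds a prediction table.
#' @return named numeric vector with `auroc`, `balanced_accuracy`,
#'   `precision`, `recall`, `f1`.
#' @export
all_metrics <- function(preds) {
  rep <- classification_report(preds)
  c(auroc = macro_auroc(preds),
    balanced_accuracy = rep$balanced_accuracy,
    precision = rep$precision,
    recall = rep$recall,
    f1 = rep$f1)
}
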