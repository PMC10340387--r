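#' Predict tumor probability
#'
#' Standard logistic link: `p = 1 / (1 + exp(-(beta0 + x . beta)))`. The
#' input must be z-scored with the evaluation dataset's own parameters and
#' contain the model's features.
#'
#' @param fit an `elnet_fit`.
#' @param X samples x features z-scored matrix, or a features x samples
#'   matrix from [apply_z()] (orientation detected by feature names).
#' @return named numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(fit, X) {
  stopifnot(inherits(fit, "elnet_fit"))
  X <- as.matrix(X)
  if (!all(fit$features %in% colnames(X)) &&
      all(fit$features %in% rownames(X))) {
    X <- t(X)
  }
  assert_that(all(fit$features %in% colnames(X)),
              "X lacks model features")
  eta <- fit$beta0 + drop(X[, fit$features, drop = FALSE] %*% fit$beta)
  stats::plogis(eta)
}

#' Confusion counts and derived metrics at a probability threshold
#'
#' A sample is called tumor when its probability is strictly above the
#' threshold (ties go to normal). Percentages are rounded half-up to whole
#' numbers for reporting, alongside the raw fractions.
#'
#' @param prob predicted probabilities.
#' @param labels 0/1 (or `"normal"`/`"tumor"`) reference labels.
#' @param threshold probability cutoff, default 0.5.
#' @return list: `TP`, `FP`, `TN`, `FN`, `threshold`, `sensitivity`,
#'   `specificity`, `accuracy` (fractions; `NA` when undefined), and
#'   `sensitivity_pct`, `specificity_pct`, `accuracy_pct` (rounded).
#' @export
confusion_metrics <- function(prob, labels, threshold = 0.5) {
  y <- as_binary_labels(labels)
  assert_that(length(prob) == length(y), "prob/labels length mismatch")
  call_tumor <- prob > threshold
  TP <- sum(call_tumor & y == 1); FN <- sum(!call_tumor & y == 1)
  TN <- sum(!call_tumor & y == 0); FP <- sum(call_tumor & y == 0)
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  acc <- (TP + TN) / length(y)
  if (TP + FN == 0) warning("no positive samples; sensitivity undefined")
  round_half_up <- function(x) if (is.na(x)) NA_real_ else
    floor(100 * x + 0.5)
  list(TP = TP, FP = FP, TN = TN, FN = FN, threshold = threshold,
       sensitivity = sens, specificity = spec, accuracy = acc,
       sensitivity_pct = round_half_up(sens),
       specificity_pct = round_half_up(spec),
       accuracy_pct = round_half_up(acc))
}

as_binary_labels <- function(labels) {
  if (is.numeric(labels)) {
    assert_that(all(labels %in% c(0, 1)), "numeric labels must be 0/1")
    return(as.numeric(labels))
  }
  assert_that(all(labels %in% c("tumor", "normal")),
              "labels must be tumor/normal or 0/1")
  as.numeric(labels == "tumor")
}

#' Accuracy across a grid of thresholds
#'
#' @param prob predicted probabilities.
#' @param labels reference labels.
#' @param grid thresholds to evaluate (default 0 to 1 in steps of 0.01).
#' @return data.frame `threshold`, `accuracy`, `sensitivity`, `specificity`.
#' @export
threshold_sweep <- function(prob, labels, grid = seq(0, 1, by = 0.01)) {
  rows <- lapply(grid, function(th) {
    cm <- suppressWarnings(confusion_metrics(prob, labels, th))
    data.frame(threshold = th, accuracy = cm$accuracy,
               sensitivity = cm$sensitivity, specificity = cm$specificity)
  })
  do.call(rbind, rows)
}

#' Empirical ROC curve and AUC
#'
#' The curve is traced over all distinct score thresholds; the area is
#' computed by the Mann-Whitney identity (probability that a random tumor
#' outscores a random normal, ties counting one half), which equals the
#' trapezoidal area under the empirical curve.
#'
#' @param prob scores (higher = more tumor-like).
#' @param labels reference labels.
#' @return list of class `roc_curve`: `fpr`, `tpr` (monotone from (0,0) to
#'   (1,1)), `thresholds`, `auc` (fraction in `[0, 1]`).
#' @export
roc_auc <- function(prob, labels) {
  y <- as_binary_labels(labels)
  assert_that(any(y == 1) && any(y == 0),
              "both classes required for a ROC curve")
  pos <- prob[y == 1]; neg <- prob[y == 0]
  # Mann-Whitney AUC via midranks
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  cuts <- sort(unique(prob), decreasing = TRUE)
  tpr <- c(0, vapply(cuts, function(cut) mean(pos >= cut), numeric(1)))
  fpr <- c(0, vapply(cuts, function(cut) mean(neg >= cut), numeric(1)))
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, cuts), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC %.4f over %d points\n", x$auc, length(x$fpr)))
  invisible(x)
}
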