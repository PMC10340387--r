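#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test with Satterthwaite degrees of freedom,
#' used by the concordance pre-filter. Degenerate input (zero variance in
#' both groups) returns p = 1 for equal means and p = 0 otherwise instead of
#' erroring.
#'
#' @param a,b numeric vectors, each of length >= 2, finite.
#' @return list with `t` and `p`.
#' @export
welch_t_test <- function(a, b) {
  assert_that(length(a) >= 2 && length(b) >= 2, "each group needs n >= 2")
  assert_that(all(is.finite(a)) && all(is.finite(b)), "values must be finite")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; adjusted values are monotone,
#' at least the raw values, and capped at 1.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Per-feature tumor-vs-normal statistics
#'
#' Log2 fold change (difference of group means on the normalized log2 scale),
#' Welch p-value, and a direction call per feature. A feature is `up`/`down`
#' when |lfc| meets `log2(fc_threshold)`, otherwise `flat`.
#'
#' @param m a `normalized_matrix` whose metadata carries tumor/normal groups.
#' @param fc_threshold fold-change threshold on the count scale (default 1.2,
#'   i.e. 20 percent deregulation).
#' @return data.frame `feature`, `lfc`, `p`, `direction`.
#' @export
feature_stats <- function(m, fc_threshold = 1.2) {
  stopifnot(inherits(m, "normalized_matrix"))
  tum <- m$values[, m$meta$group == "tumor", drop = FALSE]
  nor <- m$values[, m$meta$group == "normal", drop = FALSE]
  assert_that(ncol(tum) >= 2 && ncol(nor) >= 2,
              "need >= 2 samples per group")
  lfc <- rowMeans(tum) - rowMeans(nor)
  p <- vapply(seq_len(nrow(m$values)),
              function(i) welch_t_test(tum[i, ], nor[i, ])$p, numeric(1))
  cut <- log2(fc_threshold)
  direction <- ifelse(abs(lfc) < cut, "flat", ifelse(lfc > 0, "up", "down"))
  data.frame(feature = rownames(m$values), lfc = lfc, p = p,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Concordance pre-filter across surrogate and rare cohorts
#'
#' Selects candidate features showing at least `fc_threshold`-fold
#' deregulation in the *same* direction in both the surrogate comparison
#' (tumor cluster I vs normal) and the rare comparison (rare tumor vs rare
#' control), each with Welch p below `p_threshold`. Only features present in
#' both matrices are considered; the caller is expected to have restricted
#' features to those detected in all datasets beforehand.
#'
#' @param surrogate,rare `normalized_matrix` objects with tumor/normal groups.
#' @param fc_threshold fold-change threshold (default 1.2 = 20 percent).
#' @param p_threshold p-value threshold (default 0.1).
#' @return data.frame `feature`, `lfc_surrogate`, `p_surrogate`, `lfc_rare`,
#'   `p_rare`, `direction` (of selected features; `flat` when not selected),
#'   `selected`.
#' @export
concordance_prefilter <- function(surrogate, rare,
                                  fc_threshold = 1.2, p_threshold = 0.1) {
  assert_that(fc_threshold >= 1, "fc_threshold must be >= 1")
  assert_that(p_threshold > 0 && p_threshold <= 1,
              "p_threshold must be in (0, 1]")
  shared <- intersect(rownames(surrogate$values), rownames(rare$values))
  assert_that(length(shared) > 0, "no shared features")
  sub <- function(m, feats) { m$values <- m$values[feats, , drop = FALSE]; m }
  fs <- feature_stats(sub(surrogate, shared), fc_threshold)
  fr <- feature_stats(sub(rare, shared), fc_threshold)
  cut <- log2(fc_threshold)
  concordant <- sign(fs$lfc) == sign(fr$lfc) &
    abs(fs$lfc) >= cut & abs(fr$lfc) >= cut &
    fs$p < p_threshold & fr$p < p_threshold
  data.frame(feature = shared,
             lfc_surrogate = fs$lfc, p_surrogate = fs$p,
             lfc_rare = fr$lfc, p_rare = fr$p,
             direction = ifelse(concordant,
                                ifelse(fs$lfc > 0, "up", "down"), "flat"),
             selected = concordant,
             row.names = NULL, stringsAsFactors = FALSE)
}
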