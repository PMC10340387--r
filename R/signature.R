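#' Cross-dataset direction calls for signature features
#'
#' For each signature feature, the sign of the tumor-minus-control difference
#' of group means (normalized log2 scale) in one dataset: `up`, `down`, or
#' `flat` for an exact zero difference.
#'
#' @param features feature names.
#' @param m a `normalized_matrix` with tumor/normal groups.
#' @return character vector of direction calls aligned with `features`.
#' @export
dataset_directions <- function(features, m) {
  stopifnot(inherits(m, "normalized_matrix"))
  idx <- match(features, rownames(m$values))
  assert_that(!anyNA(idx), paste("features absent from dataset:",
                                 paste(features[is.na(idx)], collapse = ", ")))
  tum <- rowMeans(m$values[idx, m$meta$group == "tumor", drop = FALSE])
  nor <- rowMeans(m$values[idx, m$meta$group == "normal", drop = FALSE])
  d <- tum - nor
  ifelse(d > 0, "up", ifelse(d < 0, "down", "flat"))
}

#' Keep features concordantly deregulated across all datasets
#'
#' First reduction rule: a feature survives when its direction call is the
#' same in every supplied dataset (equivalently, in every supplied direction
#' column). Accepts either a data.frame of precomputed direction columns or a
#' list of `normalized_matrix` datasets from which calls are derived.
#'
#' @param sig data.frame with a `feature` column (e.g. from
#'   [extract_signature()]).
#' @param datasets either a named list of `normalized_matrix` objects, or a
#'   data.frame/matrix of direction strings (rows aligned with `sig`).
#' @return `sig` restricted to concordant rows, with the direction columns
#'   appended as `dir_<name>`.
#' @export
direction_concordance <- function(sig, datasets) {
  assert_that(is.data.frame(sig) && "feature" %in% names(sig),
              "sig must be a data.frame with a 'feature' column")
  if (is.data.frame(datasets) || is.matrix(datasets)) {
    dirs <- as.data.frame(datasets, stringsAsFactors = FALSE)
    assert_that(nrow(dirs) == nrow(sig),
                "direction table must align with signature rows")
  } else {
    assert_that(length(datasets) >= 2 && !is.null(names(datasets)),
                "datasets must be a named list of normalized matrices")
    dirs <- as.data.frame(lapply(datasets, function(m)
      dataset_directions(sig$feature, m)), stringsAsFactors = FALSE)
  }
  names(dirs) <- paste0("dir_", names(dirs))
  concordant <- apply(dirs, 1, function(row)
    length(unique(row)) == 1 && row[1] != "flat")
  out <- cbind(sig, dirs)
  out[concordant, , drop = FALSE]
}

#' Read-share abundance of signature features in the rare cohort
#'
#' Second reduction rule: a feature is retained when its mean share of total
#' reads per sample, averaged within the rare tumor group or within the rare
#' control group, exceeds the threshold in *either* group — prioritizing
#' strongly expressed miRNAs that remain robustly detectable. Shares are
#' computed on raw counts, before normalization.
#'
#' When the raw rare-cohort counts are not available but the signature table
#' carries a recorded strong-expression call (a logical `abundant` column, as
#' in [sig33_reference()]), `rare` may be omitted and the recorded call is
#' applied instead.
#'
#' @param sig data.frame with a `feature` column.
#' @param rare a [count_matrix()] (the rare cohort, raw counts), or `NULL`
#'   to filter on a recorded `abundant` column.
#' @param threshold read-share cutoff as a fraction (default 0.001 = 0.1
#'   percent of total reads).
#' @return `sig` restricted to abundant rows, with `share_tumor`,
#'   `share_normal` and `abundance_share` (the maximum of the two) appended
#'   when computed from counts.
#' @export
abundance_filter <- function(sig, rare = NULL, threshold = 0.001) {
  assert_that(is.data.frame(sig) && "feature" %in% names(sig),
              "sig must be a data.frame with a 'feature' column")
  if (is.null(rare)) {
    assert_that("abundant" %in% names(sig) && is.logical(sig$abundant),
                "without rare counts, sig needs a logical 'abundant' column")
    return(sig[sig$abundant, , drop = FALSE])
  }
  stopifnot(inherits(rare, "count_matrix"))
  idx <- match(sig$feature, rownames(rare$counts))
  assert_that(!anyNA(idx), paste("features absent from rare cohort:",
                                 paste(sig$feature[is.na(idx)], collapse = ", ")))
  shares <- sweep(rare$counts, 2, colSums(rare$counts), "/")
  tum <- rowMeans(shares[idx, rare$meta$group == "tumor", drop = FALSE])
  nor <- rowMeans(shares[idx, rare$meta$group == "normal", drop = FALSE])
  out <- cbind(sig, share_tumor = tum, share_normal = nor,
               abundance_share = pmax(tum, nor))
  rownames(out) <- NULL
  out[out$abundance_share > threshold, , drop = FALSE]
}

#' Dominant mature arm of a precursor
#'
#' The arm (`-5p` or `-3p`) with the greater total read count in a
#' mature-arm matrix; an exact tie returns `-5p` with a warning.
#'
#' @param mature a [count_matrix()] with mature-arm feature names.
#' @param precursor precursor name.
#' @return `"-5p"` or `"-3p"`.
#' @export
dominant_arm <- function(mature, precursor) {
  stopifnot(inherits(mature, "count_matrix"))
  arm5 <- paste0(precursor, "-5p"); arm3 <- paste0(precursor, "-3p")
  tot <- function(f) if (f %in% rownames(mature$counts))
    sum(mature$counts[f, ]) else 0
  t5 <- tot(arm5); t3 <- tot(arm3)
  assert_that(t5 + t3 > 0, paste("no mature-arm reads for", precursor))
  if (t5 == t3) {
    warning(sprintf("tie between arms of %s; returning -5p", precursor))
    return("-5p")
  }
  if (t5 > t3) "-5p" else "-3p"
}

#' Confirm signature members by qPCR and keep the significant ones
#'
#' Final reduction rule: a signature member survives when its qPCR assay's
#' relative expression differs between tumor and control groups at
#' `p < p_threshold` (two-sided Wilcoxon rank-sum on delta-Cq) *and* the
#' observed direction matches the signature's direction call (lower delta-Cq
#' in tumors means up-regulation).
#'
#' @param sig10 data.frame with `feature` and a direction column named
#'   `direction` or `dir_surrogate`.
#' @param qpcr_results data.frame mapping assays to features, with columns
#'   `feature`, `p`, `direction` (observed qPCR direction, `up`/`down`),
#'   e.g. from [qpcr_validate()].
#' @param p_threshold significance cutoff (default 0.05).
#' @return `sig10` restricted to confirmed rows with `qpcr_p` appended;
#'   warns when no assay is significant.
#' @export
make_sig3 <- function(sig10, qpcr_results, p_threshold = 0.05) {
  dir_col <- if ("direction" %in% names(sig10)) "direction" else "dir_surrogate"
  assert_that(dir_col %in% names(sig10), "sig10 needs a direction column")
  idx <- match(sig10$feature, qpcr_results$feature)
  assert_that(!anyNA(idx), "every signature member needs a qPCR result")
  qp <- qpcr_results[idx, , drop = FALSE]
  keep <- qp$p < p_threshold & qp$direction == sig10[[dir_col]]
  if (!any(keep)) warning("no significant, direction-concordant qPCR assay")
  out <- cbind(sig10, qpcr_p = qp$p, qpcr_direction = qp$direction)
  rownames(out) <- NULL
  out[keep, , drop = FALSE]
}

#' Retrain the classifier on a reduced feature set
#'
#' Re-runs the full cross-validated elastic net restricted to the given
#' features, on the same balanced training data (same seed, same folds), as
#' done when benchmarking reduced signatures against the full model.
#'
#' @param features feature subset to keep.
#' @param X full samples x features z-scored training matrix.
#' @param y 0/1 labels.
#' @param config a [train_config()].
#' @return a `cv_elnet` object.
#' @export
retrain_reduced <- function(features, X, y, config = train_config()) {
  assert_that(length(features) >= 1, "empty feature list")
  assert_that(all(features %in% colnames(X)),
              "features must be columns of the training matrix")
  cv_elnet(X[, features, drop = FALSE], y, config)
}
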