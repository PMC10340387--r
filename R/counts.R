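#' Construct a count matrix with sample metadata
#'
#' The package's basic container for raw miRNA-seq counts: an integer matrix
#' with miRNA precursors (or mature arms) in rows and samples in columns, plus
#' per-sample metadata giving the experimental group (`tumor`/`normal`), a
#' dataset label and a batch label.
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   rownames (feature names) and colnames (sample ids).
#' @param meta data.frame with columns `sample_id`, `group`, `dataset`,
#'   `batch`; one row per sample, in any order.
#' @return an object of class `count_matrix` with elements `counts` and
#'   `meta` (meta reordered to match the columns of `counts`).
#' @export
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "counts must have feature rownames and sample colnames")
  assert_that(!anyDuplicated(rownames(counts)),
              paste("duplicate feature names:",
                    paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                          collapse = ", ")))
  assert_that(!anyDuplicated(colnames(counts)),
              paste("duplicate sample ids:",
                    paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                          collapse = ", ")))
  assert_that(all(is.finite(counts)) && all(counts >= 0),
              "counts must be finite and non-negative")
  assert_that(max(abs(counts - round(counts))) < 1e-8,
              "counts must be integers")
  storage.mode(counts) <- "double"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "dataset", "batch")
  assert_that(all(required %in% names(meta)),
              paste("metadata must contain columns:",
                    paste(required, collapse = ", ")))
  missing <- setdiff(colnames(counts), meta$sample_id)
  assert_that(length(missing) == 0,
              paste("metadata missing samples:", paste(missing, collapse = ", ")))
  assert_that(!anyDuplicated(meta$sample_id), "duplicate sample ids in metadata")
  meta <- meta[match(colnames(counts), meta$sample_id), required]
  rownames(meta) <- NULL
  assert_that(all(meta$group %in% c("tumor", "normal")),
              "group must be 'tumor' or 'normal'")
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$meta$group)),
                            as.integer(table(x$meta$group))), collapse = ", ")))
  invisible(x)
}

#' Read a count matrix and its metadata from TSV
#'
#' Expects the package's standard on-disk layout: a tab-delimited count table
#' whose first column `mirna` holds feature names and remaining columns hold
#' integer counts per sample, and a metadata table with columns `sample_id`,
#' `group`, `dataset`, `batch`.
#'
#' @param path count TSV path.
#' @param meta_path metadata TSV path.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, meta_path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  assert_that(!anyDuplicated(header),
              paste("duplicate sample column in", path, ":",
                    paste(unique(header[duplicated(header)]), collapse = ", ")))
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(names(tab)[1] == "mirna", "first column of count TSV must be 'mirna'")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$mirna
  meta <- utils::read.delim(meta_path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

#' Write a count matrix and its metadata to TSV
#'
#' @param x a [count_matrix()].
#' @param path count TSV path.
#' @param meta_path metadata TSV path.
#' @return `x`, invisibly.
#' @export
write_count_matrix <- function(x, path, meta_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(mirna = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Collapse mature-arm counts to precursor level
#'
#' Sums the reads mapped to the `-5p` and `-3p` arms of each precursor under
#' the precursor name, which makes in-house mature-arm tables comparable with
#' precursor-level repository data. Features without an arm suffix pass
#' through unchanged; a lone arm collapses to its precursor name.
#'
#' @param x a [count_matrix()] with mature-arm (or mixed) feature names.
#' @return a precursor-level [count_matrix()]; grand total is conserved.
#' @export
collapse_to_precursor <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  precursor <- sub("-[53]p$", "", rownames(x$counts))
  collapsed <- rowsum(x$counts, group = precursor, reorder = FALSE)
  count_matrix(collapsed, x$meta)
}

#' Discard low-count miRNAs
#'
#' A feature is kept when its mean count across `n` samples is at least 10
#' reads, where `n` is the size of the smallest experimental group — i.e. it
#' is discarded iff `rowSums / n < 10` (strict). Survivors are the "detected"
#' miRNAs carried into normalization.
#'
#' @param x a [count_matrix()].
#' @param group_sizes optional integer vector of group sizes; defaults to the
#'   group tabulation of `x`'s metadata.
#' @param min_mean detection threshold in mean reads (default 10).
#' @return the filtered [count_matrix()]; warns if nothing survives.
#' @export
filter_low_counts <- function(x, group_sizes = NULL, min_mean = 10) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(group_sizes)) group_sizes <- as.integer(table(x$meta$group))
  n <- min(group_sizes)
  assert_that(n > 0, "smallest group must be non-empty")
  keep <- rowSums(x$counts) / n >= min_mean
  if (!any(keep)) warning("no features pass the low-count filter")
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants for sequencing depth: each sample's factor is
#' the median, over features with non-zero counts in every sample, of the
#' ratio between the sample's count and the geometric-mean reference row. If
#' no feature is non-zero everywhere, falls back to total-count ratios
#' (sample total over geometric mean of totals) with a warning.
#'
#' @param x a [count_matrix()].
#' @return named positive numeric vector of size factors, one per sample.
#' @export
estimate_size_factors <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  allpos <- rowSums(counts == 0) == 0
  if (!any(allpos)) {
    warning("no feature with non-zero counts in all samples; ",
            "falling back to total-count ratio normalization")
    totals <- colSums(counts)
    assert_that(all(totals > 0), "empty samples cannot be normalized")
    sf <- totals / exp(mean(log(totals)))
    return(sf)
  }
  logref <- rowMeans(log(counts[allpos, , drop = FALSE]))
  sf <- apply(counts[allpos, , drop = FALSE], 2, function(cnt) {
    exp(stats::median(log(cnt) - logref))
  })
  sf
}

#' Log2 normalization of counts
#'
#' Divides counts by per-sample size factors and applies
#' `log2(normalized + pseudocount)`. This shifted-log transform is the
#' package's variance-stabilizing surrogate: strictly monotone per sample and
#' zero-safe.
#'
#' @param x a [count_matrix()].
#' @param size_factors optional; defaults to [estimate_size_factors()].
#' @param pseudocount positive real added before the log (default 1).
#' @return an object of class `normalized_matrix` with elements `values`
#'   (features x samples, log2 scale), `size_factors`, `pseudocount`, `meta`.
#' @export
normalize_log2 <- function(x, size_factors = NULL, pseudocount = 1) {
  stopifnot(inherits(x, "count_matrix"))
  assert_that(pseudocount > 0, "pseudocount must be positive")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(x)
  assert_that(length(size_factors) == ncol(x$counts) && all(size_factors > 0),
              "size factors must be positive, one per sample")
  values <- log2(sweep(x$counts, 2, size_factors, "/") + pseudocount)
  structure(list(values = values, size_factors = size_factors,
                 pseudocount = pseudocount, meta = x$meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d features x %d samples (log2, pseudocount %g)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}

values_of <- function(m) {
  if (inherits(m, "normalized_matrix")) m$values else as.matrix(m)
}

#' Fit per-feature z-transform parameters
#'
#' Records each feature's mean and population (divisor `n`) standard
#' deviation on the normalized log2 scale. Each evaluation dataset is
#' z-scored with its own parameters, which makes classifier inputs scale-free
#' across platforms.
#'
#' @param m a `normalized_matrix` (or plain features x samples matrix).
#' @return object of class `z_params`: list with `mean`, `sd`, `features`.
#' @export
fit_z <- function(m) {
  v <- values_of(m)
  mu <- rowMeans(v)
  sdev <- sqrt(rowMeans((v - mu)^2))
  structure(list(mean = mu, sd = sdev, features = rownames(v)),
            class = "z_params")
}

#' Apply a z-transform
#'
#' Centers and scales features by previously fitted parameters; features with
#' zero standard deviation map to 0.
#'
#' @param m a `normalized_matrix` or matrix whose rows are a subset of the
#'   fitted features.
#' @param params a `z_params` object from [fit_z()].
#' @return z-scored matrix, features x samples.
#' @export
apply_z <- function(m, params) {
  stopifnot(inherits(params, "z_params"))
  v <- values_of(m)
  idx <- match(rownames(v), params$features)
  assert_that(!anyNA(idx), "matrix contains features absent from z parameters")
  sdev <- params$sd[idx]
  z <- (v - params$mean[idx]) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  z
}
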