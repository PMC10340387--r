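# shared fixtures, built in code

# small count matrix with both groups
toy_counts <- function(counts = NULL, groups = c("tumor", "tumor", "normal"),
                       features = NULL) {
  n <- length(groups)
  if (is.null(counts)) {
    counts <- matrix(seq_len(4 * n) * 10, nrow = 4, ncol = n)
  }
  counts <- as.matrix(counts)
  if (is.null(features)) features <- sprintf("mir-%02d", seq_len(nrow(counts)))
  rownames(counts) <- features
  colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  count_matrix(counts, data.frame(
    sample_id = colnames(counts), group = groups,
    dataset = "toy", batch = "b1", stringsAsFactors = FALSE))
}

# normalized matrix straight from given values (size factors 1)
toy_normalized <- function(values, groups, batch = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("mir-%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  if (is.null(batch)) batch <- "b1"
  structure(list(values = values,
                 size_factors = rep(1, ncol(values)),
                 pseudocount = 1,
                 meta = data.frame(sample_id = colnames(values),
                                   group = groups, dataset = "toy",
                                   batch = rep_len(batch, ncol(values)),
                                   stringsAsFactors = FALSE)),
            class = "normalized_matrix")
}

# the default seeded end-to-end run is expensive; compute it once per suite
.pipeline_cache <- new.env(parent = emptyenv())

default_pipeline_run <- function() {
  if (is.null(.pipeline_cache$report)) {
    .pipeline_cache$bundle <- generate_cohorts(synthetic_config(seed = 1))
    .pipeline_cache$report <- run_pipeline(pipeline_config(seed = 1))
  }
  list(bundle = .pipeline_cache$bundle, report = .pipeline_cache$report)
}
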