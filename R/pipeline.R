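#' Pipeline configuration
#'
#' Aggregates every tunable constant of the workflow: the synthetic-cohort
#' configuration (or paths to on-disk cohorts), the detection/pre-filter/
#' classification thresholds, and the training configuration. The seed is
#' mandatory; all stage seeds derive from it.
#'
#' @param seed integer seed governing every stochastic stage.
#' @param synthetic a [synthetic_config()]; defaults to the standard study
#'   conditions with this seed.
#' @param cohort_dir optional directory holding `surrogate/rare/exosome`
#'   count + metadata TSVs (as written by [write_cohort_bundle()]); when
#'   given, cohorts are read instead of simulated.
#' @param low_count_min detection threshold, mean reads (default 10).
#' @param fc_threshold pre-filter fold change (default 1.2).
#' @param p_threshold pre-filter p-value (default 0.1).
#' @param class_threshold tumor-call probability cutoff (default 0.5).
#' @param abundance_threshold read-share cutoff (default 0.001).
#' @param qpcr_p_threshold qPCR confirmation cutoff (default 0.05).
#' @param n_qpcr_references number of candidate reference assays (default 4).
#' @param train a [train_config()]; defaults to this seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            synthetic = synthetic_config(seed = seed),
                            cohort_dir = NULL,
                            low_count_min = 10,
                            fc_threshold = 1.2,
                            p_threshold = 0.1,
                            class_threshold = 0.5,
                            abundance_threshold = 0.001,
                            qpcr_p_threshold = 0.05,
                            n_qpcr_references = 4,
                            train = train_config(seed = seed)) {
  assert_that(!missing(seed) && is.numeric(seed) && length(seed) == 1,
              "seed is mandatory")
  assert_that(p_threshold > 0 && p_threshold <= 1, "p_threshold must be in (0,1]")
  assert_that(qpcr_p_threshold > 0 && qpcr_p_threshold <= 1,
              "qpcr_p_threshold must be in (0,1]")
  assert_that(fc_threshold >= 1, "fc_threshold must be >= 1")
  assert_that(class_threshold >= 0 && class_threshold <= 1,
              "class_threshold must be in [0,1]")
  assert_that(abundance_threshold >= 0 && abundance_threshold < 1,
              "abundance_threshold must be in [0,1)")
  structure(list(seed = as.integer(seed), synthetic = synthetic,
                 cohort_dir = cohort_dir,
                 low_count_min = low_count_min, fc_threshold = fc_threshold,
                 p_threshold = p_threshold, class_threshold = class_threshold,
                 abundance_threshold = abundance_threshold,
                 qpcr_p_threshold = qpcr_p_threshold,
                 n_qpcr_references = n_qpcr_references, train = train),
            class = "pipeline_config")
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML or JSON configuration, fills defaults and range-checks every
#' threshold. Unknown top-level keys are rejected; a missing seed is an
#' error.
#'
#' @param path configuration file path (`.yaml`/`.yml` or `.json`).
#' @return a [pipeline_config()].
#' @export
validate_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("seed", "synthetic", "low_count_min", "fc_threshold",
             "p_threshold", "class_threshold", "abundance_threshold",
             "qpcr_p_threshold", "n_qpcr_references", "train", "cohort_dir")
  unknown <- setdiff(names(raw), known)
  assert_that(length(unknown) == 0,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  assert_that("seed" %in% names(raw), "config must provide a seed")
  syn <- do.call(synthetic_config,
                 c(raw$synthetic %||% list(),
                   if (is.null(raw$synthetic$seed)) list(seed = raw$seed)))
  trn <- do.call(train_config,
                 c(raw$train %||% list(),
                   if (is.null(raw$train$seed)) list(seed = raw$seed)))
  args <- raw[setdiff(names(raw), c("synthetic", "train"))]
  do.call(pipeline_config, c(args, list(synthetic = syn, train = trn)))
}

center_to_model <- function(m, model) {
  # replace the dataset's own feature means by the model's centering means:
  # removes the cross-dataset location shift before projection
  v <- values_of(m)
  common <- intersect(rownames(v), model$features)
  v <- v[common, , drop = FALSE]
  v - rowMeans(v) + model$center[match(common, model$features)]
}

subset_features <- function(x, feats) {
  if (inherits(x, "count_matrix")) {
    x$counts <- x$counts[feats, , drop = FALSE]
  } else {
    x$values <- x$values[feats, , drop = FALSE]
  }
  x
}

subset_samples <- function(m, ids) {
  keep <- match(ids, m$meta$sample_id)
  m$values <- m$values[, keep, drop = FALSE]
  m$meta <- m$meta[keep, , drop = FALSE]
  m$size_factors <- m$size_factors[keep]
  m
}

evaluate_model <- function(fit, datasets, threshold) {
  rows <- lapply(names(datasets), function(nm) {
    m <- datasets[[nm]]
    z <- apply_z(m, fit_z(m))
    prob <- predict_proba(fit, z)
    cm <- suppressWarnings(confusion_metrics(prob, m$meta$group, threshold))
    roc <- roc_auc(prob, m$meta$group)
    data.frame(dataset = nm, auc = roc$auc,
               auc_pct = 100 * roc$auc,
               accuracy = cm$accuracy, sensitivity = cm$sensitivity,
               specificity = cm$specificity,
               TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full transfer-learning workflow
#'
#' Executes simulate (or load) - detect - normalize - similarity screen -
#' PCA stratification - concordance pre-filter - balanced elastic-net
#' training - cross-dataset evaluation - signature reduction, and returns a
#' machine-readable report. Identical configuration and seed give an
#' identical report.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for per-stage TSV/JSON artifacts.
#' @return list of class `pipeline_report`; see the fields written by the
#'   summary JSON (`similarity`, `clusters`, `prefilter`, `signatures`,
#'   `metrics`, `qpcr`, `seeds`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  ## stage: cohorts
  bundle <- if (!is.null(config$cohort_dir)) {
    d <- config$cohort_dir
    structure(list(
      surrogate = read_count_matrix(file.path(d, "surrogate_counts.tsv"),
                                    file.path(d, "surrogate_meta.tsv")),
      rare = read_count_matrix(file.path(d, "rare_counts.tsv"),
                               file.path(d, "rare_meta.tsv")),
      exosome = read_count_matrix(file.path(d, "exosome_counts.tsv"),
                                  file.path(d, "exosome_meta.tsv")),
      truth = NULL, cluster_truth = NULL, config = NULL),
      class = "cohort_bundle")
  } else {
    generate_cohorts(config$synthetic)
  }

  ## stage: detection filter and shared features
  filtered <- lapply(bundle[c("surrogate", "rare", "exosome")],
                     filter_low_counts, min_mean = config$low_count_min)
  shared <- Reduce(intersect, lapply(filtered, function(x) rownames(x$counts)))
  assert_that(length(shared) >= 3, "fewer than 3 features shared across datasets")
  filtered <- lapply(filtered, subset_features, feats = shared)

  ## stage: normalization
  norm <- lapply(filtered, normalize_log2)

  ## stage: similarity screen (surrogate tumors vs rare tumors)
  similarity <- rank_entities(
    mean_profile(norm$rare, "tumor"),
    list(surrogate = mean_profile(norm$surrogate, "tumor")))

  ## stage: PCA stratification
  pca <- fit_pca(norm$surrogate, n_components = 2)
  tumor_ids <- norm$surrogate$meta$sample_id[norm$surrogate$meta$group == "tumor"]
  rare_centered <- center_to_model(batch_center(norm$rare), pca)
  rare_tumor_scores <- project_samples(pca, rare_centered)[
    norm$rare$meta$group == "tumor", , drop = FALSE]
  pca <- anchor_dim2(pca, rare_tumor_scores)
  clusters <- assign_clusters(pca, pca$scores[tumor_ids, , drop = FALSE])
  rare_scores <- project_samples(pca, rare_centered)
  cluster_I_ids <- clusters$sample[clusters$cluster == "I"]
  normal_ids <- norm$surrogate$meta$sample_id[norm$surrogate$meta$group == "normal"]
  stratified <- subset_samples(norm$surrogate, c(cluster_I_ids, normal_ids))

  ## stage: concordance pre-filter
  prefilter <- concordance_prefilter(stratified, norm$rare,
                                     config$fc_threshold, config$p_threshold)
  selected <- prefilter$feature[prefilter$selected]

  ## stage: split, balance, train
  split <- split_train_test(stratified$meta$sample_id, stratified$meta$group,
                            derive_seed(seed, 21))
  train_groups <- stratified$meta$group[match(split$train,
                                              stratified$meta$sample_id)]
  balanced <- downsample_balance(split$train, train_groups,
                                 derive_seed(seed, 22))
  test_set <- subset_samples(stratified, split$test)

  report <- list(config = config,
                 similarity = similarity,
                 pca_explained = pca$explained,
                 clusters = clusters,
                 rare_scores = rare_scores,
                 prefilter = prefilter,
                 split = list(train = split$train, test = split$test,
                              balanced = balanced),
                 seeds = c(base = seed,
                           folds = derive_seed(config$train$seed, 11),
                           split = derive_seed(seed, 21),
                           balance = derive_seed(seed, 22),
                           qpcr = derive_seed(seed, 23)))

  if (length(selected) == 0) {
    report$signatures <- list()
    report$metrics <- NULL
    report$n_nonzero <- 0L
    class(report) <- "pipeline_report"
    if (!is.null(out_dir)) write_report(report, out_dir)
    return(report)
  }

  train_m <- subset_samples(subset_features(stratified, selected), balanced)
  zp <- fit_z(train_m)
  X <- t(apply_z(train_m, zp))
  y <- as.numeric(train_m$meta$group == "tumor")
  cv_full <- cv_elnet(X, y, config$train)
  sig_full <- extract_signature(cv_full$fit)

  eval_sets <- list(surrogate_test = subset_features(test_set, selected),
                    rare = subset_features(norm$rare, selected),
                    exosome = subset_features(norm$exosome, selected))

  ## stage: reduction
  dir_sets <- list(surrogate = subset_features(stratified, selected),
                   rare = subset_features(norm$rare, selected),
                   exosome = subset_features(norm$exosome, selected))
  sig_conc <- if (nrow(sig_full) > 0) {
    direction_concordance(sig_full, dir_sets)
  } else sig_full
  sig_reduced <- if (nrow(sig_conc) > 0) {
    abundance_filter(sig_conc, bundle$rare, config$abundance_threshold)
  } else sig_conc

  ## stage: qPCR confirmation of the reduced signature
  qpcr_results <- NULL
  sig_qpcr <- sig_reduced[0, , drop = FALSE]
  if (nrow(sig_reduced) > 0) {
    shares <- rowMeans(sweep(bundle$rare$counts, 2,
                             colSums(bundle$rare$counts), "/"))
    ref_pool <- setdiff(names(sort(shares, decreasing = TRUE)),
                        sig_full$feature)
    references <- utils::head(ref_pool, config$n_qpcr_references)
    qtab <- generate_qpcr_table(bundle, sig_reduced$feature, references,
                                derive_seed(seed, 23))
    qpcr_results <- qpcr_validate(qtab)
    sig_qpcr <- suppressWarnings(
      make_sig3(sig_reduced, qpcr_results, config$qpcr_p_threshold))
  }

  ## stage: retrain reduced models and evaluate everything
  models <- list(full = cv_full)
  if (nrow(sig_reduced) > 0 && nrow(sig_reduced) < nrow(sig_full)) {
    models$reduced <- retrain_reduced(sig_reduced$feature, X, y, config$train)
  } else if (nrow(sig_reduced) > 0) {
    models$reduced <- cv_full
  }
  if (nrow(sig_qpcr) > 0) {
    models$qpcr <- if (nrow(sig_qpcr) < nrow(sig_reduced)) {
      retrain_reduced(sig_qpcr$feature, X, y, config$train)
    } else models$reduced
  }

  metrics <- do.call(rbind, lapply(names(models), function(nm) {
    df <- evaluate_model(models[[nm]]$fit, eval_sets, config$class_threshold)
    cbind(model = sprintf("SIG-%d", sum(models[[nm]]$fit$beta != 0)),
          stage = nm, df, stringsAsFactors = FALSE)
  }))

  report$signatures <- list(full = sig_full, concordant = sig_conc,
                            reduced = sig_reduced, qpcr = sig_qpcr)
  report$models <- models
  report$metrics <- metrics
  report$qpcr <- qpcr_results
  report$n_nonzero <- sum(cv_full$fit$beta != 0)
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  shared features after detection: %d\n",
              nrow(x$prefilter %||% data.frame())))
  cat(sprintf("  pre-filtered candidates: %d\n",
              sum(x$prefilter$selected %||% 0)))
  cat(sprintf("  full-model nonzero coefficients: %d\n", x$n_nonzero %||% 0L))
  if (!is.null(x$metrics)) {
    cat("  AUC grid (%):\n")
    print(x$metrics[, c("stage", "model", "dataset", "auc_pct")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write pipeline artifacts
#'
#' Per-stage TSVs, the model JSONs, a summary JSON and a manifest with MD5
#' content hashes.
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$similarity, "similarity.tsv")
  wt(report$clusters, "clusters.tsv")
  wt(report$prefilter, "prefilter.tsv")
  if (!is.null(report$metrics)) wt(report$metrics, "metrics.tsv")
  if (!is.null(report$qpcr)) wt(report$qpcr, "qpcr.tsv")
  for (nm in names(report$signatures %||% list())) {
    if (nrow(report$signatures[[nm]]) > 0)
      wt(report$signatures[[nm]], sprintf("signature_%s.tsv", nm))
  }
  for (nm in names(report$models %||% list())) {
    write_elnet_fit(report$models[[nm]]$fit,
                    file.path(out_dir, sprintf("model_%s.json", nm)))
  }
  summary <- list(
    seeds = as.list(report$seeds),
    n_prefiltered = sum(report$prefilter$selected),
    n_nonzero = report$n_nonzero,
    signature_sizes = lapply(report$signatures %||% list(), nrow),
    auc = if (!is.null(report$metrics))
      split(stats::setNames(report$metrics$auc_pct, report$metrics$dataset),
            report$metrics$stage))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- lapply(stats::setNames(file.path(out_dir, files), files),
                     function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
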