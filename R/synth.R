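#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions the simulator emulates: a large surrogate
#' tumor cohort with two latent tumor sub-clusters plus normals, a small rare
#' cohort, and a shallow exosome cohort, with a planted set of concordantly
#' up/down-regulated miRNAs of controlled effect size over a negative-binomial
#' background with a log-normal abundance ladder.
#'
#' @param n_features number of miRNAs.
#' @param n_surrogate_tumor_I,n_surrogate_tumor_II,n_surrogate_normal
#'   surrogate cohort sample counts (defaults 180 / 100 / 44).
#' @param n_rare_tumor,n_rare_normal rare cohort counts (defaults 6 / 9).
#' @param n_exo_tumor,n_exo_control exosome cohort counts (defaults 7 / 6).
#' @param n_signature_up,n_signature_down planted signature sizes (8 / 7).
#' @param n_cluster2_module features carrying the orthogonal sub-cluster
#'   module (default 8).
#' @param lfc_signature planted tumor-vs-normal effect, log2 units (default 2,
#'   i.e. four-fold).
#' @param lfc_cluster2 sub-cluster module effect, log2 units (default 1.5).
#' @param nb_dispersion negative-binomial dispersion phi in
#'   `var = mu + phi mu^2` (default 0.15).
#' @param depth_mean_surrogate,depth_mean_rare,depth_mean_exo expected
#'   library sizes in reads (defaults 2e6 / 5e6 / 5e4).
#' @param seed integer RNG seed; all randomness derives from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_features = 500,
                             n_surrogate_tumor_I = 180,
                             n_surrogate_tumor_II = 100,
                             n_surrogate_normal = 44,
                             n_rare_tumor = 6, n_rare_normal = 9,
                             n_exo_tumor = 7, n_exo_control = 6,
                             n_signature_up = 8, n_signature_down = 7,
                             n_cluster2_module = 8,
                             lfc_signature = 2, lfc_cluster2 = 1.5,
                             nb_dispersion = 0.15,
                             depth_mean_surrogate = 2e6,
                             depth_mean_rare = 5e6,
                             depth_mean_exo = 5e4,
                             seed = 1) {
  cfg <- as.list(environment())
  counts <- unlist(cfg[grep("^n_", names(cfg))])
  assert_that(all(counts >= 0), "all counts must be >= 0")
  assert_that(lfc_signature >= 0, "lfc_signature must be >= 0")
  assert_that(nb_dispersion > 0, "nb_dispersion must be > 0")
  assert_that(n_signature_up + n_signature_down + n_cluster2_module <=
                n_features,
              "planted sets exceed n_features")
  structure(cfg, class = "synthetic_config")
}

rnb_counts <- function(mu, phi) {
  matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / phi),
         nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Generate the three synthetic cohorts
#'
#' Counts are drawn feature-wise from negative binomials whose mean is a
#' shared baseline abundance profile (log-normal ladder, normalized to unit
#' share) scaled by a per-sample library size drawn around the cohort's
#' configured depth. Tumor samples in every cohort have planted signature
#' features scaled by `2^(+/- lfc_signature)`; surrogate cluster-II tumors
#' additionally carry an orthogonal module scaled by `2^(+/- lfc_cluster2)`.
#' Signature features are planted on the abundant half of the ladder so they
#' remain detectable at exosome depth; the sub-cluster module is drawn from
#' the remaining features. One exosome control sample shares the rare-disease
#' batch label (mirroring the mixed control composition of such cohorts), so
#' group-vs-batch logic is exercised downstream.
#'
#' @param config a [synthetic_config()].
#' @return list of class `cohort_bundle`: `surrogate`, `rare`, `exosome`
#'   ([count_matrix()] each), `truth` (planted feature names with directions
#'   and the cluster-II module), `cluster_truth` (named `"I"`/`"II"` per
#'   surrogate tumor sample), `config`.
#' @export
generate_cohorts <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  features <- sprintf("mir-%04d", seq_len(cfg$n_features))

  plan <- with_seed(derive_seed(cfg$seed, 1), {
    weight <- stats::rlnorm(cfg$n_features, meanlog = 0, sdlog = 1.5)
    share <- weight / sum(weight)
    abundant <- features[order(share, decreasing = TRUE)][
      seq_len(ceiling(cfg$n_features / 2))]
    sig <- sample(abundant, cfg$n_signature_up + cfg$n_signature_down)
    up <- sig[seq_len(cfg$n_signature_up)]
    down <- setdiff(sig, up)
    pool <- setdiff(features, sig)
    c2 <- sample(pool, cfg$n_cluster2_module)
    c2_up <- c2[seq_len(ceiling(length(c2) / 2))]
    c2_down <- setdiff(c2, c2_up)
    list(share = stats::setNames(share, features), up = up, down = down,
         cluster2_up = c2_up, cluster2_down = c2_down)
  })

  base_lfc <- stats::setNames(rep(0, cfg$n_features), features)
  base_lfc[plan$up] <- cfg$lfc_signature
  base_lfc[plan$down] <- -cfg$lfc_signature
  c2_lfc <- stats::setNames(rep(0, cfg$n_features), features)
  c2_lfc[plan$cluster2_up] <- cfg$lfc_cluster2
  c2_lfc[plan$cluster2_down] <- -cfg$lfc_cluster2

  simulate <- function(n_per_type, types, depth_mean, stream) {
    # types: list of per-sample multipliers on the log2 scale
    n <- length(types)
    with_seed(derive_seed(cfg$seed, stream), {
      depth <- depth_mean * stats::rlnorm(n, meanlog = -0.3^2 / 2, sdlog = 0.3)
      mu <- vapply(seq_len(n), function(i)
        plan$share * 2^types[[i]] * depth[i], numeric(cfg$n_features))
      rownames(mu) <- features
      rnb_counts(mu, cfg$nb_dispersion)
    })
  }

  # surrogate cohort
  sur_types <- c(replicate(cfg$n_surrogate_tumor_I, base_lfc,
                           simplify = FALSE),
                 replicate(cfg$n_surrogate_tumor_II, base_lfc + c2_lfc,
                           simplify = FALSE),
                 replicate(cfg$n_surrogate_normal, base_lfc * 0,
                           simplify = FALSE))
  sur_counts <- simulate(NULL, sur_types, cfg$depth_mean_surrogate, 2)
  n_sur_tum <- cfg$n_surrogate_tumor_I + cfg$n_surrogate_tumor_II
  sur_ids <- c(sprintf("SUR-T%03d", seq_len(n_sur_tum)),
               sprintf("SUR-N%03d", seq_len(cfg$n_surrogate_normal)))
  colnames(sur_counts) <- sur_ids
  sur_meta <- data.frame(
    sample_id = sur_ids,
    group = rep(c("tumor", "normal"),
                c(n_sur_tum, cfg$n_surrogate_normal)),
    dataset = "surrogate", batch = "surrogate",
    stringsAsFactors = FALSE)
  surrogate <- count_matrix(sur_counts, sur_meta)
  cluster_truth <- stats::setNames(
    rep(c("I", "II"), c(cfg$n_surrogate_tumor_I, cfg$n_surrogate_tumor_II)),
    sur_ids[seq_len(n_sur_tum)])

  # rare cohort (cells); controls split across two donor batches
  rare_types <- c(replicate(cfg$n_rare_tumor, base_lfc, simplify = FALSE),
                  replicate(cfg$n_rare_normal, base_lfc * 0,
                            simplify = FALSE))
  rare_counts <- simulate(NULL, rare_types, cfg$depth_mean_rare, 3)
  rare_ids <- c(sprintf("RARE-T%02d", seq_len(cfg$n_rare_tumor)),
                sprintf("RARE-N%02d", seq_len(cfg$n_rare_normal)))
  colnames(rare_counts) <- rare_ids
  n_rare_dis <- ceiling(cfg$n_rare_normal / 2)
  rare_meta <- data.frame(
    sample_id = rare_ids,
    group = rep(c("tumor", "normal"),
                c(cfg$n_rare_tumor, cfg$n_rare_normal)),
    dataset = "rare",
    batch = c(rep("rare_disease", cfg$n_rare_tumor),
              rep(c("rare_disease", "healthy"),
                  c(n_rare_dis, cfg$n_rare_normal - n_rare_dis))),
    stringsAsFactors = FALSE)
  rare <- count_matrix(rare_counts, rare_meta)

  # exosome cohort (shallow); one control carries the rare-disease batch
  exo_types <- c(replicate(cfg$n_exo_tumor, base_lfc, simplify = FALSE),
                 replicate(cfg$n_exo_control, base_lfc * 0,
                           simplify = FALSE))
  exo_counts <- simulate(NULL, exo_types, cfg$depth_mean_exo, 4)
  exo_ids <- c(sprintf("EXO-T%02d", seq_len(cfg$n_exo_tumor)),
               sprintf("EXO-N%02d", seq_len(cfg$n_exo_control)))
  colnames(exo_counts) <- exo_ids
  exo_batch <- c(rep("rare_disease", cfg$n_exo_tumor),
                 rep("healthy", cfg$n_exo_control))
  if (cfg$n_exo_control > 0) exo_batch[cfg$n_exo_tumor + 1] <- "rare_disease"
  exo_meta <- data.frame(
    sample_id = exo_ids,
    group = rep(c("tumor", "normal"),
                c(cfg$n_exo_tumor, cfg$n_exo_control)),
    dataset = "exosome", batch = exo_batch,
    stringsAsFactors = FALSE)
  exosome <- count_matrix(exo_counts, exo_meta)

  structure(list(surrogate = surrogate, rare = rare, exosome = exosome,
                 truth = list(up = plan$up, down = plan$down,
                              cluster2_up = plan$cluster2_up,
                              cluster2_down = plan$cluster2_down,
                              share = plan$share),
                 cluster_truth = cluster_truth, config = cfg),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "cohort_bundle: surrogate %d, rare %d, exosome %d samples; %d features; %d planted\n",
    ncol(x$surrogate$counts), ncol(x$rare$counts), ncol(x$exosome$counts),
    nrow(x$surrogate$counts), length(x$truth$up) + length(x$truth$down)))
  invisible(x)
}

#' Generate a synthetic qPCR Cq table from a cohort bundle
#'
#' Target Cq values follow the rare cohort's expression:
#' `Cq = base_cq - log2(cpm + 0.5) + noise`, so a doubling of expression
#' lowers Cq by one cycle. Reference assays are generated from each
#' reference feature's mean expression plus low-variance noise (one tenth of
#' `noise_sd`), emulating stable reference RNAs.
#'
#' @param bundle a `cohort_bundle`.
#' @param targets feature names assayed as targets.
#' @param references feature names assayed as stable references.
#' @param seed integer seed.
#' @param noise_sd Gaussian Cq noise for targets, cycles (default 0.25).
#' @param base_cq offset cycle count (default 30).
#' @return a [qpcr_table()] over the rare cohort's samples.
#' @export
generate_qpcr_table <- function(bundle, targets, references, seed,
                                noise_sd = 0.25, base_cq = 30) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  assert_that(length(targets) >= 1 && length(references) >= 1,
              "targets and references must be non-empty")
  rare <- bundle$rare
  unknown <- setdiff(c(targets, references), rownames(rare$counts))
  assert_that(length(unknown) == 0,
              paste("unknown feature names:", paste(unknown, collapse = ", ")))
  cpm <- sweep(rare$counts, 2, colSums(rare$counts), "/") * 1e6
  samples <- colnames(rare$counts)
  groups <- rare$meta$group
  with_seed(derive_seed(seed, 7), {
    rows <- list()
    for (f in targets) {
      cq <- base_cq - log2(cpm[f, ] + 0.5) +
        stats::rnorm(length(samples), 0, noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        sample = samples, group = groups, assay = f, role = "target",
        cq = as.numeric(cq), stringsAsFactors = FALSE)
    }
    for (f in references) {
      level <- base_cq - log2(mean(cpm[f, ]) + 0.5)
      cq <- level + stats::rnorm(length(samples), 0, noise_sd / 10)
      rows[[length(rows) + 1]] <- data.frame(
        sample = samples, group = groups, assay = f, role = "reference",
        cq = as.numeric(cq), stringsAsFactors = FALSE)
    }
    qpcr_table(do.call(rbind, rows))
  })
}

#' Write a cohort bundle to disk
#'
#' Each cohort goes to the package's standard count/metadata TSV pair; the
#' planted truth record is written as JSON.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("surrogate", "rare", "exosome")) {
    write_count_matrix(bundle[[nm]],
                       file.path(dir, paste0(nm, "_counts.tsv")),
                       file.path(dir, paste0(nm, "_meta.tsv")))
  }
  jsonlite::write_json(
    list(up = bundle$truth$up, down = bundle$truth$down,
         cluster2_up = bundle$truth$cluster2_up,
         cluster2_down = bundle$truth$cluster2_down,
         cluster_truth = as.list(bundle$cluster_truth)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
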