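small_config <- function(...) {
  synthetic_config(n_features = 60, n_surrogate_tumor_I = 20,
                   n_surrogate_tumor_II = 12, n_surrogate_normal = 10,
                   n_signature_up = 4, n_signature_down = 3,
                   n_cluster2_module = 4,
                   depth_mean_surrogate = 2e5, depth_mean_rare = 2e5,
                   depth_mean_exo = 2e4, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_features = 10, n_signature_up = 6,
                                n_signature_down = 4, n_cluster2_module = 3),
               "exceed")
  expect_error(synthetic_config(nb_dispersion = 0), "dispersion")
  expect_error(synthetic_config(lfc_signature = -1), "lfc_signature")
})

test_that("identical seeds give identical bundles; different seeds differ", {
  b1 <- generate_cohorts(small_config(seed = 5))
  b2 <- generate_cohorts(small_config(seed = 5))
  expect_identical(b1$surrogate$counts, b2$surrogate$counts)
  expect_identical(b1$truth, b2$truth)
  b3 <- generate_cohorts(small_config(seed = 6))
  expect_false(identical(b1$surrogate$counts, b3$surrogate$counts))
})

test_that("planted sets are disjoint and present in all three cohorts", {
  b <- generate_cohorts(small_config(seed = 7))
  planted <- c(b$truth$up, b$truth$down)
  module <- c(b$truth$cluster2_up, b$truth$cluster2_down)
  expect_length(intersect(planted, module), 0)
  for (m in list(b$surrogate, b$rare, b$exosome)) {
    expect_true(all(c(planted, module) %in% rownames(m$counts)))
    expect_true(all(m$meta$group %in% c("tumor", "normal")))
  }
  expect_equal(unname(table(b$cluster_truth)[c("I", "II")]), c(20L, 12L),
               ignore_attr = TRUE)
})

test_that("library sizes track the configured depth", {
  cfg <- synthetic_config(n_features = 100, n_surrogate_tumor_I = 50,
                          n_surrogate_tumor_II = 30,
                          n_surrogate_normal = 20,
                          depth_mean_surrogate = 1e5, seed = 8)
  b <- generate_cohorts(cfg)
  mean_depth <- mean(colSums(b$surrogate$counts))
  expect_gt(mean_depth, 0.5 * 1e5)
  expect_lt(mean_depth, 1.5 * 1e5)
})

test_that("planted effects are detectable by per-feature t-tests (oracle)", {
  # direct simulation oracle: at lfc 2 and 20 per group, a two-sample t-test
  # on log-normalized planted features rejects at p < 0.01 for > 90% of
  # planted features across replicates
  hits <- 0; total <- 0
  for (r in 1:20) {
    cfg <- synthetic_config(n_features = 60, n_surrogate_tumor_I = 20,
                            n_surrogate_tumor_II = 0,
                            n_surrogate_normal = 20,
                            n_signature_up = 4, n_signature_down = 3,
                            n_cluster2_module = 0, lfc_signature = 2,
                            depth_mean_surrogate = 2e5, seed = 900 + r)
    b <- generate_cohorts(cfg)
    nm <- normalize_log2(b$surrogate)
    grp <- nm$meta$group
    for (f in c(b$truth$up, b$truth$down)) {
      p <- stats::t.test(nm$values[f, grp == "tumor"],
                         nm$values[f, grp == "normal"])$p.value
      hits <- hits + (p < 0.01); total <- total + 1
    }
  }
  expect_gt(hits / total, 0.9)
})

test_that("a null effect size leaves planted features undetectable", {
  cfg <- small_config(seed = 9, lfc_signature = 0)
  b <- generate_cohorts(cfg)
  nm <- normalize_log2(b$surrogate)
  grp <- nm$meta$group
  p <- vapply(c(b$truth$up, b$truth$down), function(f)
    stats::t.test(nm$values[f, grp == "tumor"],
                  nm$values[f, grp == "normal"])$p.value, numeric(1))
  expect_gt(min(p), 0.001)   # nothing wildly significant at null
})

test_that("sub-cluster structure is visible to pca when planted", {
  b <- generate_cohorts(synthetic_config(seed = 10))
  nm <- normalize_log2(b$surrogate)
  pc <- fit_pca(nm, 2)
  sc <- pc$scores
  grp <- nm$meta$group
  truth <- b$cluster_truth[rownames(sc)[grp == "tumor"]]
  tumor_sc <- sc[grp == "tumor", ]
  # tumors separate from normals on Dim1
  expect_gt(mean(tumor_sc[, 1]), mean(sc[grp == "normal", 1]))
  # the two tumor subclusters separate along Dim2
  d2_I <- tumor_sc[truth == "I", 2]; d2_II <- tumor_sc[truth == "II", 2]
  expect_gt(abs(mean(d2_I) - mean(d2_II)),
            2 * (sd(d2_I) + sd(d2_II)))
})

test_that("qpcr generation reflects expression with analytic expectations", {
  b <- generate_cohorts(small_config(seed = 11, lfc_signature = 2))
  up <- b$truth$up[1]
  flat <- setdiff(rownames(b$rare$counts),
                  unlist(b$truth[c("up", "down", "cluster2_up",
                                   "cluster2_down")]))[1:2]
  tab <- generate_qpcr_table(b, targets = up, references = flat, seed = 3,
                             noise_sd = 0)
  d <- delta_cq(tab, flat)
  diff_dcq <- mean(d$delta_cq[d$group == "tumor"]) -
    mean(d$delta_cq[d$group == "normal"])
  expect_lt(abs(diff_dcq - (-2)), 0.6)   # 4-fold up -> about -2 cycles
  # determinism
  tab2 <- generate_qpcr_table(b, targets = up, references = flat, seed = 3,
                              noise_sd = 0)
  expect_identical(tab, tab2)
  expect_error(generate_qpcr_table(b, "not-a-mir", flat, 1), "unknown")
})

test_that("zero-noise cq values equal the analytic generator expectation", {
  b <- generate_cohorts(small_config(seed = 12, lfc_signature = 0))
  feats <- rownames(b$rare$counts)[1:3]
  tab <- generate_qpcr_table(b, targets = feats[1], references = feats[2:3],
                             seed = 1, noise_sd = 0, base_cq = 30)
  cpm <- sweep(b$rare$counts, 2, colSums(b$rare$counts), "/") * 1e6
  tgt <- tab[tab$role == "target", ]
  expect_equal(tgt$cq, unname(30 - log2(cpm[feats[1], tgt$sample] + 0.5)))
  # a target with expression equal to the reference summary has delta-cq 0
  ref_rows <- tab[tab$role == "reference", ]
  ref_mean <- tapply(ref_rows$cq, ref_rows$sample, mean)
  d <- delta_cq(tab, feats[2:3])
  expect_equal(d$delta_cq, as.numeric(tgt$cq - ref_mean[tgt$sample]))
})

test_that("cohort bundles round-trip through the on-disk layout", {
  b <- generate_cohorts(small_config(seed = 13))
  dir <- withr::local_tempdir()
  write_cohort_bundle(b, dir)
  sur <- read_count_matrix(file.path(dir, "surrogate_counts.tsv"),
                           file.path(dir, "surrogate_meta.tsv"))
  expect_equal(sur$counts, b$surrogate$counts)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$up, b$truth$up)
})
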