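three_datasets <- function(effects, seed = 71) {
  # effects: features x 3 matrix of log2 tumor-normal offsets
  set.seed(seed)
  mk <- function(eff, n_t, n_n) {
    shift <- outer(eff, c(rep(1, n_t), rep(0, n_n)))
    toy_normalized(shift + matrix(rnorm(length(eff) * (n_t + n_n),
                                        sd = 0.01), length(eff)),
                   groups = rep(c("tumor", "normal"), c(n_t, n_n)))
  }
  list(surrogate = mk(effects[, 1], 8, 8),
       rare = mk(effects[, 2], 6, 9),
       exosome = mk(effects[, 3], 7, 6))
}

test_that("direction concordance keeps only features agreeing in all sets", {
  eff <- rbind(c(1, 1, 1), c(-1, -1, -1), c(1, 1, -1), c(-1, 1, -1))
  ds <- three_datasets(eff)
  sig <- data.frame(feature = rownames(ds$surrogate$values)[1:4],
                    beta = c(0.5, -0.4, 0.3, -0.2))
  out <- direction_concordance(sig, ds)
  expect_equal(out$feature, sig$feature[1:2])
  expect_equal(out$dir_surrogate, c("up", "down"))
  # all-up toy signature: identity
  all_up <- three_datasets(matrix(1, 3, 3))
  sig2 <- data.frame(feature = rownames(all_up$surrogate$values),
                     beta = c(1, 1, 1))
  expect_equal(nrow(direction_concordance(sig2, all_up)), 3)
  # flipping one dataset's labels empties the concordant set
  flipped <- all_up
  flipped$exosome$meta$group <- rev(flipped$exosome$meta$group)
  expect_equal(nrow(direction_concordance(sig2, flipped)), 0)
})

test_that("direction concordance accepts a precomputed direction table", {
  sig <- data.frame(feature = c("a", "b", "c"), beta = c(1, -1, 1))
  dirs <- data.frame(surrogate = c("up", "down", "up"),
                     rare = c("up", "down", "down"),
                     exo = c("up", "down", "up"))
  out <- direction_concordance(sig, dirs)
  expect_equal(out$feature, c("a", "b"))
})

test_that("abundance filter applies the 0.1% read-share rule per group", {
  # feature 1: 0.2% in tumors; feature 2: 0.05% everywhere; feature 3 high
  tot <- 1e5
  cnt <- rbind(c(200, 200, 50, 50),     # 0.2% tumor share -> kept
               c(50, 50, 50, 50),       # 0.05% -> dropped
               c(5000, 5000, 5000, 5000))
  cnt <- rbind(cnt, matrix(round((tot - colSums(cnt)) / 2), 2, 4))
  x <- toy_counts(counts = cnt,
                  groups = c("tumor", "tumor", "normal", "normal"))
  sig <- data.frame(feature = rownames(x$counts)[1:3])
  out <- abundance_filter(sig, x, threshold = 0.001)
  expect_setequal(out$feature, c("mir-01", "mir-03"))
  expect_gt(out$abundance_share[out$feature == "mir-01"], 0.001)
  # threshold 0 keeps everything
  expect_equal(nrow(abundance_filter(sig, x, threshold = 0)), 3)
  # either-group rule: tumor-only abundance suffices
  expect_true("mir-01" %in% out$feature)
})

test_that("abundance filter can run on recorded strong-expression calls", {
  sig <- data.frame(feature = c("a", "b"), abundant = c(TRUE, FALSE))
  expect_equal(abundance_filter(sig)$feature, "a")
  expect_error(abundance_filter(data.frame(feature = "a")), "abundant")
})

test_that("dominant arm picks the heavier strand with -5p tie rule", {
  x <- toy_counts(counts = rbind(c(60, 40), c(15, 5), c(0, 50), c(25, 25)),
                  groups = c("tumor", "normal"),
                  features = c("mir-9-5p", "mir-9-3p", "mir-7-3p",
                               "mir-5-5p"))
  expect_equal(dominant_arm(x, "mir-9"), "-5p")
  expect_equal(dominant_arm(x, "mir-7"), "-3p")
  x2 <- toy_counts(counts = rbind(c(10, 10), c(10, 10)),
                   groups = c("tumor", "normal"),
                   features = c("mir-5-5p", "mir-5-3p"))
  expect_warning(arm <- dominant_arm(x2, "mir-5"), "tie")
  expect_equal(arm, "-5p")
})

test_that("qpcr confirmation keeps significant, direction-concordant members", {
  sig10 <- data.frame(feature = c("a", "b", "c", "d"),
                      direction = c("up", "up", "down", "up"))
  qres <- data.frame(feature = c("a", "b", "c", "d"),
                     p = c(0.01, 0.20, 0.01, 0.03),
                     direction = c("up", "up", "down", "down"))
  out <- make_sig3(sig10, qres)
  expect_equal(out$feature, c("a", "c"))   # b insignificant, d discordant
  # nothing significant: empty with a warning
  qres$p <- 0.5
  expect_warning(out2 <- make_sig3(sig10, qres), "no significant")
  expect_equal(nrow(out2), 0)
})

test_that("retraining on the full signature reproduces the original model", {
  set.seed(72)
  grp <- rep(0:1, each = 20)
  X <- scale(matrix(rnorm(40 * 6), 40, 6) + outer(grp, c(2, -2, 0, 0, 0, 0)))
  colnames(X) <- paste0("f", 1:6)
  cfg <- train_config(alpha_grid = c(0.3, 1), seed = 5,
                      lambda_path_length = 30)
  cv <- cv_elnet(X, grp, cfg)
  re <- retrain_reduced(colnames(X), X, grp, cfg)
  expect_equal(re$fit$beta, cv$fit$beta)
  expect_error(retrain_reduced(character(0), X, grp, cfg), "empty")
  # reduced models never use features outside their list
  re2 <- retrain_reduced(c("f1", "f2"), X, grp, cfg)
  expect_setequal(re2$fit$features, c("f1", "f2"))
})
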