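sim_xy <- function(n = 60, p = 6, strength = 0.8, seed = 51) {
  # non-separable toy logistic data
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("f", seq_len(p))
  y <- rbinom(n, 1, plogis(0.2 + strength * X[, 1] - 0.5 * X[, 2]))
  list(X = X, y = y)
}

test_that("stratified split halves each class and partitions the samples", {
  ids <- c(sprintf("T%03d", 1:277), sprintf("N%02d", 1:44))
  groups <- rep(c("tumor", "normal"), c(277, 44))
  sp <- split_train_test(ids, groups, seed = 9)
  expect_equal(sort(c(sp$train, sp$test)), sort(ids))
  expect_length(intersect(sp$train, sp$test), 0)
  # 277 tumors: 139 train / 138 test or the reverse is fixed by ceiling
  expect_equal(sum(grepl("^T", sp$train)), 139)
  expect_equal(sum(grepl("^T", sp$test)), 138)
  expect_equal(sum(grepl("^N", sp$train)), 22)
  expect_equal(sum(grepl("^N", sp$test)), 22)
  expect_identical(split_train_test(ids, groups, seed = 9), sp)
  expect_false(identical(split_train_test(ids, groups, seed = 10)$train,
                         sp$train))
})

test_that("downsampling balances classes and leaves balanced sets alone", {
  ids <- c(sprintf("T%03d", 1:139), sprintf("N%02d", 1:22))
  groups <- rep(c("tumor", "normal"), c(139, 22))
  bal <- downsample_balance(ids, groups, seed = 3)
  expect_equal(sum(grepl("^T", bal)), 22)
  expect_equal(sum(grepl("^N", bal)), 22)
  expect_true(all(bal %in% ids))
  balanced <- c("T1", "T2", "N1", "N2")
  expect_setequal(downsample_balance(balanced, c("tumor", "tumor", "normal",
                                                 "normal"), 1), balanced)
})

test_that("large penalties give the null model with intercept logit(ybar)", {
  d <- sim_xy()
  f <- fit_elnet_logistic(d$X, d$y, alpha = 0.5, lambda = 10)
  expect_true(all(f$beta == 0))
  expect_equal(f$beta0, qlogis(mean(d$y)), tolerance = 1e-6)
  # lambda_max from the path is the boundary of all-zero fits
  lam <- lambda_path(d$X, d$y, alpha = 1)
  f_edge <- fit_elnet_logistic(d$X, d$y, 1, lam[1])
  expect_true(all(f_edge$beta == 0))
})

test_that("lambda = 0 reproduces the unregularized logistic MLE", {
  d <- sim_xy()
  f <- fit_elnet_logistic(d$X, d$y, alpha = 0.5, lambda = 0,
                          max_iter = 500, tol = 1e-12)
  g <- stats::glm(d$y ~ d$X, family = stats::binomial)
  expect_equal(unname(c(f$beta0, f$beta)), unname(coef(g)), tolerance = 1e-4)
})

test_that("kkt conditions hold at the returned solution", {
  d <- sim_xy(n = 80, p = 10)
  for (alpha in c(0.2, 0.6, 1)) {
    lambda <- 0.05
    f <- fit_elnet_logistic(d$X, d$y, alpha, lambda, tol = 1e-10,
                            max_iter = 300)
    prob <- plogis(f$beta0 + drop(d$X %*% f$beta))
    score <- drop(crossprod(d$X, prob - d$y)) / nrow(d$X) +
      lambda * (1 - alpha) * f$beta
    nz <- f$beta != 0
    if (any(nz)) expect_lt(max(abs(abs(score[nz]) - lambda * alpha)), 1e-7)
    if (any(!nz)) expect_lte(max(abs(score[!nz])), lambda * alpha + 1e-7)
    expect_lt(abs(mean(prob - d$y)), 1e-7)   # unpenalized intercept
  }
})

test_that("solutions agree with glmnet across the mixing grid", {
  skip_if_not_installed("glmnet")
  d <- sim_xy(n = 70, p = 8, seed = 53)
  for (alpha in c(0.1, 0.5, 0.9)) {
    for (lambda in c(0.02, 0.1)) {
      f <- fit_elnet_logistic(d$X, d$y, alpha, lambda, tol = 1e-12,
                              max_iter = 500)
      g <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = alpha,
                          lambda = lambda, standardize = FALSE,
                          thresh = 1e-14)
      expect_equal(f$beta0, as.numeric(g$a0), tolerance = 1e-5)
      expect_equal(unname(f$beta), as.numeric(g$beta), tolerance = 1e-5)
    }
  }
})

test_that("solution is invariant to feature order", {
  d <- sim_xy()
  f <- fit_elnet_logistic(d$X, d$y, 0.5, 0.05, tol = 1e-10)
  perm <- c(3, 1, 6, 2, 5, 4)
  fp <- fit_elnet_logistic(d$X[, perm], d$y, 0.5, 0.05, tol = 1e-10)
  expect_equal(fp$beta[colnames(d$X)], f$beta, tolerance = 1e-8)
})

test_that("nonzero count is non-increasing in lambda along a lasso path", {
  d <- sim_xy(n = 50, p = 10, seed = 55)
  lam <- lambda_path(d$X, d$y, alpha = 1, length.out = 30)
  fits <- surrosig:::fit_elnet_path(d$X, d$y, 1, lam)
  nz <- vapply(fits, function(f) sum(f$beta != 0), numeric(1))
  # lambdas descend along the path, so the active set grows; allow a slack
  # of one feature for swaps between correlated predictors
  expect_true(all(diff(nz) >= -1))
  expect_equal(nz[1], 0)   # path starts at the all-zero boundary
})

test_that("cross-validation honors the 1-se definition and fold seeding", {
  d <- sim_xy(n = 44, p = 8, strength = 1.5, seed = 56)
  cfg <- train_config(alpha_grid = c(0.3, 1), n_folds = 5, seed = 2,
                      lambda_path_length = 40)
  cv <- cv_elnet(d$X, d$y, cfg)
  expect_true(all(cv$per_alpha$lambda_1se >= cv$per_alpha$lambda_min))
  expect_true(cv$alpha_opt %in% cfg$alpha_grid)
  expect_true(all(cv$cv_table$cvm >= 0))
  cv2 <- cv_elnet(d$X, d$y, cfg)
  expect_identical(cv$fit$beta, cv2$fit$beta)   # deterministic
})

test_that("pure-noise features yield an empty model under the 1-se rule", {
  zeros <- 0L
  for (seed in 1:5) {
    set.seed(600 + seed)
    X <- scale(matrix(rnorm(44 * 20), 44, 20))
    colnames(X) <- paste0("f", 1:20)
    y <- rep(c(0, 1), each = 22)
    cv <- cv_elnet(X, y, train_config(alpha_grid = seq(0, 1, 0.2),
                                      seed = seed,
                                      lambda_path_length = 40))
    zeros <- zeros + (sum(cv$fit$beta != 0) == 0)
  }
  expect_gte(zeros, 4)
})

test_that("a strong planted signal is recovered by the chosen model", {
  set.seed(57)
  grp <- rep(0:1, each = 22)
  X <- matrix(rnorm(44 * 10), 44, 10)
  X[, 1:4] <- X[, 1:4] + outer(grp, c(2, 2, -2, -2))
  X <- scale(X); colnames(X) <- paste0("f", 1:10)
  cv <- cv_elnet(X, grp, train_config(alpha_grid = c(0.1, 0.5, 1), seed = 1,
                                      lambda_path_length = 40))
  sig <- extract_signature(cv$fit)
  expect_gte(sum(paste0("f", 1:4) %in% sig$feature), 3)
  expect_equal(sig$direction[sig$feature == "f1"], "up")
})

test_that("signature extraction orders by |beta| with sign tags", {
  fit <- structure(list(beta0 = 0,
                        beta = c(a = 0.1, b = -0.5, c = 0, d = 0.3),
                        alpha = 0.5, lambda = 0.1,
                        features = c("a", "b", "c", "d"),
                        converged = TRUE, iterations = 1),
                   class = "elnet_fit")
  sig <- extract_signature(fit)
  expect_equal(sig$feature, c("b", "d", "a"))
  expect_equal(sig$direction, c("down", "up", "up"))
  fit$beta[] <- 0
  expect_equal(nrow(extract_signature(fit)), 0)
})

test_that("refitting on the signature's own features reproduces predictions", {
  d <- sim_xy(n = 60, p = 8, strength = 1.2, seed = 58)
  f <- fit_elnet_logistic(d$X, d$y, 0.5, 0.08, tol = 1e-10, max_iter = 300)
  sig <- extract_signature(f)
  expect_gt(nrow(sig), 0)
  f2 <- fit_elnet_logistic(d$X[, sig$feature, drop = FALSE], d$y, 0.5, 0.08,
                           tol = 1e-10, max_iter = 300)
  p1 <- predict_proba(f, d$X)
  p2 <- predict_proba(f2, d$X[, sig$feature, drop = FALSE])
  expect_equal(p1, p2, tolerance = 1e-6)
})
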