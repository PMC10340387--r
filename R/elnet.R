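#' Training configuration for the elastic-net classifier
#'
#' @param alpha_grid mixing parameters to scan; 0 = ridge, 1 = lasso.
#' @param n_folds cross-validation folds (default 10; 5 also supported).
#' @param lambda_path_length number of penalties on the geometric path.
#' @param lambda_min_ratio smallest path penalty relative to lambda_max.
#' @param rule `"lambda_1se"` (default: largest penalty whose CV deviance is
#'   within one standard error of the minimum) or `"lambda_min"`.
#' @param seed integer seed for fold assignment.
#' @param max_iter maximum outer IRLS iterations per fit.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @return list of class `train_config`.
#' @export
train_config <- function(alpha_grid = seq(0, 1, by = 0.1), n_folds = 10,
                         lambda_path_length = 100, lambda_min_ratio = 1e-3,
                         rule = c("lambda_1se", "lambda_min"), seed = 1,
                         max_iter = 100, tol = 1e-7) {
  rule <- match.arg(rule)
  assert_that(all(alpha_grid >= 0 & alpha_grid <= 1),
              "alpha grid must lie in [0, 1]")
  assert_that(n_folds >= 2, "need at least 2 folds")
  assert_that(tol > 0, "tol must be positive")
  structure(list(alpha_grid = alpha_grid, n_folds = n_folds,
                 lambda_path_length = lambda_path_length,
                 lambda_min_ratio = lambda_min_ratio, rule = rule,
                 seed = seed, max_iter = max_iter, tol = tol),
            class = "train_config")
}

#' Stratified half/half train-test split
#'
#' Splits samples of each class at random into equal halves (sizes differing
#' by at most one for odd classes); the split is seeded and deterministic.
#'
#' @param ids sample ids.
#' @param groups class labels aligned with `ids`.
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_train_test <- function(ids, groups, seed) {
  assert_that(length(ids) == length(groups), "ids/groups length mismatch")
  with_seed(seed, {
    train <- character(0)
    for (g in sort(unique(groups))) {
      members <- ids[groups == g]
      n_train <- ceiling(length(members) / 2)
      train <- c(train, sample(members, n_train))
    }
    list(train = sort(train), test = sort(setdiff(ids, train)))
  })
}

#' Downsample the majority class to a balanced set
#'
#' Randomly subsamples the larger class without replacement to the size of
#' the smaller class. An already balanced input is returned unchanged.
#'
#' @param ids sample ids (e.g. a training split).
#' @param groups class labels aligned with `ids`.
#' @param seed integer seed.
#' @return character vector of retained ids (equal class counts).
#' @export
downsample_balance <- function(ids, groups, seed) {
  assert_that(length(ids) == length(groups), "ids/groups length mismatch")
  tab <- table(groups)
  n_min <- min(tab)
  with_seed(seed, {
    keep <- character(0)
    for (g in names(tab)) {
      members <- ids[groups == g]
      keep <- c(keep, if (length(members) > n_min) sample(members, n_min)
                      else members)
    }
    sort(keep)
  })
}

## ---- penalized binomial fitting ------------------------------------------

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Geometric penalty path
#'
#' `lambda_max` is the smallest penalty that zeroes every coefficient for the
#' null-model working response, `max_j |mean(x_j (y - ybar))| / max(alpha,
#' 0.001)` (the 0.001 floor keeps the ridge path finite); the path descends
#' geometrically to `lambda_max * lambda_min_ratio`. When fold assignments
#' are supplied, `lambda_max` is taken over the full data *and* every
#' cross-validation training subset, so the start of the path is the exact
#' null model in every fold fit — without this, fold-level score maxima can
#' exceed the full-data boundary and the "null end" of the CV curve is not
#' actually null.
#'
#' @param X samples x features matrix.
#' @param y 0/1 labels.
#' @param alpha mixing parameter.
#' @param length.out path length.
#' @param lambda_min_ratio ratio of smallest to largest penalty.
#' @param folds optional integer fold assignment per sample.
#' @return decreasing numeric vector of penalties.
#' @export
lambda_path <- function(X, y, alpha, length.out = 100,
                        lambda_min_ratio = 1e-3, folds = NULL) {
  score_max <- function(Xs, ys)
    max(abs(crossprod(Xs, ys - mean(ys)))) / nrow(Xs)
  s <- score_max(X, y)
  if (!is.null(folds)) {
    for (f in unique(folds)) {
      keep <- folds != f
      s <- max(s, score_max(X[keep, , drop = FALSE], y[keep]))
    }
  }
  lambda_max <- s / max(alpha, 1e-3)
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = length.out))
}

#' Fit a binomial elastic-net model at fixed penalty
#'
#' Minimizes `(1/N) * binomial negative log-likelihood +
#' lambda * (alpha ||beta||_1 + (1 - alpha)/2 ||beta||_2^2)` with an
#' unpenalized intercept, by cyclic coordinate descent with soft-thresholding
#' on the iteratively reweighted least-squares quadratic approximation.
#' Inputs are expected to be z-scored already; no internal standardization is
#' performed. Converged when the largest coefficient change across an outer
#' iteration falls below `tol`.
#'
#' @param X samples x features numeric matrix (z-scored columns).
#' @param y numeric 0/1 labels (1 = tumor, the positive class).
#' @param alpha mixing parameter in `[0, 1]`.
#' @param lambda penalty strength (>= 0).
#' @param max_iter,tol outer-loop controls.
#' @param init optional warm start, list with `beta0`, `beta`.
#' @return object of class `elnet_fit`: `beta0`, `beta` (named), `alpha`,
#'   `lambda`, `features`, `converged`, `iterations`.
#' @export
fit_elnet_logistic <- function(X, y, alpha, lambda, max_iter = 100,
                               tol = 1e-7, init = NULL) {
  X <- as.matrix(X)
  assert_that(all(is.finite(X)), "X contains non-finite values")
  y <- as.numeric(y)
  assert_that(all(y %in% c(0, 1)), "y must be 0/1")
  assert_that(length(unique(y)) == 2, "both classes must be present")
  assert_that(alpha >= 0 && alpha <= 1 && lambda >= 0,
              "alpha in [0,1] and lambda >= 0 required")
  n <- nrow(X); p <- ncol(X)
  beta <- if (is.null(init)) numeric(p) else init$beta
  beta0 <- if (is.null(init)) stats::qlogis(mean(y)) else init$beta0
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(beta0 + X %*% beta)
    prob <- stats::plogis(eta)
    w <- pmax(prob * (1 - prob), 1e-5)
    z <- eta + (y - prob) / w
    # covariance-form sufficient statistics of the weighted quadratic
    wX <- w * X
    A <- crossprod(X, wX) / n          # (1/n) X' W X
    bvec <- colSums(wX * z) / n        # (1/n) X' W z
    xw <- colSums(wX) / n
    wz <- sum(w * z) / n
    wbar <- sum(w) / n
    denom <- diag(A) + lambda * (1 - alpha)
    beta_old <- beta; beta0_old <- beta0
    # cyclic coordinate descent with soft-thresholding
    for (inner in seq_len(1000)) {
      delta_max <- 0
      for (j in seq_len(p)) {
        rho <- bvec[j] - sum(A[j, ] * beta) + A[j, j] * beta[j] -
          xw[j] * beta0
        excess <- abs(rho) - lambda * alpha   # scalar soft-threshold
        bj_new <- if (excess > 0) sign(rho) * excess / denom[j] else 0
        if (bj_new != beta[j]) {
          delta_max <- max(delta_max, abs(bj_new - beta[j]))
          beta[j] <- bj_new
        }
      }
      b0_new <- (wz - sum(xw * beta)) / wbar
      if (b0_new != beta0) {
        delta_max <- max(delta_max, abs(b0_new - beta0))
        beta0 <- b0_new
      }
      if (delta_max < tol) break
    }
    if (max(abs(c(beta - beta_old, beta0 - beta0_old))) < tol) {
      converged <- TRUE
      break
    }
  }
  names(beta) <- colnames(X)
  structure(list(beta0 = beta0, beta = beta, alpha = alpha, lambda = lambda,
                 features = colnames(X), converged = converged,
                 iterations = it),
            class = "elnet_fit")
}

#' @export
print.elnet_fit <- function(x, ...) {
  cat(sprintf("elnet_fit: alpha %.2g lambda %.4g, %d/%d nonzero coefficients\n",
              x$alpha, x$lambda, sum(x$beta != 0), length(x$beta)))
  invisible(x)
}

fit_elnet_path <- function(X, y, alpha, lambdas, max_iter = 100, tol = 1e-7) {
  # warm-started descent along the penalty path; once the training deviance
  # is essentially saturated (ratio > 0.999, as in glmnet's devmax stop) the
  # remaining, weaker penalties cannot change the fit meaningfully and the
  # last fit is carried forward
  fits <- vector("list", length(lambdas))
  init <- NULL
  dev_null <- binomial_deviance(rep(mean(y), length(y)), y)
  saturated <- FALSE
  for (i in seq_along(lambdas)) {
    if (saturated) {
      fits[[i]] <- fits[[i - 1]]
      fits[[i]]$lambda <- lambdas[i]
      next
    }
    fits[[i]] <- fit_elnet_logistic(X, y, alpha, lambdas[i],
                                    max_iter = max_iter, tol = tol,
                                    init = init)
    init <- list(beta0 = fits[[i]]$beta0, beta = fits[[i]]$beta)
    prob <- stats::plogis(fits[[i]]$beta0 + drop(X %*% fits[[i]]$beta))
    if (1 - binomial_deviance(prob, y) / dev_null > 0.999) saturated <- TRUE
  }
  fits
}

#' Mean binomial deviance of predicted probabilities
#'
#' `-2/N * sum(y log p + (1-y) log(1-p))`, with probabilities clipped away
#' from 0 and 1 for numerical safety.
#'
#' @param prob predicted probabilities.
#' @param y 0/1 labels.
#' @return non-negative scalar.
#' @export
binomial_deviance <- function(prob, y) {
  prob <- pmin(pmax(prob, 1e-10), 1 - 1e-10)
  -2 * mean(y * log(prob) + (1 - y) * log(1 - prob))
}

make_stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (g in unique(y)) {
      idx <- sample(which(y == g))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Cross-validate the elastic net over a mixing-parameter grid
#'
#' For each alpha, builds a penalty path on the full data and computes the
#' mean and standard error (across stratified, seeded folds) of the held-out
#' binomial deviance along the path; `lambda_min` is the deviance-minimizing
#' penalty and `lambda_1se` the largest penalty whose mean deviance is within
#' one standard error of that minimum. The rule-selected penalty of each
#' alpha is compared across the grid, and the alpha with the smallest
#' rule-selected deviance wins; rule deviances within a small tolerance
#' (`max(0.01 * best, 1e-3)`) of the best are treated as tied, and ties go
#' to the sparser fitted model, then to the larger alpha. The final model is
#' refit on all samples at the chosen `(alpha, lambda)`.
#'
#' @param X samples x features matrix (z-scored columns).
#' @param y 0/1 labels.
#' @param config a [train_config()].
#' @return object of class `cv_elnet`: `fit` (the chosen `elnet_fit`),
#'   `alpha_opt`, `lambda_opt`, `cv_table` (per alpha/lambda mean and se of
#'   deviance), `per_alpha` (lambda_min, lambda_1se, rule deviance, nonzero
#'   count per alpha), `folds`.
#' @export
cv_elnet <- function(X, y, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  X <- as.matrix(X); y <- as.numeric(y)
  # folds cannot outnumber the smaller class in a stratified scheme
  n_folds <- min(config$n_folds, min(table(y)))
  if (n_folds < config$n_folds) {
    message(sprintf("cv_elnet: reducing folds from %d to %d (class size)",
                    config$n_folds, n_folds))
  }
  folds <- make_stratified_folds(y, n_folds, derive_seed(config$seed, 11))
  cv_rows <- list()
  per_alpha <- list()
  for (a in config$alpha_grid) {
    lambdas <- lambda_path(X, y, a, config$lambda_path_length,
                           config$lambda_min_ratio, folds = folds)
    dev_fold <- matrix(NA_real_, nrow = n_folds,
                       ncol = length(lambdas))
    for (f in seq_len(n_folds)) {
      hold <- folds == f
      fits <- fit_elnet_path(X[!hold, , drop = FALSE], y[!hold], a, lambdas,
                             config$max_iter, config$tol)
      dev_fold[f, ] <- vapply(fits, function(fit) {
        prob <- stats::plogis(fit$beta0 +
                                drop(X[hold, , drop = FALSE] %*% fit$beta))
        binomial_deviance(prob, y[hold])
      }, numeric(1))
    }
    cvm <- colMeans(dev_fold)
    cvse <- apply(dev_fold, 2, stats::sd) / sqrt(n_folds)
    i_min <- which.min(cvm)
    within <- which(cvm <= cvm[i_min] + cvse[i_min])
    i_1se <- min(within)                  # lambdas descend: first = largest
    i_rule <- if (config$rule == "lambda_1se") i_1se else i_min
    full_path <- fit_elnet_path(X, y, a, lambdas[seq_len(i_rule)],
                                config$max_iter, config$tol)
    fit_rule <- full_path[[i_rule]]
    cv_rows[[length(cv_rows) + 1]] <-
      data.frame(alpha = a, lambda = lambdas, cvm = cvm, cvse = cvse)
    per_alpha[[length(per_alpha) + 1]] <-
      list(alpha = a, lambda_min = lambdas[i_min],
           lambda_1se = lambdas[i_1se], lambda_rule = lambdas[i_rule],
           deviance_rule = cvm[i_rule], se_rule = cvse[i_rule],
           nonzero = sum(fit_rule$beta != 0), fit = fit_rule)
  }
  dev_rule <- vapply(per_alpha, function(z) z$deviance_rule, numeric(1))
  nz <- vapply(per_alpha, function(z) z$nonzero, numeric(1))
  alphas <- vapply(per_alpha, function(z) z$alpha, numeric(1))
  best <- min(dev_rule)
  tied <- which(dev_rule <= best + max(0.01 * best, 1e-3))
  tied <- tied[order(nz[tied], -alphas[tied])]
  pick <- tied[1]
  chosen <- per_alpha[[pick]]
  structure(list(fit = chosen$fit, alpha_opt = chosen$alpha,
                 lambda_opt = chosen$lambda_rule,
                 cv_table = do.call(rbind, cv_rows),
                 per_alpha = data.frame(
                   alpha = alphas,
                   lambda_min = vapply(per_alpha, function(z) z$lambda_min,
                                       numeric(1)),
                   lambda_1se = vapply(per_alpha, function(z) z$lambda_1se,
                                       numeric(1)),
                   deviance_rule = dev_rule, nonzero = nz),
                 folds = folds),
            class = "cv_elnet")
}

#' @export
print.cv_elnet <- function(x, ...) {
  cat(sprintf("cv_elnet: alpha_opt %.2g, lambda_opt %.4g, %d nonzero\n",
              x$alpha_opt, x$lambda_opt, sum(x$fit$beta != 0)))
  invisible(x)
}

#' Extract the signature of a fitted model
#'
#' Features with non-zero coefficients, ordered by decreasing |beta|, tagged
#' `up` (positive coefficient, higher in tumors) or `down`.
#'
#' @param fit an `elnet_fit`.
#' @return data.frame `feature`, `beta`, `direction` (possibly empty).
#' @export
extract_signature <- function(fit) {
  stopifnot(inherits(fit, "elnet_fit"))
  nz <- fit$beta[fit$beta != 0]
  nz <- nz[order(-abs(nz))]
  data.frame(feature = names(nz), beta = unname(nz),
             direction = ifelse(nz > 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialize a fitted model to JSON
#'
#' @param fit an `elnet_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_elnet_fit <- function(fit, path) {
  stopifnot(inherits(fit, "elnet_fit"))
  jsonlite::write_json(
    list(alpha = fit$alpha, lambda = fit$lambda, beta0 = fit$beta0,
         coefficients = as.list(fit$beta)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
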