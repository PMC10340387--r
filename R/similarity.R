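#' Mean expression profile of a group
#'
#' Arithmetic mean of normalized log2 expression per feature across the
#' samples of one group, the unit compared in the cohort similarity screen.
#'
#' @param m a `normalized_matrix`.
#' @param group group label (`"tumor"` or `"normal"`).
#' @return named numeric vector of per-feature means.
#' @export
mean_profile <- function(m, group = "tumor") {
  stopifnot(inherits(m, "normalized_matrix"))
  sel <- m$meta$group == group
  assert_that(any(sel), paste("no samples in group", group))
  rowMeans(m$values[, sel, drop = FALSE])
}

#' Spearman similarity of two expression profiles
#'
#' Restricts both profiles to their shared feature names, computes the
#' average-rank Spearman correlation and an ordinary least-squares line of
#' `b` on `a` (on the log2 values, as plotted in cross-entity scatterplots).
#'
#' @param a,b named numeric profiles (e.g. from [mean_profile()]).
#' @param label entity label carried into the result.
#' @return list of class `similarity_result`: `entity`, `n_shared`, `rho`,
#'   `slope`, `intercept`, and `degenerate` flag (TRUE when either profile
#'   has zero variance, in which case `rho` is `NA`).
#' @export
spearman_similarity <- function(a, b, label = "candidate") {
  shared <- intersect(names(a), names(b))
  assert_that(length(shared) >= 3, "need at least 3 shared features")
  av <- a[shared]; bv <- b[shared]
  degenerate <- stats::sd(av) == 0 || stats::sd(bv) == 0
  rho <- if (degenerate) NA_real_ else
    stats::cor(av, bv, method = "spearman")
  slope <- if (degenerate) NA_real_ else
    stats::cov(av, bv) / stats::var(av)
  intercept <- if (degenerate) NA_real_ else mean(bv) - slope * mean(av)
  structure(list(entity = label, n_shared = length(shared), rho = rho,
                 slope = slope, intercept = intercept,
                 degenerate = degenerate),
            class = "similarity_result")
}

#' Rank candidate surrogate cohorts by miRNome similarity
#'
#' Compares the rare-tumor mean profile against each candidate tumor profile
#' and orders candidates by decreasing Spearman rho; ties are broken by
#' lexicographic entity label.
#'
#' @param rare_profile named numeric vector (rare-cohort tumor mean profile).
#' @param candidate_profiles named list of candidate profiles.
#' @return data.frame with columns `entity`, `n_shared`, `rho`, `slope`,
#'   `intercept`, ordered best-first.
#' @export
rank_entities <- function(rare_profile, candidate_profiles) {
  assert_that(length(candidate_profiles) >= 1, "no candidates supplied")
  assert_that(!is.null(names(candidate_profiles)),
              "candidate_profiles must be a named list")
  res <- lapply(names(candidate_profiles), function(lab) {
    s <- spearman_similarity(rare_profile, candidate_profiles[[lab]], lab)
    data.frame(entity = s$entity, n_shared = s$n_shared, rho = s$rho,
               slope = s$slope, intercept = s$intercept,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(-out$rho, out$entity), , drop = FALSE]
}
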