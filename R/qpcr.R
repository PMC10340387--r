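#' Assemble a qPCR Cq table
#'
#' Long-format container for quantification-cycle values: one row per
#' (sample, assay), with the assay role (`target` or `reference`) and the
#' sample's experimental group.
#'
#' @param df data.frame with columns `sample`, `group`, `assay`, `role`, `cq`.
#' @return the validated data.frame, class `qpcr_table`.
#' @export
qpcr_table <- function(df) {
  required <- c("sample", "group", "assay", "role", "cq")
  assert_that(all(required %in% names(df)),
              paste("qPCR table needs columns:", paste(required, collapse = ", ")))
  assert_that(all(is.finite(df$cq)), "Cq values must be finite")
  assert_that(all(df$role %in% c("target", "reference")),
              "role must be 'target' or 'reference'")
  structure(df[required], class = c("qpcr_table", "data.frame"))
}

#' geNORM-style reference stability ranking
#'
#' For each candidate reference assay j, the stability value M_j is the mean,
#' over the other candidates k, of the standard deviation across samples of
#' the pairwise difference `Cq_j - Cq_k`. Lower M means more stable; the two
#' lowest-M assays are the recommended reference pair. M is invariant to
#' adding a constant to any one assay.
#'
#' @param tab a [qpcr_table()]; only rows with `role == "reference"` are used.
#' @return data.frame `assay`, `M`, ranked most-stable first.
#' @export
genorm_stability <- function(tab) {
  refs <- tab[tab$role == "reference", , drop = FALSE]
  assays <- unique(refs$assay)
  assert_that(length(assays) >= 2, "need >= 2 candidate reference assays")
  samples <- sort(unique(refs$sample))
  cqm <- matrix(NA_real_, nrow = length(samples), ncol = length(assays),
                dimnames = list(samples, assays))
  cqm[cbind(match(refs$sample, samples), match(refs$assay, assays))] <- refs$cq
  assert_that(!anyNA(cqm), "every reference assay needs a Cq in every sample")
  M <- vapply(seq_along(assays), function(j) {
    mean(vapply(setdiff(seq_along(assays), j), function(k)
      stats::sd(cqm[, j] - cqm[, k]), numeric(1)))
  }, numeric(1))
  out <- data.frame(assay = assays, M = M, stringsAsFactors = FALSE)
  out[order(out$M, out$assay), , drop = FALSE]
}

#' Delta-Cq relative expression
#'
#' For each sample and target assay, `delta_cq = Cq_target - mean(Cq_refs)`
#' (the arithmetic mean of reference Cq values equals the log-scale geometric
#' mean of reference quantities) and relative expression `2^(-delta_cq)`,
#' so lower Cq (more template) gives higher relative expression.
#'
#' @param tab a [qpcr_table()].
#' @param references assay names used as the reference summary.
#' @return data.frame `sample`, `group`, `assay`, `delta_cq`, `rel_expr`.
#' @export
delta_cq <- function(tab, references) {
  assert_that(all(references %in% tab$assay),
              paste("unknown reference assays:",
                    paste(setdiff(references, tab$assay), collapse = ", ")))
  refs <- tab[tab$assay %in% references, , drop = FALSE]
  ref_mean <- tapply(refs$cq, refs$sample, mean)
  targets <- tab[tab$role == "target", , drop = FALSE]
  assert_that(all(targets$sample %in% names(ref_mean)),
              "every sample needs reference Cq values")
  dcq <- targets$cq - as.numeric(ref_mean[targets$sample])
  data.frame(sample = targets$sample, group = targets$group,
             assay = targets$assay, delta_cq = dcq,
             rel_expr = 2^(-dcq), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon test: exact for small tie-free samples,
#' normal approximation with tie correction otherwise.
#'
#' @param a,b numeric vectors.
#' @return list with `U` (Mann-Whitney statistic of `a` vs `b`) and `p`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  assert_that(length(a) >= 1 && length(b) >= 1, "both groups must be non-empty")
  if (all(c(a, b) == c(a, b)[1])) return(list(U = length(a) * length(b) / 2,
                                              p = 1))
  exact <- length(a) <= 12 && length(b) <= 12 &&
    !any(duplicated(c(a, b)))
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Validate signature targets by qPCR
#'
#' Runs the delta-Cq comparison for each target assay: selects the two most
#' stable reference assays by [genorm_stability()], computes per-sample
#' delta-Cq, and tests tumor vs normal with the Wilcoxon rank-sum test. The
#' observed direction is `up` when the mean tumor delta-Cq is lower than the
#' mean control delta-Cq (more template in tumors).
#'
#' @param tab a [qpcr_table()].
#' @param assay_features optional named character vector mapping assay names
#'   to signature feature names (defaults to identity).
#' @return data.frame `assay`, `feature`, `p`, `direction`, `mean_dcq_tumor`,
#'   `mean_dcq_normal`, plus the chosen references as an attribute
#'   `references`.
#' @export
qpcr_validate <- function(tab, assay_features = NULL) {
  stab <- genorm_stability(tab)
  refs <- utils::head(stab$assay, 2)
  dcq <- delta_cq(tab, refs)
  assays <- unique(dcq$assay)
  rows <- lapply(assays, function(a) {
    d <- dcq[dcq$assay == a, ]
    tt <- d$delta_cq[d$group == "tumor"]
    nn <- d$delta_cq[d$group == "normal"]
    w <- wilcoxon_rank_sum(tt, nn)
    data.frame(assay = a,
               feature = if (is.null(assay_features)) a else
                 unname(assay_features[a]),
               p = w$p,
               direction = if (mean(tt) < mean(nn)) "up" else "down",
               mean_dcq_tumor = mean(tt), mean_dcq_normal = mean(nn),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "references") <- refs
  out
}
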