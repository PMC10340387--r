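#!/usr/bin/env Rscript
# PCA stratification of the surrogate cohort: fit an oriented 2-component
# PCA, project the rare cohort into that space, re-anchor Dim2 so the rare
# tumors sit on the retained cluster-I side, and label cluster II
# (Dim2 > 0) for removal.
suppressPackageStartupMessages(library(surrosig))

read_cohort <- function(nm) read_count_matrix(
  file.path("results/cohorts", paste0(nm, "_counts.tsv")),
  file.path("results/cohorts", paste0(nm, "_meta.tsv")))

filtered <- lapply(c(surrogate = "surrogate", rare = "rare"),
                   function(nm) filter_low_counts(read_cohort(nm)))
shared <- intersect(rownames(filtered$surrogate$counts),
                    rownames(filtered$rare$counts))
norm <- lapply(filtered, function(x) {
  x$counts <- x$counts[shared, , drop = FALSE]
  normalize_log2(x)
})

pca <- fit_pca(norm$surrogate, 2)
rare_bc <- batch_center(norm$rare)
rare_centered <- rare_bc$values - rowMeans(rare_bc$values) +
  pca$center[match(rownames(rare_bc$values), pca$features)]
rare_scores <- project_samples(pca, rare_centered)
pca <- anchor_dim2(pca, rare_scores[norm$rare$meta$group == "tumor", ,
                                    drop = FALSE])
rare_scores <- project_samples(pca, rare_centered)

tumors <- norm$surrogate$meta$sample_id[norm$surrogate$meta$group == "tumor"]
clusters <- assign_clusters(pca, pca$scores[tumors, , drop = FALSE])

scores_out <- rbind(
  data.frame(sample = rownames(pca$scores), cohort = "surrogate",
             group = norm$surrogate$meta$group, pca$scores),
  data.frame(sample = rownames(rare_scores), cohort = "rare",
             group = norm$rare$meta$group, rare_scores))
write.table(scores_out, "results/pca_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(clusters, "results/clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Dim1 + Dim2 explain %.0f%% of the variance\n",
            100 * sum(pca$explained)))
print(table(clusters$cluster))
cat(sprintf("rare tumors project to mean Dim1 %.1f (surrogate normals %.1f)\n",
            mean(rare_scores[norm$rare$meta$group == "tumor", 1]),
            mean(pca$scores[norm$surrogate$meta$group == "normal", 1])))
cat("wrote results/pca_scores.tsv and results/clusters.tsv\n")
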