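#!/usr/bin/env Rscript
# Concordance pre-filter: keep miRNAs deregulated by at least 20% in the
# same direction (Welch p < 0.1) in both the stratified surrogate comparison
# (cluster-I tumors vs normals) and the rare comparison (tumors vs controls).
suppressPackageStartupMessages(library(surrosig))

read_cohort <- function(nm) read_count_matrix(
  file.path("results/cohorts", paste0(nm, "_counts.tsv")),
  file.path("results/cohorts", paste0(nm, "_meta.tsv")))

filtered <- lapply(c(surrogate = "surrogate", rare = "rare",
                     exosome = "exosome"),
                   function(nm) filter_low_counts(read_cohort(nm)))
shared <- Reduce(intersect, lapply(filtered, function(x) rownames(x$counts)))
norm <- lapply(filtered, function(x) {
  x$counts <- x$counts[shared, , drop = FALSE]
  normalize_log2(x)
})

clusters <- read.delim("results/clusters.tsv")
keep <- c(clusters$sample[clusters$cluster == "I"],
          norm$surrogate$meta$sample_id[norm$surrogate$meta$group == "normal"])
idx <- match(keep, norm$surrogate$meta$sample_id)
stratified <- norm$surrogate
stratified$values <- stratified$values[, idx]
stratified$meta <- stratified$meta[idx, ]
stratified$size_factors <- stratified$size_factors[idx]

pf <- concordance_prefilter(stratified, norm$rare)
write.table(pf, "results/prefilter.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d of %d shared miRNAs pass the concordance pre-filter\n",
            sum(pf$selected), nrow(pf)))
print(pf[pf$selected, c("feature", "lfc_surrogate", "lfc_rare",
                        "direction")], row.names = FALSE)
cat("wrote results/prefilter.tsv\n")
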