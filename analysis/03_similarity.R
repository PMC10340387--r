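#!/usr/bin/env Rscript
# Surrogate-cohort screen: rank candidate tumor entities by the Spearman
# correlation of their mean miRNA profile with the rare-tumor profile.
# With simulated data there is one genuine surrogate; a label-shuffled
# version of it serves as the negative comparator the screen must rank last.
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

rare_profile <- mean_profile(norm$rare, "tumor")
surrogate_profile <- mean_profile(norm$surrogate, "tumor")
shuffled <- surrogate_profile
set.seed(1)
names(shuffled) <- sample(names(shuffled))

ranking <- rank_entities(rare_profile,
                         list(surrogate = surrogate_profile,
                              shuffled_surrogate = shuffled))
write.table(ranking, "results/similarity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(ranking, row.names = FALSE)
cat(sprintf("best match: %s (rho = %.3f over %d shared miRNAs)\n",
            ranking$entity[1], ranking$rho[1], ranking$n_shared[1]))
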