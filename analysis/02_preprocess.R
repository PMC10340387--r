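#!/usr/bin/env Rscript
# Detection filtering and normalization: discard miRNAs below 10 mean reads
# (n = smallest group), keep the features detected in all three cohorts, and
# normalize each cohort by median-of-ratios size factors + log2.
suppressPackageStartupMessages(library(surrosig))

bundle <- lapply(
  c(surrogate = "surrogate", rare = "rare", exosome = "exosome"),
  function(nm) read_count_matrix(
    file.path("results/cohorts", paste0(nm, "_counts.tsv")),
    file.path("results/cohorts", paste0(nm, "_meta.tsv"))))

filtered <- lapply(bundle, filter_low_counts)
detected <- data.frame(
  dataset = names(filtered),
  n_input = vapply(bundle, function(x) nrow(x$counts), numeric(1)),
  n_detected = vapply(filtered, function(x) nrow(x$counts), numeric(1)))
shared <- Reduce(intersect, lapply(filtered, function(x) rownames(x$counts)))

dir.create("results", showWarnings = FALSE)
write.table(detected, "results/detected_features.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sf <- do.call(rbind, lapply(names(filtered), function(nm) {
  x <- filtered[[nm]]
  x$counts <- x$counts[shared, , drop = FALSE]
  data.frame(dataset = nm, sample = colnames(x$counts),
             size_factor = unname(estimate_size_factors(x)))
}))
write.table(sf, "results/size_factors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(detected, row.names = FALSE)
cat(sprintf("features detected in all three cohorts: %d\n", length(shared)))
cat(sprintf("size factor range: %.2f - %.2f\n",
            min(sf$size_factor), max(sf$size_factor)))
cat("wrote results/detected_features.tsv and results/size_factors.tsv\n")
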