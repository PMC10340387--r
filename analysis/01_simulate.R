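#!/usr/bin/env Rscript
# Simulate the three study cohorts under the default conditions: a large
# surrogate cohort (180 cluster-I + 100 cluster-II tumors, 44 normals), a
# small rare-disease cell cohort (6 tumors, 9 controls) and a shallow
# exosome cohort (7 tumors, 6 controls), with 15 planted signature miRNAs.
suppressPackageStartupMessages(library(surrosig))

seed <- 1
bundle <- generate_cohorts(synthetic_config(seed = seed))
write_cohort_bundle(bundle, "results/cohorts")

cat("cohorts written to results/cohorts\n")
print(bundle)
cat(sprintf("planted up: %s\n", paste(bundle$truth$up, collapse = ", ")))
cat(sprintf("planted down: %s\n", paste(bundle$truth$down, collapse = ", ")))
cat(sprintf("mean library size: surrogate %.2e, rare %.2e, exosome %.2e\n",
            mean(colSums(bundle$surrogate$counts)),
            mean(colSums(bundle$rare$counts)),
            mean(colSums(bundle$exosome$counts))))
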