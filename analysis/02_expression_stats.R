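#!/usr/bin/env Rscript
# Expression-level statistics on the simulated cohort: per-gene one-sample
# t-tests of the log fold change against no tumor-vs-normal difference
# (reported with medians and quartiles on the fold-change scale), all
# pairwise inter-gene Pearson correlations of log expression, and
# gene-vs-phenotype association tests. P-values are raw.
library(gemtree)

cohort <- read_cohort("results/cohort.csv")
es <- expression_stats(cohort)
readr::write_tsv(es$fold_changes, "results/fold_changes.tsv")
readr::write_tsv(es$correlations, "results/correlations.tsv")

cat("fold-change summaries (tumor vs normal):\n")
print(es$fold_changes, digits = 3)
cat("\ninter-gene correlations (log scale):\n")
print(es$correlations, digits = 3)

# example phenotype association: hENT1 by jaundice status
assoc <- phenotype_association(log(cohort$hENT1_fc), cohort$jaundice)
cat(sprintf("\nhENT1 (log) by jaundice: t = %.3f, p = %.3f\n",
            assoc$statistic, assoc$p_value))
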