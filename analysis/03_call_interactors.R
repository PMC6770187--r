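#!/usr/bin/env Rscript
# Runs the combined decision rule (SAM-type weight, one-tailed Welch
# t-test, fold change, WT-only rescue) over the quantified matrices and
# scores the calls against the simulation's ground truth.

library(apmscall)

raw <- read_count_matrix("results/quantification/counts_raw.tsv",
                         "results/quantification/groups.tsv")
nsc <- read_count_matrix("results/quantification/counts_normalized.tsv",
                         "results/quantification/groups.tsv",
                         normalized = TRUE)
truth <- read.delim("results/fixture/truth.tsv")

calls <- call_interactors(raw, nsc)
hits <- calls[calls$verdict == "hit", ]
write.table(calls, "results/decisions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(hits, "results/hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d hits out of %d proteins tested (%d statistical, %d rescue)\n",
            nrow(hits), nrow(calls), sum(hits$path == "statistical"),
            sum(hits$path == "rescue")))

lab <- setNames(truth$label, truth$protein)
tp <- sum(lab[hits$protein] != "background")
fp <- sum(lab[hits$protein] == "background")
n_true <- sum(lab != "background")
cat(sprintf("vs truth: sensitivity %.2f (%d/%d), false-discovery proportion %.3f (%d/%d)\n",
            tp / n_true, tp, n_true, fp / max(1, nrow(hits)), fp,
            nrow(hits)))
cat("top hits by weight:\n")
print(utils::head(hits[, c("protein", "W", "p_value", "fold_change",
                           "path")]), row.names = FALSE)
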