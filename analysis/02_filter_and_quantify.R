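#!/usr/bin/env Rscript
# Applies the evidence filters to the simulated PSM table, groups peptides
# to proteins, checks the aggregate identification FDR, tallies spectral
# counts and normalizes them between samples. Writes the raw and
# normalized matrices under results/quantification/.

library(apmscall)

dir.create("results/quantification", recursive = TRUE,
           showWarnings = FALSE)
psms <- read_psm_table("results/fixture/psms.tsv")
groups <- read_group_map("results/fixture/groups.tsv")
th <- filter_thresholds()

kept <- filter_psms(psms, th)
cat(sprintf("peptide filter: %d -> %d PSMs (%.1f%% removed)\n",
            nrow(psms), nrow(kept),
            100 * (1 - nrow(kept) / nrow(psms))))

prots <- group_to_proteins(kept, th)
cat(sprintf("protein grouping: %d -> %d proteins\n",
            length(unique(kept$protein_accession)), nrow(prots)))

fdr <- estimate_fdr(prots)
cat(sprintf("aggregate FDR estimate: %.4f (must stay below %.2f): %s\n",
            fdr, th$max_fdr, if (fdr < th$max_fdr) "ok" else "FAILED"))

kept <- kept[kept$protein_accession %in% prots$protein, ]
raw <- compute_spectral_counts(kept, groups)
nsc <- normalize_counts(raw)
write_count_matrix(raw, "results/quantification/counts_raw.tsv",
                   "results/quantification/groups.tsv")
write_count_matrix(nsc, "results/quantification/counts_normalized.tsv")
cat(sprintf("spectral counts: %d proteins x %d samples; totals %s -> all %.1f\n",
            nrow(raw$counts), ncol(raw$counts),
            paste(colSums(raw$counts), collapse = "/"),
            mean(colSums(raw$counts))))
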