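#' Run the full interactor-calling pipeline
#'
#' Orchestrates evidence filtering, protein grouping, spectral counting,
#' normalization and interactor calling, writing every intermediate table
#' plus a JSON run report. The quantitative input is either a PSM table
#' (which is filtered and tallied) or a pre-aggregated raw count matrix —
#' exactly one of the two.
#'
#' @param psm_file PSM table TSV (see [write_psm_table()] for the schema),
#'   or NULL.
#' @param counts_file raw count-matrix TSV, or NULL.
#' @param groups_file two-column TSV mapping sample_id to WT/EV.
#' @param out_dir output directory, created if needed.
#' @param filters a [filter_thresholds()].
#' @param decisions a [decision_thresholds()].
#' @param fasta_file optional two-record ortholog FASTA; when given
#'   together with \code{peptides_file}, a species-call table is written.
#' @param peptides_file optional one-peptide-per-line text file.
#' @param overlap_file optional gene case-count TSV; when given, the
#'   overlap percentage table is written.
#' @param quiet suppress per-stage log messages.
#' @return (invisibly) the run report: a list of per-stage counts, the
#'   thresholds used, and the output paths. Also written as
#'   \code{run_report.json}.
#' @export
run_pipeline <- function(psm_file = NULL, counts_file = NULL, groups_file,
                         out_dir, filters = filter_thresholds(),
                         decisions = decision_thresholds(),
                         fasta_file = NULL, peptides_file = NULL,
                         overlap_file = NULL, quiet = FALSE) {
  if (is.null(psm_file) == is.null(counts_file))
    stop("supply exactly one of `psm_file` or `counts_file`",
         call. = FALSE)
  stopifnot(inherits(filters, "filter_thresholds"),
            inherits(decisions, "decision_thresholds"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  report <- list(stages = list(),
                 filter_thresholds = unclass(filters),
                 decision_thresholds = unclass(decisions))

  group_map <- read_group_map(groups_file)

  if (!is.null(psm_file)) {
    psms <- read_psm_table(psm_file)
    report$stages$n_psms_input <- nrow(psms)
    kept <- filter_psms(psms, filters)
    report$stages$n_psms_filtered <- nrow(kept)
    log_stage("filter_psms: %d -> %d PSMs", nrow(psms), nrow(kept))

    prots <- group_to_proteins(kept, filters)
    report$stages$n_proteins_input <-
      length(unique(kept$protein_accession))
    report$stages$n_proteins_retained <- nrow(prots)
    log_stage("group_to_proteins: %d -> %d proteins",
              report$stages$n_proteins_input, nrow(prots))

    if (nrow(prots) > 0) {
      fdr <- estimate_fdr(prots)
      report$stages$fdr_estimate <- fdr
      report$stages$fdr_pass <- fdr < filters$max_fdr
      if (!report$stages$fdr_pass)
        warning(sprintf("aggregate FDR %.4f not below %.4f", fdr,
                        filters$max_fdr), call. = FALSE)
      log_stage("estimate_fdr: %.4f (max %.4f)", fdr, filters$max_fdr)
    }

    kept <- kept[kept$protein_accession %in% prots$protein, ,
                 drop = FALSE]
    write_psm_table(kept, file.path(out_dir, "filtered_psms.tsv"))
    raw <- compute_spectral_counts(kept, group_map)
  } else {
    raw <- read_count_matrix(counts_file, groups_file)
    report$stages$n_proteins_input <- nrow(raw$counts)
  }
  report$stages$n_proteins_quantified <- nrow(raw$counts)
  log_stage("spectral counts: %d proteins x %d samples",
            nrow(raw$counts), ncol(raw$counts))

  nsc <- normalize_counts(raw)
  write_count_matrix(raw, file.path(out_dir, "counts_raw.tsv"),
                     file.path(out_dir, "groups.tsv"))
  write_count_matrix(nsc, file.path(out_dir, "counts_normalized.tsv"))

  calls <- call_interactors(raw, nsc, decisions)
  hits <- calls[calls$verdict == "hit", , drop = FALSE]
  report$stages$n_hits <- nrow(hits)
  report$stages$n_hits_statistical <- sum(hits$path == "statistical")
  report$stages$n_hits_rescue <- sum(hits$path == "rescue")
  log_stage("call_interactors: %d hits (%d statistical, %d rescue)",
            nrow(hits), report$stages$n_hits_statistical,
            report$stages$n_hits_rescue)
  write_decisions(calls, file.path(out_dir, "decisions.tsv"))
  write_decisions(hits, file.path(out_dir, "hits.tsv"))

  if (!is.null(fasta_file) && !is.null(peptides_file)) {
    pair <- read_ortholog_pair(fasta_file)
    peps <- readLines(peptides_file)
    peps <- peps[nzchar(peps)]
    sp <- assign_species_table(peps, pair)
    utils::write.table(sp, file.path(out_dir, "species_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$n_species_calls <- nrow(sp)
    log_stage("assign_species: %d peptides", nrow(sp))
  }
  if (!is.null(overlap_file)) {
    ov <- overlap_table(read_overlap_table(overlap_file))
    utils::write.table(ov, file.path(out_dir, "overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$n_overlap_genes <- nrow(ov)
    log_stage("overlap_table: %d genes", nrow(ov))
  }

  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

# Decision tables are written with fixed significant digits so that
# equal-seed runs are byte-identical across platforms.
write_decisions <- function(calls, file) {
  out <- calls
  for (col in c("W", "p_value", "fold_change"))
    out[[col]] <- trimws(formatC(out[[col]], digits = 10, format = "g"))
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(calls)
}

#' Generate a complete seeded demo dataset on disk
#'
#' Writes everything an end-to-end run needs: the simulated PSM table,
#' ground-truth raw count matrix, group map, truth table, a synthetic
#' two-species ortholog FASTA with a single planted discriminating site
#' (threonine in species A encoded by alanine in species B), a peptide list
#' probing that site, and the published case-overlap fixture.
#'
#' @param config a [sim_config()]; its seed drives every file.
#' @param out_dir output directory, created if needed.
#' @param ortholog_length length of the synthetic ortholog sequences
#'   (default 2818, mimicking full-length neurofibromin).
#' @param site_position ungapped position of the planted T/A mismatch
#'   (default 2489).
#' @return (invisibly) named character vector of the files written.
#' @export
generate_fixture <- function(config = sim_config(), out_dir,
                             ortholog_length = 2818L,
                             site_position = 2489L) {
  stopifnot(inherits(config, "sim_config"),
            site_position >= 1, site_position <= ortholog_length)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_psm_table(config)

  files <- c(psms = file.path(out_dir, "psms.tsv"),
             counts = file.path(out_dir, "counts_truth.tsv"),
             groups = file.path(out_dir, "groups.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             fasta = file.path(out_dir, "ortholog_pair.fa"),
             peptides = file.path(out_dir, "peptides.txt"),
             overlap = file.path(out_dir, "overlap.tsv"))
  write_psm_table(sim$psms, files["psms"])
  write_count_matrix(sim$matrix, files["counts"], files["groups"])
  utils::write.table(sim$truth, files["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # ortholog pair: same random backbone, one planted T<->A substitution
  aa <- strsplit("ACDEFGHIKMNPQRSTVWY", "")[[1]]  # L excluded: I/L collapse
  backbone <- sample(aa, ortholog_length, replace = TRUE)
  seq_a <- seq_b <- backbone
  seq_a[site_position] <- "T"
  seq_b[site_position] <- "A"
  seqs <- Biostrings::AAStringSet(c(
    species_a_synthetic = paste(seq_a, collapse = ""),
    species_b_synthetic = paste(seq_b, collapse = "")))
  Biostrings::writeXStringSet(seqs, files["fasta"], width = 60)

  # peptides: tryptic-sized windows, some covering the site, some not
  win <- function(s, from, len) substr(s, from, from + len - 1)
  sa <- paste(seq_a, collapse = "")
  sb <- paste(seq_b, collapse = "")
  peps <- c(win(sa, site_position - 4, 9),   # covers site, species A
            win(sb, site_position - 4, 9),   # covers site, species B
            win(sa, 101, 12),                # conserved -> ambiguous
            paste(sample(aa, 10, replace = TRUE), collapse = ""))
  writeLines(peps, files["peptides"])

  file.copy(system.file("extdata", "table1_overlaps.tsv",
                        package = "apmscall", mustWork = TRUE),
            files["overlap"], overwrite = TRUE)
  invisible(files)
}
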