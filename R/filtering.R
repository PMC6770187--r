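#' Evidence-filter thresholds
#'
#' Scaffold-style identification cutoffs applied before quantification.
#' All probability and length cutoffs are strict ("greater than")
#' inequalities; the peptides-per-protein requirement is "at least".
#'
#' @param min_peptide_length_exclusive retain peptides strictly longer than
#'   this (default 5, i.e. length > 5 residues).
#' @param excluded_charge precursor charge state removed outright (default
#'   1, the singly-protonated MH+1 ions).
#' @param min_peptide_probability retain PSMs with peptide probability
#'   strictly above this (default 0.80).
#' @param min_peptides_per_protein minimum number of distinct peptide
#'   sequences per protein, pooled across samples (default 2).
#' @param min_protein_probability retain proteins with probability strictly
#'   above this (default 0.99).
#' @param max_fdr aggregate false-discovery-rate bound the retained set must
#'   stay strictly below (default 0.01).
#' @return validated list of class \code{filter_thresholds}.
#' @export
filter_thresholds <- function(min_peptide_length_exclusive = 5L,
                              excluded_charge = 1L,
                              min_peptide_probability = 0.80,
                              min_peptides_per_protein = 2L,
                              min_protein_probability = 0.99,
                              max_fdr = 0.01) {
  th <- list(min_peptide_length_exclusive =
               as.integer(min_peptide_length_exclusive),
             excluded_charge = as.integer(excluded_charge),
             min_peptide_probability = min_peptide_probability,
             min_peptides_per_protein = as.integer(min_peptides_per_protein),
             min_protein_probability = min_protein_probability,
             max_fdr = max_fdr)
  if (th$min_peptide_length_exclusive < 0 || th$excluded_charge < 1 ||
      th$min_peptides_per_protein < 1)
    stop("invalid filter threshold", call. = FALSE)
  for (f in c("min_peptide_probability", "min_protein_probability",
              "max_fdr"))
    if (th[[f]] < 0 || th[[f]] > 1)
      stop(sprintf("invalid filter threshold `%s`", f), call. = FALSE)
  class(th) <- "filter_thresholds"
  th
}

validate_psms <- function(psms) {
  need <- c("peptide_sequence", "charge", "peptide_probability",
            "protein_accession", "protein_probability", "sample_id")
  miss <- setdiff(need, names(psms))
  if (length(miss))
    stop("PSM table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_seq <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", psms$peptide_sequence) |
    !nzchar(psms$peptide_sequence)
  if (any(bad_seq))
    stop("malformed peptide sequence at row ", which(bad_seq)[1],
         call. = FALSE)
  for (col in c("peptide_probability", "protein_probability")) {
    bad <- is.na(psms[[col]]) | psms[[col]] < 0 | psms[[col]] > 1
    if (any(bad))
      stop(sprintf("%s out of [0,1] at row %d", col, which(bad)[1]),
           call. = FALSE)
  }
  invisible(psms)
}

#' Filter PSMs on peptide-level evidence
#'
#' Retains exactly the rows with peptide length strictly greater than the
#' length cutoff, charge different from the excluded charge state, and
#' peptide probability strictly greater than the probability cutoff. Row
#' order is preserved.
#'
#' @param psms data frame of PSM records (see [simulate_psm_table()] for
#'   the column contract).
#' @param thresholds a [filter_thresholds()].
#' @return the retained subset of \code{psms}.
#' @export
filter_psms <- function(psms, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  validate_psms(psms)
  keep <- nchar(psms$peptide_sequence) >
            thresholds$min_peptide_length_exclusive &
          psms$charge != thresholds$excluded_charge &
          psms$peptide_probability > thresholds$min_peptide_probability
  psms[keep, , drop = FALSE]
}

#' Group filtered PSMs to proteins
#'
#' Pools distinct peptide sequences per protein accession across all
#' samples and retains proteins with at least
#' \code{min_peptides_per_protein} distinct peptides and protein
#' probability strictly above \code{min_protein_probability}.
#'
#' @inheritParams filter_psms
#' @return data frame with one row per retained protein: \code{protein},
#'   \code{n_distinct_peptides}, \code{n_psms}, \code{protein_probability},
#'   sorted by protein id.
#' @export
group_to_proteins <- function(psms, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (nrow(psms) == 0)
    return(data.frame(protein = character(),
                      n_distinct_peptides = integer(), n_psms = integer(),
                      protein_probability = numeric(),
                      stringsAsFactors = FALSE))
  pp <- tapply(psms$protein_probability, psms$protein_accession,
               function(v) unique(v))
  conflict <- vapply(pp, length, integer(1)) > 1
  if (any(conflict))
    stop("conflicting protein_probability for accession ",
         names(pp)[conflict][1], call. = FALSE)
  npep <- tapply(psms$peptide_sequence, psms$protein_accession,
                 function(v) length(unique(v)))
  npsm <- tapply(psms$peptide_sequence, psms$protein_accession, length)
  prot <- sort(names(npep))
  out <- data.frame(protein = prot,
                    n_distinct_peptides = as.integer(npep[prot]),
                    n_psms = as.integer(npsm[prot]),
                    protein_probability = as.numeric(unlist(pp[prot])),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[out$n_distinct_peptides >= thresholds$min_peptides_per_protein &
      out$protein_probability > thresholds$min_protein_probability, ,
      drop = FALSE]
}

#' Aggregate identification FDR of a retained protein set
#'
#' Estimates the expected fraction of false identifications as the mean
#' probability complement, \code{mean(1 - protein_probability)}, over the
#' retained proteins. This is a sanity check on the retained list as a
#' whole (compared strictly against \code{max_fdr}), not a per-protein
#' filter.
#'
#' @param proteins protein evidence table from [group_to_proteins()].
#' @return the estimated FDR, a fraction in [0, 1].
#' @export
estimate_fdr <- function(proteins) {
  if (nrow(proteins) == 0)
    stop("FDR undefined for an empty protein table", call. = FALSE)
  mean(1 - proteins$protein_probability)
}

#' Tally retained PSMs into a raw spectral-count matrix
#'
#' \code{counts[p, s]} is the number of retained PSM rows for protein p in
#' sample s. Every sample in the group map appears as a column even if it
#' has no retained PSMs.
#'
#' @param psms filtered (and protein-grouped) PSM table.
#' @param group_map named character vector sample id -> "WT"/"EV".
#' @return a raw [count_matrix()].
#' @export
compute_spectral_counts <- function(psms, group_map) {
  unknown <- setdiff(unique(psms$sample_id), names(group_map))
  if (length(unknown))
    stop("sample(s) missing from group map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  proteins <- sort(unique(psms$protein_accession))
  samples <- names(group_map)
  m <- matrix(0L, nrow = length(proteins), ncol = length(samples),
              dimnames = list(proteins, samples))
  if (nrow(psms) > 0) {
    tab <- table(factor(psms$protein_accession, levels = proteins),
                 factor(psms$sample_id, levels = samples))
    m[] <- as.integer(tab)
  }
  count_matrix(m, group_map, normalized = FALSE)
}

#' Normalize spectral counts between samples
#'
#' Total-count scaling: every sample's column is multiplied by (mean of all
#' per-sample raw totals) / (that sample's raw total), so all per-sample
#' totals become equal and the grand total is preserved. A sample whose raw
#' total is zero is left unscaled, with a warning. The operation is
#' idempotent when no column total is zero.
#'
#' @param x a raw [count_matrix()].
#' @return a [count_matrix()] with the \code{normalized} flag set.
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  storage.mode(m) <- "double"
  if (ncol(m) > 0) {
    totals <- colSums(m)
    target <- mean(totals)
    fac <- ifelse(totals > 0, target / totals, 1)
    if (any(totals == 0))
      warning("sample(s) with zero total left unscaled: ",
              paste(colnames(m)[totals == 0], collapse = ", "),
              call. = FALSE)
    m <- sweep(m, 2, fac, `*`)
  }
  count_matrix(m, x$groups, normalized = TRUE)
}
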