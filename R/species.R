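#' Globally align two ortholog protein sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and linear
#' gap penalty -2, with deterministic tie-breaking (diagonal over up over
#' left). High-identity ortholog pairs such as human and mouse
#' neurofibromin align essentially gap-free, which is what the downstream
#' discriminating-site logic relies on.
#'
#' @param sequence_a,sequence_b nonempty amino-acid strings over the 20
#'   standard residues.
#' @param label_a,label_b species labels attached to the pair.
#' @return object of class \code{ortholog_pair}: labels, the input
#'   sequences, the two gapped aligned strings (equal length) and the
#'   alignment \code{score}.
#' @export
align_orthologs <- function(sequence_a, sequence_b,
                            label_a = "species_a", label_b = "species_b") {
  for (s in list(sequence_a, sequence_b)) {
    if (!is.character(s) || length(s) != 1 || !nzchar(s))
      stop("sequences must be nonempty strings", call. = FALSE)
    if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", s))
      stop("sequence contains a non-amino-acid character", call. = FALSE)
  }
  aln <- nw_align_cpp(sequence_a, sequence_b,
                      match = 1L, mismatch = -1L, gap = -2L)
  structure(list(label_a = label_a, label_b = label_b,
                 sequence_a = sequence_a, sequence_b = sequence_b,
                 aligned_a = aln$aligned_a, aligned_b = aln$aligned_b,
                 score = aln$score),
            class = "ortholog_pair")
}

#' @export
print.ortholog_pair <- function(x, ...) {
  cat(sprintf("ortholog_pair: %s (%d aa) vs %s (%d aa), score %d, %d columns\n",
              x$label_a, nchar(x$sequence_a), x$label_b,
              nchar(x$sequence_b), x$score, nchar(x$aligned_a)))
  invisible(x)
}

collapse_il <- function(s) chartr("L", "I", s)

#' Discriminating sites between two aligned orthologs
#'
#' Lists every alignment column whose residues differ between the two
#' sequences — the positions that make a peptide species-specific. Because
#' mass spectrometry cannot distinguish isoleucine from leucine, I and L
#' are treated as identical by default. Positions are reported 1-based in
#' both alignment-column space and each ungapped protein's own coordinate
#' space (the convention in which the human neurofibromin site is written
#' T2489); a gap is reported as residue \code{"-"} with position \code{NA}.
#'
#' @param pair an [align_orthologs()] result.
#' @param il_equivalent treat I and L as the same residue (default TRUE).
#' @return data frame with columns \code{column}, \code{pos_a},
#'   \code{pos_b}, \code{residue_a}, \code{residue_b}, sorted by column.
#' @export
find_discriminating_sites <- function(pair, il_equivalent = TRUE) {
  stopifnot(inherits(pair, "ortholog_pair"))
  ca <- strsplit(pair$aligned_a, "")[[1]]
  cb <- strsplit(pair$aligned_b, "")[[1]]
  ea <- if (il_equivalent) chartr("L", "I", ca) else ca
  eb <- if (il_equivalent) chartr("L", "I", cb) else cb
  diff <- which(ea != eb)
  pos_a <- cumsum(ca != "-")
  pos_b <- cumsum(cb != "-")
  data.frame(column = diff,
             pos_a = ifelse(ca[diff] == "-", NA_integer_, pos_a[diff]),
             pos_b = ifelse(cb[diff] == "-", NA_integer_, pos_b[diff]),
             residue_a = ca[diff], residue_b = cb[diff],
             stringsAsFactors = FALSE)
}

#' Assign a peptide to one of two ortholog species
#'
#' Exact substring matching of the peptide against each ungapped ortholog
#' sequence (with I/L collapsed when \code{il_equivalent}). A peptide found
#' in only one sequence is species-specific — necessarily because its span
#' covers at least one discriminating site; one found in both is
#' \code{ambiguous}; one found in neither is \code{unmatched}.
#'
#' @param peptide amino-acid string of length >= 6 (the minimum surviving
#'   the evidence length filter).
#' @inheritParams find_discriminating_sites
#' @return object of class \code{species_call}: the \code{peptide}, a
#'   \code{verdict} in \code{species_a}/\code{species_b}/\code{ambiguous}/
#'   \code{unmatched} and \code{match_positions}, a data frame of
#'   (sequence, start) for every occurrence.
#' @export
assign_species <- function(peptide, pair, il_equivalent = TRUE) {
  stopifnot(inherits(pair, "ortholog_pair"))
  if (!is.character(peptide) || length(peptide) != 1 || nchar(peptide) < 6)
    stop("peptide must be a single string of length >= 6", call. = FALSE)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", peptide))
    stop("peptide contains a non-amino-acid character", call. = FALSE)
  pep <- if (il_equivalent) collapse_il(peptide) else peptide
  sa <- if (il_equivalent) collapse_il(pair$sequence_a) else pair$sequence_a
  sb <- if (il_equivalent) collapse_il(pair$sequence_b) else pair$sequence_b
  starts <- function(seq) {
    hit <- gregexpr(pep, seq, fixed = TRUE)[[1]]
    if (hit[1] == -1) integer(0) else as.integer(hit)
  }
  st_a <- starts(sa)
  st_b <- starts(sb)
  verdict <- if (length(st_a) && length(st_b)) "ambiguous"
  else if (length(st_a)) "species_a"
  else if (length(st_b)) "species_b"
  else "unmatched"
  structure(list(
    peptide = peptide, verdict = verdict,
    match_positions = data.frame(
      sequence = rep(c("a", "b"), c(length(st_a), length(st_b))),
      start = c(st_a, st_b), stringsAsFactors = FALSE)),
    class = "species_call")
}

#' @export
print.species_call <- function(x, ...) {
  cat(sprintf("species_call: %s -> %s (%d match(es))\n",
              x$peptide, x$verdict, nrow(x$match_positions)))
  invisible(x)
}

#' Species calls for a set of peptides, as a table
#'
#' @param peptides character vector of peptides (length >= 6 each).
#' @inheritParams assign_species
#' @return data frame with columns \code{peptide}, \code{verdict},
#'   \code{n_matches_a}, \code{n_matches_b}.
#' @export
assign_species_table <- function(peptides, pair, il_equivalent = TRUE) {
  calls <- lapply(peptides, assign_species, pair = pair,
                  il_equivalent = il_equivalent)
  data.frame(
    peptide = peptides,
    verdict = vapply(calls, `[[`, character(1), "verdict"),
    n_matches_a = vapply(calls, function(c)
      sum(c$match_positions$sequence == "a"), integer(1)),
    n_matches_b = vapply(calls, function(c)
      sum(c$match_positions$sequence == "b"), integer(1)),
    stringsAsFactors = FALSE)
}

#' Read an ortholog pair from a two-record FASTA and align it
#'
#' @param fasta_file path to a FASTA file with exactly two amino-acid
#'   records; the first is taken as species A.
#' @return an [align_orthologs()] result labelled with the FASTA record
#'   names.
#' @export
read_ortholog_pair <- function(fasta_file) {
  seqs <- Biostrings::readAAStringSet(fasta_file)
  if (length(seqs) != 2)
    stop("expected exactly 2 FASTA records, found ", length(seqs),
         call. = FALSE)
  align_orthologs(as.character(seqs[[1]]), as.character(seqs[[2]]),
                  label_a = names(seqs)[1], label_b = names(seqs)[2])
}
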