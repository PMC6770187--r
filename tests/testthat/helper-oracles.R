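# Independent straight-line oracles used by the property and acceptance
# tests. These deliberately avoid the package's own code paths: the p-value
# comes from stats::t.test, the weight and fold change from the raw
# formulas, and tallies/alignments from naive loops.

oracle_welch_p <- function(wt, ev) {
  if (stats::var(wt) == 0 && stats::var(ev) == 0) return(NA_real_)
  stats::t.test(wt, ev, alternative = "greater",
                var.equal = FALSE)$p.value
}

# verdict for a single protein under the combined rule
oracle_verdict <- function(nwt, nev, rwt, rev,
                           sam_cutoff = 0.6, p_cutoff = 0.1,
                           fold_cutoff = 2, rescue_min = 4,
                           eps = 1e-12) {
  m1 <- mean(nwt); m2 <- mean(nev)
  s1 <- stats::sd(nwt); s2 <- stats::sd(nev)
  den <- s1 - s2
  W <- if (abs(den) < eps) {
    if (abs(m1 - m2) < eps) 0 else sign(m1 - m2) * Inf
  } else (m1 - m2) / den
  p <- oracle_welch_p(nwt, nev)
  fc <- if (m2 > 0) m1 / m2 else NA_real_
  stats_pass <- abs(W) > sam_cutoff && !is.na(p) && p < p_cutoff &&
    !is.na(fc) && fc >= fold_cutoff
  rescue_pass <- all(rev == 0) && sum(rwt) >= rescue_min
  if (stats_pass || rescue_pass) "hit" else "non_hit"
}

# naive per-(protein, sample) PSM tally using an explicit loop
oracle_tally <- function(psms, proteins, samples) {
  m <- matrix(0L, length(proteins), length(samples),
              dimnames = list(proteins, samples))
  for (r in seq_len(nrow(psms))) {
    p <- psms$protein_accession[r]
    s <- psms$sample_id[r]
    m[p, s] <- m[p, s] + 1L
  }
  m
}

# brute-force global-alignment score by top-down dynamic programming,
# written independently of the compiled implementation
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == 0) j * gap
    else if (j == 0) i * gap
    else max(rec(i - 1, j - 1) + if (a[i] == b[j]) match else mismatch,
             rec(i - 1, j) + gap,
             rec(i, j - 1) + gap)
    memo[[key]] <- v
    v
  }
  rec(length(a), length(b))
}

# small random raw/normalized matrix pair for decision-rule properties
random_matrix_pair <- function(n_prot = 10, lambda = 4) {
  m <- matrix(stats::rpois(n_prot * 8, lambda), nrow = n_prot,
              dimnames = list(sprintf("P%02d", seq_len(n_prot)),
                              c(paste0("WT_", 1:4), paste0("EV_", 1:4))))
  storage.mode(m) <- "integer"
  groups <- stats::setNames(rep(c("WT", "EV"), each = 4), colnames(m))
  raw <- count_matrix(m, groups)
  list(raw = raw, norm = suppressWarnings(normalize_counts(raw)))
}

random_aa <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                               "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
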