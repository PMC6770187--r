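mk_psm <- function(peptide = "PEPTIDES", charge = 2L, pprob = 0.9,
                   protein = "P1", protprob = 0.995, sample = "s1") {
  data.frame(peptide_sequence = peptide, charge = charge,
             peptide_probability = pprob, protein_accession = protein,
             protein_probability = protprob, sample_id = sample,
             stringsAsFactors = FALSE)
}

test_that("peptide-level boundaries are strict as specified", {
  th <- filter_thresholds()
  expect_equal(nrow(filter_psms(mk_psm("PEPTI"), th)), 0)     # length 5
  expect_equal(nrow(filter_psms(mk_psm("PEPTID"), th)), 1)    # length 6
  expect_equal(nrow(filter_psms(mk_psm(charge = 1L), th)), 0) # MH+1
  expect_equal(nrow(filter_psms(mk_psm(pprob = 0.80), th)), 0)
  expect_equal(nrow(filter_psms(mk_psm(pprob = 0.81), th)), 1)
  empty <- mk_psm()[0, ]
  expect_equal(nrow(filter_psms(empty, th)), 0)
})

test_that("filtering preserves row order and flags malformed records", {
  psms <- rbind(mk_psm("AAAAAAA", sample = "s1"),
                mk_psm("PEPTI"),
                mk_psm("CCCCCCC", sample = "s2"))
  out <- filter_psms(psms)
  expect_identical(out$peptide_sequence, c("AAAAAAA", "CCCCCCC"))
  expect_error(filter_psms(rbind(mk_psm(), mk_psm("PEpTIDE"))), "row 2")
  expect_error(filter_psms(mk_psm(pprob = 1.5)), "row 1")
})

test_that("protein grouping needs distinct peptides and strict probability", {
  th <- filter_thresholds()
  # one distinct peptide seen in 10 PSMs: rejected
  many <- do.call(rbind, replicate(10, mk_psm("AAAAAAA"), simplify = FALSE))
  expect_equal(nrow(group_to_proteins(many, th)), 0)
  # two distinct peptides at probability 0.995: retained
  two <- rbind(mk_psm("AAAAAAA"), mk_psm("CCCCCCC"))
  got <- group_to_proteins(two, th)
  expect_equal(got$protein, "P1")
  expect_equal(got$n_distinct_peptides, 2L)
  # probability exactly at the cutoff fails the strict > comparison
  at <- rbind(mk_psm("AAAAAAA", protprob = 0.99),
              mk_psm("CCCCCCC", protprob = 0.99))
  expect_equal(nrow(group_to_proteins(at, th)), 0)
  expect_equal(nrow(group_to_proteins(mk_psm()[0, ], th)), 0)
})

test_that("conflicting protein probabilities are an error", {
  bad <- rbind(mk_psm("AAAAAAA", protprob = 0.995),
               mk_psm("CCCCCCC", protprob = 0.999))
  expect_error(group_to_proteins(bad), "conflicting")
})

test_that("aggregate FDR is the mean probability complement", {
  tbl <- function(p) data.frame(protein = sprintf("P%d", seq_along(p)),
                                protein_probability = p)
  expect_equal(estimate_fdr(tbl(c(1, 1, 1))), 0)
  expect_equal(estimate_fdr(tbl(c(0.99, 0.995))), 0.0075)
  # all at 0.99 estimates exactly 0.01, which fails the strict < check
  fdr <- estimate_fdr(tbl(rep(0.99, 5)))
  expect_equal(fdr, 0.01)
  expect_false(fdr < filter_thresholds()$max_fdr)
  expect_error(estimate_fdr(tbl(numeric())), "empty")
})

test_that("spectral counts tally retained PSMs per protein and sample", {
  gm <- c(s1 = "WT", s2 = "EV")
  psms <- rbind(mk_psm("AAAAAAA"), mk_psm("AAAAAAA"), mk_psm("CCCCCCC"),
                mk_psm("DDDDDDD", protein = "P2", sample = "s2"))
  m <- compute_spectral_counts(psms, gm)
  expect_equal(m$counts["P1", "s1"], 3L)
  expect_equal(m$counts["P1", "s2"], 0L)  # absent in a sample -> 0
  expect_equal(m$counts["P2", "s2"], 1L)
  expect_false(m$normalized)
  expect_error(compute_spectral_counts(mk_psm(sample = "s9"), gm),
               "s9")
})

test_that("tallies agree with a naive loop on simulated evidence", {
  sim <- simulate_psm_table(sim_config(n_background = 15, n_true = 5,
                                       seed = 21))
  gm <- sim$matrix$groups
  got <- compute_spectral_counts(sim$psms, gm)
  expect_identical(got$counts,
                   oracle_tally(sim$psms, rownames(got$counts),
                                names(gm)))
})

test_that("normalization equalizes totals and preserves the grand total", {
  m <- matrix(c(40, 60, 150, 50), 2,
              dimnames = list(c("P1", "P2"), c("s1", "s2")))
  storage.mode(m) <- "integer"
  x <- count_matrix(m, c(s1 = "WT", s2 = "EV"))
  nm <- normalize_counts(x)
  expect_true(nm$normalized)
  # totals 100 and 200, mean 150: factors 1.5 and 0.75
  expect_equal(unname(colSums(nm$counts)), c(150, 150))
  expect_equal(nm$counts["P1", "s1"], 60)
  expect_equal(nm$counts["P1", "s2"], 112.5)
  expect_equal(sum(nm$counts), sum(m))
})

test_that("normalization leaves balanced or single-sample matrices alone", {
  m <- matrix(c(10L, 20L, 15L, 15L), 2,
              dimnames = list(c("P1", "P2"), c("s1", "s2")))
  x <- count_matrix(m, c(s1 = "WT", s2 = "EV"))
  expect_equal(normalize_counts(x)$counts, m + 0)
  one <- count_matrix(m[, 1, drop = FALSE], c(s1 = "WT"))
  expect_equal(normalize_counts(one)$counts, m[, 1, drop = FALSE] + 0)
})

test_that("a zero-total sample is left unscaled with a warning", {
  m <- matrix(c(10L, 20L, 0L, 0L), 2,
              dimnames = list(c("P1", "P2"), c("s1", "s2")))
  x <- count_matrix(m, c(s1 = "WT", s2 = "EV"))
  expect_warning(nm <- normalize_counts(x), "s2")
  expect_equal(unname(nm$counts[, "s2"]), c(0, 0))
})

test_that("raising any threshold never increases the retained set", {
  set.seed(31)
  sim <- simulate_psm_table(sim_config(n_background = 30, n_true = 5,
                                       noise_fraction = 0.3, seed = 31))
  base <- filter_thresholds()
  n0 <- nrow(filter_psms(sim$psms, base))
  for (th in list(filter_thresholds(min_peptide_length_exclusive = 7),
                  filter_thresholds(min_peptide_probability = 0.9))) {
    expect_lte(nrow(filter_psms(sim$psms, th)), n0)
  }
  kept <- filter_psms(sim$psms, base)
  p0 <- nrow(group_to_proteins(kept, base))
  for (th in list(filter_thresholds(min_peptides_per_protein = 4),
                  filter_thresholds(min_protein_probability = 0.999))) {
    expect_lte(nrow(group_to_proteins(kept, th)), p0)
  }
})

test_that("filter-count-normalize pipeline matches a naive single pass", {
  for (seed in 1:8) {
    set.seed(seed)
    sim <- simulate_psm_table(sim_config(n_background = 12, n_true = 3,
                                         noise_fraction = 0.25,
                                         seed = seed))
    th <- filter_thresholds()
    gm <- sim$matrix$groups
    # package path
    kept <- filter_psms(sim$psms, th)
    prots <- group_to_proteins(kept, th)
    kept <- kept[kept$protein_accession %in% prots$protein, ]
    got <- normalize_counts(compute_spectral_counts(kept, gm))
    # naive path: one explicit loop over rows, then manual scaling
    keep <- logical(nrow(sim$psms))
    for (r in seq_len(nrow(sim$psms))) {
      keep[r] <- nchar(sim$psms$peptide_sequence[r]) > 5 &&
        sim$psms$charge[r] != 1 &&
        sim$psms$peptide_probability[r] > 0.8
    }
    kk <- sim$psms[keep, ]
    ok_prot <- character()
    for (p in unique(kk$protein_accession)) {
      rows <- kk[kk$protein_accession == p, ]
      if (length(unique(rows$peptide_sequence)) >= 2 &&
          rows$protein_probability[1] > 0.99)
        ok_prot <- c(ok_prot, p)
    }
    kk <- kk[kk$protein_accession %in% ok_prot, ]
    m <- oracle_tally(kk, sort(unique(kk$protein_accession)), names(gm))
    m <- m + 0
    tot <- colSums(m)
    for (s in seq_along(tot))
      if (tot[s] > 0) m[, s] <- m[, s] * mean(tot) / tot[s]
    expect_equal(got$counts, m, tolerance = 1e-12)
  }
})
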