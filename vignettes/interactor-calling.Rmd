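---
title: "Calling bait-prey interactors from AP-MS spectral counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling bait-prey interactors from AP-MS spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmscall)
```

## The experiment and the statistical model

An AP-MS pulldown series compares replicate purifications of a tagged
bait (here written WT, for the wild-type bait construct) against
empty-vector (EV) control purifications. Every protein identified in any
sample gets a spectral count — the number of peptide-spectrum matches
(PSMs) attributed to it — per sample, giving a protein × sample count
matrix with a two-group design. The design this package targets is 4 WT
vs 4 EV replicates.

Background binders (resins, tags and abundant cytosolic proteins bind
nonspecifically) appear in both groups at similar expectation; true
interactors are either *enriched* in WT or *exclusive* to WT. The calling
procedure combines four ingredients, each applied per protein:

* **SAM-type weight.** `W = (μ₁ − μ₂) / (δ₁ − δ₂)`, with group means μ
  and sample (n−1) standard deviations δ, WT indexed 1. The statistic
  grows as the group means separate and the spreads shrink; the cutoff is
  `|W| > 0.6`. The *difference* of standard deviations in the denominator
  is how the source procedure prints the formula, and the default mode
  (`sam_mode = "as_printed"`) is faithful to it. Because a difference
  denominator can vanish for well-separated groups, the conventional
  sum-denominator form is available as `sam_mode = "sum_denominator"`;
  neither mode is guessed to be "intended" — the printed form is the
  default, the alternative is explicit. When the denominator is within
  `epsilon` (default 1e-12) of zero, W is defined as 0 for equal means
  and as a signed infinity otherwise; the infinity deliberately passes
  the `|W|` cutoff, since equal spreads with separated means are maximal
  evidence under this statistic.

* **One-tailed Welch t-test.** Unequal-variance t statistic with
  Welch–Satterthwaite degrees of freedom, alternative fixed as WT mean >
  EV mean (bait enrichment is the only biologically sensible direction;
  depleted proteins are never hits), cutoff `p < 0.1`. When both groups
  have zero variance the statistic is undefined and the protein is
  routed to the rescue rule; when only one variance is zero the formula
  remains well defined and is used as is.

* **Fold change.** `μ₁ / μ₂ ≥ 2` on normalized counts; undefined when
  the EV mean is zero (again routed to rescue). The ratio is
  one-directional: depletion cannot produce a hit.

* **Rescue rule.** A protein never observed in EV (every raw EV count
  exactly 0) whose raw WT counts total at least 4 is a hit even if the
  statistics above are undefined or fail. Presence/absence is judged on
  *raw* counts — "pulled down with a spectral count of at least 4" reads
  as raw evidence — while the three statistical tests run on normalized
  counts. The threshold is interpreted as the total across WT replicates
  by default; `rescue_mode = "mean"` and `"per_replicate"` are provided
  for the stricter readings.

A protein is a hit when the statistical path (all three tests) or the
rescue path passes; the reported `path` gives the statistical one
precedence when both pass. Results are sorted by descending W with ties
broken by protein id. No multiple-testing correction is applied — the
procedure is a fixed-cutoff decision rule, not an error-rate-controlled
test battery.

## Evidence filtering and quantification

Upstream of the decision rule, PSM-level evidence is filtered with
Scaffold-style cutoffs: peptide length strictly greater than 5 residues,
no +1 (MH+1) charge states, peptide probability strictly greater than
0.80; proteins need at least 2 distinct peptide sequences (pooled across
samples, by exact sequence) and protein probability strictly greater
than 0.99. The strict inequalities mirror the "greater than" phrasing of
the cutoffs; the distinct-peptide count intentionally ignores PSM
multiplicity. Shared-peptide grouping is simplified to unique-accession
assignment — each PSM row already names one accession.

The aggregate identification FDR is estimated as the mean probability
complement, `mean(1 − protein_probability)`, over retained proteins, and
compared strictly against 0.01. Two conventions are worth noting. First,
the estimator is a whole-list sanity check, not a per-protein filter: no
decoy counts are available at this stage, and the probability complement
is the natural plug-in estimate. Second, the bound "FDR < 1.0" in the
source convention omits its unit; it is read here as 1.0 *percent*,
because a false-discovery *rate* bound of 1.0 (i.e. 100%) would be
vacuous.

Normalized spectral counts (N-SC) are produced by total-count scaling:
each sample's column is multiplied by (mean of all per-sample totals) /
(that sample's total), which equalizes per-sample totals and preserves
the grand total. The operation is idempotent when no sample total is
zero; a zero-total sample is left unscaled (with a warning), which also
means a second normalization pass would shift the target mean — one
reason the pipeline normalizes exactly once.

## The synthetic-data generator

`sim_config()` / `simulate_count_matrix()` / `simulate_psm_table()`
generate experiments with known truth labels. Counts are negative
binomial in the mean/dispersion parameterization (variance
`μ + φμ²`) — the standard overdispersed model for spectral counts.
Defaults, chosen once as a realistic operating point for this kind of
pulldown series and then frozen:

| parameter | default | meaning |
|---|---|---|
| `n_background`, `n_true` | 200, 20 | background binders / true interactors |
| `n_wt_replicates`, `n_ev_replicates` | 4, 4 | the replicate design |
| `background_mean` | 15 | mean count per background protein per sample |
| `mean_shape` | 5 | gamma shape of per-protein baseline abundance |
| `dispersion` (φ) | 0.05 | mild extra-Poisson spread, CV ≈ 37% at the mean |
| `enrichment` | 8 | WT/EV mean ratio of enriched interactors |
| `exclusive_fraction` | 0.5 | fraction of interactors with zero EV mean |
| `noise_fraction` | 0.1 | PSM rows degraded to low-confidence evidence |

Per-protein baseline abundances are gamma-distributed so the matrix
spans low- and high-abundance preys; proteins surviving the ≥ 2-peptide
filter in real experiments are moderately abundant, which motivates both
the mean and the near-Poisson dispersion (replicate pulldowns processed
identically vary mostly by counting statistics). Exclusive interactors
draw WT counts with mean `enrichment × max(baseline, background_mean)`,
guaranteeing enough evidence for the rescue rule to be exercised. The
PSM table expands the count matrix row-for-row — each (protein, sample)
cell with count c yields exactly c PSM rows — so unfiltered tallies
reproduce the matrix bit-for-bit; `noise_fraction` of rows are degraded
(low peptide probability, and a third each additionally shortened to 4–5
residues or set to charge 1) so every filter boundary sees traffic.

What the generator does *not* emulate: correlated contaminant structure
across samples, peptide-level abundance biases (length, hydrophobicity,
missed cleavages), shared peptides between proteins, dynamic-range
compression of spectral counts, and batch effects. Passing tests
therefore demonstrate the pipeline's arithmetic and decision logic under
the stated stochastic model, not robustness to every artefact of real
AP-MS data.

Determinism: both simulators seed R's RNG from `config$seed` and draw in
a fixed order, so identical configs give bit-identical outputs; the
on-disk fixture writer (`generate_fixture()`) derives every file,
including the synthetic ortholog pair, from that one seed.

## Species disambiguation

Two ortholog sequences are aligned globally (Needleman–Wunsch; match +1,
mismatch −1, linear gap −2) with deterministic tie-breaking (diagonal
over up over left), implemented in C++ since full-length neurofibromin
is ~2800 residues. Discriminating sites are the alignment columns where
the residues differ; isoleucine and leucine are treated as equivalent by
default because their residue masses are identical to mass spectrometry.
Peptides are assigned by exact substring matching against each ungapped
sequence: found in one → species-specific (necessarily spanning a
discriminating site), in both → ambiguous, in neither → unmatched.
Matching is deliberately not error-tolerant — the species determination
rests on exact residue identity. Coordinates are reported 1-based in
each ungapped protein's own space, the convention in which the human
neurofibromin site is written T2489. Real-sequence validation requires
user-supplied ortholog FASTA records; the shipped fixtures use synthetic
sequences with one planted T/A site and say so in their names.

## Case-overlap arithmetic

`compute_overlap_percent()` is exact integer arithmetic:
`100 × overlap/total`, rounded *half away from zero* to one decimal —
base R's banker's rounding would turn 6.25% into 6.2%, while the
published convention prints 54.6% for 471/862. The shipped
`table1_overlaps()` fixture carries the 20 published per-gene fractions
(one keratin's cell is blank in the published table and is left absent
rather than imputed). The published prose summarizes the range as
"20–55%"; the exactly computed range is 19.9%–55.5%, the small
discrepancy being rounding in the prose, not in the data.

## Validation strategy and problem sizes

The test suite checks every operation against independent oracles:
verdicts against a straight-line reimplementation of the rule on 500+
random 4 vs 4 matrices, Welch p-values against `stats::t.test` to 1e-9,
alignment scores against a brute-force dynamic program (short pairs) and
`Biostrings::pairwiseAlignment` (long pairs), tallies against explicit
loops, and overlap percentages against exact decimal arithmetic.
Null-uniformity of the one-tailed p-values is checked by
Kolmogorov–Smirnov at α = 0.01 on 2000 null proteins; ground-truth
recovery at the default design (200 + 20 proteins, enrichment 8) must
reach sensitivity ≥ 0.80 with false-discovery proportion ≤ 0.15 — the
frozen defaults give sensitivity ≈ 1 and FDP ≈ 0 with a comfortable
margin. A frozen-seed end-to-end run is regression-tested
byte-for-byte. These sizes keep the whole suite under a minute while
leaving each check statistically meaningful.

## Known limitations

* Peptide and protein probabilities are consumed as inputs; the
  upstream identification models that produce them are out of scope.
* The FDR estimator is decoy-free by construction and only as good as
  the input probabilities.
* The as-printed SAM denominator is discontinuous near δ₁ = δ₂; the
  epsilon/sentinel convention makes it total, but users comparing W
  values across proteins should prefer the sum-denominator mode for a
  smoothly behaved statistic.
* Two-species panels only; no error-tolerant peptide matching.
* The rescue rule's presence/absence reading is binary in the raw
  counts; a single stray EV spectrum disqualifies a protein regardless
  of its WT evidence.
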