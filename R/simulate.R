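#' Configuration for a synthetic AP-MS experiment
#'
#' Defines the ground-truth structure of a simulated bait-vs-control
#' pulldown series: a majority of nonspecific background binders present at
#' equal expectation in both groups, and a minority of true interactors that
#' are either enriched in the bait (WT) pulldowns or exclusive to them.
#' Spectral counts are drawn from a negative binomial distribution
#' (mean/dispersion parameterization), the standard overdispersed model for
#' count data of this kind; per-protein baseline abundances are
#' gamma-distributed so the matrix spans low- and high-abundance preys.
#'
#' @param n_background number of nonspecific background proteins.
#' @param n_true number of true interactors.
#' @param n_wt_replicates,n_ev_replicates replicate pulldowns per group
#'   (default 4 and 4, the design the pipeline targets).
#' @param background_mean mean spectral count per background protein per
#'   sample (default 15).
#' @param dispersion negative-binomial dispersion; the count variance is
#'   \code{mu + dispersion * mu^2} (default 0.05, i.e. close to counting
#'   noise with modest extra-Poisson spread).
#' @param enrichment multiplicative WT/EV mean ratio for true interactors
#'   (>= 1; default 8).
#' @param exclusive_fraction fraction of true interactors whose EV mean is
#'   identically zero (default 0.5).
#' @param noise_fraction fraction of emitted PSM rows degraded into
#'   low-confidence evidence (short peptide, +1 charge, or low peptide
#'   probability) so that every evidence filter is exercised (default 0.1).
#' @param mean_shape gamma shape of the per-protein baseline abundance
#'   distribution (default 5).
#' @param sticky_contaminants number of high-abundance background proteins
#'   (10x \code{background_mean}, equal in both groups) stressing the
#'   fold-change filter; default 0 (off).
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_background = 200, n_true = 20,
                       n_wt_replicates = 4, n_ev_replicates = 4,
                       background_mean = 15, dispersion = 0.05,
                       enrichment = 8, exclusive_fraction = 0.5,
                       noise_fraction = 0.1, mean_shape = 5,
                       sticky_contaminants = 0, seed = 1L) {
  cfg <- list(n_background = n_background, n_true = n_true,
              n_wt_replicates = n_wt_replicates,
              n_ev_replicates = n_ev_replicates,
              background_mean = background_mean, dispersion = dispersion,
              enrichment = enrichment,
              exclusive_fraction = exclusive_fraction,
              noise_fraction = noise_fraction, mean_shape = mean_shape,
              sticky_contaminants = sticky_contaminants,
              seed = as.integer(seed))
  chk_count <- function(f, min = 0) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v < min || v != round(v))
      stop(sprintf("invalid config field `%s`", f), call. = FALSE)
  }
  chk_pos <- function(f) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v <= 0)
      stop(sprintf("invalid config field `%s`", f), call. = FALSE)
  }
  chk_frac <- function(f) {
    v <- cfg[[f]]
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(sprintf("invalid config field `%s`", f), call. = FALSE)
  }
  chk_count("n_background"); chk_count("n_true")
  chk_count("n_wt_replicates", 1); chk_count("n_ev_replicates", 1)
  chk_count("sticky_contaminants")
  chk_pos("background_mean"); chk_pos("dispersion"); chk_pos("mean_shape")
  chk_frac("exclusive_fraction"); chk_frac("noise_fraction")
  if (is.na(cfg$enrichment) || cfg$enrichment < 1)
    stop("invalid config field `enrichment`", call. = FALSE)
  if (is.na(cfg$seed)) stop("invalid config field `seed`", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# Core generator shared by simulate_count_matrix() and simulate_psm_table().
# Assumes the RNG has already been seeded; draws in a fixed order so both
# entry points see identical matrices.
sim_core <- function(cfg) {
  n_exc <- round(cfg$exclusive_fraction * cfg$n_true)
  n_enr <- cfg$n_true - n_exc
  n_stk <- cfg$sticky_contaminants
  n <- cfg$n_background + cfg$n_true + n_stk
  proteins <- sprintf("PROT%04d", seq_len(n))
  label <- rep(c("background", "true_enriched", "true_exclusive",
                 "background"),
               times = c(cfg$n_background, n_enr, n_exc, n_stk))
  samples <- c(sprintf("WT_%d", seq_len(cfg$n_wt_replicates)),
               sprintf("EV_%d", seq_len(cfg$n_ev_replicates)))
  groups <- stats::setNames(rep(c("WT", "EV"),
                                c(cfg$n_wt_replicates, cfg$n_ev_replicates)),
                            samples)

  base_mu <- stats::rgamma(n, shape = cfg$mean_shape,
                           rate = cfg$mean_shape / cfg$background_mean)
  if (n_stk > 0)  # sticky contaminants: abundant, equal in both groups
    base_mu[(n - n_stk + 1):n] <- 10 * cfg$background_mean

  mu_wt <- base_mu
  mu_ev <- base_mu
  mu_wt[label == "true_enriched"] <- cfg$enrichment *
    base_mu[label == "true_enriched"]
  mu_wt[label == "true_exclusive"] <- cfg$enrichment *
    pmax(base_mu[label == "true_exclusive"], cfg$background_mean)
  mu_ev[label == "true_exclusive"] <- 0

  size <- 1 / cfg$dispersion
  draw <- function(mu, k) {
    out <- matrix(0L, nrow = length(mu), ncol = k)
    nz <- mu > 0
    if (any(nz))
      out[nz, ] <- stats::rnbinom(sum(nz) * k, size = size, mu = mu[nz])
    out
  }
  m <- cbind(draw(mu_wt, cfg$n_wt_replicates),
             draw(mu_ev, cfg$n_ev_replicates))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(proteins, samples)

  list(matrix = count_matrix(m, groups, normalized = FALSE),
       truth = data.frame(protein = proteins, label = label,
                          stringsAsFactors = FALSE))
}

#' Simulate a spectral-count matrix with known truth labels
#'
#' Draws a protein x sample matrix of nonnegative integer counts under the
#' structure described in [sim_config()]: background proteins share one
#' overdispersed distribution in both groups; \code{true_enriched} proteins
#' have WT mean equal to \code{enrichment} times their EV mean;
#' \code{true_exclusive} proteins have identically zero EV counts and WT
#' mean at least \code{background_mean}.
#'
#' @param config a [sim_config()].
#' @return list with \code{matrix} (a raw [count_matrix()]) and \code{truth}
#'   (data frame \code{protein}, \code{label} with labels in
#'   \code{background}, \code{true_enriched}, \code{true_exclusive}).
#' @export
simulate_count_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sim_core(config)
}

#' Simulate a PSM-level evidence table
#'
#' Expands the count matrix of [simulate_count_matrix()] (drawn with the
#' same seed, hence identical) into one row per peptide-spectrum match.
#' Every (protein, sample) cell with count c contributes exactly c rows, so
#' an unfiltered tally reproduces the matrix. Each protein carries a pool of
#' 3-8 distinct random peptides (length 6-30 over the 20 standard amino
#' acids) and a protein probability drawn near 1; a \code{noise_fraction} of
#' rows is degraded to low peptide probability and, for a third of those
#' each, to length-4/5 peptides or +1 charge, so the evidence filters have
#' work to do. Clean rows have peptide probability > 0.8 and charge 2 or 3.
#'
#' @param config a [sim_config()].
#' @return list with \code{psms} (data frame with columns
#'   \code{peptide_sequence}, \code{charge}, \code{peptide_probability},
#'   \code{protein_accession}, \code{protein_probability},
#'   \code{sample_id}), plus the \code{matrix} and \code{truth} the PSMs
#'   aggregate back to.
#' @export
simulate_psm_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  core <- sim_core(config)
  m <- core$matrix$counts
  n <- nrow(m)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rand_pep <- function(len) paste(sample(aa, len, replace = TRUE),
                                  collapse = "")

  pools <- lapply(seq_len(n), function(i) {
    k <- sample(3:8, 1)
    vapply(sample(6:30, k, replace = TRUE), rand_pep, character(1))
  })
  prot_prob <- 1 - 0.02 * stats::rbeta(n, 1, 6)   # mode at 1, mostly > 0.99

  if (n == 0 || sum(m) == 0) {
    psms <- data.frame(peptide_sequence = character(), charge = integer(),
                       peptide_probability = numeric(),
                       protein_accession = character(),
                       protein_probability = numeric(),
                       sample_id = character(), stringsAsFactors = FALSE)
    return(list(psms = psms, matrix = core$matrix, truth = core$truth))
  }

  idx <- which(m > 0, arr.ind = TRUE)
  reps <- m[idx]
  prot_i <- rep(idx[, 1], reps)
  samp_i <- rep(idx[, 2], reps)
  total <- length(prot_i)

  pep <- vapply(prot_i, function(i) sample(pools[[i]], 1), character(1))
  charge <- sample(2:3, total, replace = TRUE)
  pprob <- 0.8 + 0.2 * stats::rbeta(total, 5, 1)

  noisy <- stats::runif(total) < config$noise_fraction
  if (any(noisy)) {
    k <- sum(noisy)
    pprob[noisy] <- stats::runif(k, 0, 0.8)
    kind <- sample(1:3, k, replace = TRUE)
    short <- which(noisy)[kind == 2]
    pep[short] <- vapply(sample(4:5, length(short), replace = TRUE),
                         rand_pep, character(1))
    charge[which(noisy)[kind == 3]] <- 1L
  }

  psms <- data.frame(
    peptide_sequence = pep,
    charge = as.integer(charge),
    peptide_probability = pprob,
    protein_accession = rownames(m)[prot_i],
    protein_probability = prot_prob[prot_i],
    sample_id = colnames(m)[samp_i],
    stringsAsFactors = FALSE)
  list(psms = psms, matrix = core$matrix, truth = core$truth)
}

#' Write / read a PSM evidence table as TSV
#' @param psms data frame of PSM records.
#' @param file file path.
#' @return the table (invisibly for the writer).
#' @export
write_psm_table <- function(psms, file) {
  utils::write.table(psms, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(psms)
}

#' @rdname write_psm_table
#' @export
read_psm_table <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE,
                    colClasses = c(peptide_sequence = "character",
                                   protein_accession = "character",
                                   sample_id = "character"))
}
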