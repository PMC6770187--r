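#' Decision thresholds for interactor calling
#'
#' Cutoffs of the combined decision rule: a protein is a statistical hit
#' when all three of \code{|W| > sam_cutoff}, one-tailed Welch
#' \code{p < p_cutoff} and \code{fold change >= fold_cutoff} hold on
#' normalized counts, and a rescue hit when it is detected in the bait (WT)
#' pulldowns but never in the empty-vector (EV) controls with enough raw
#' spectral evidence.
#'
#' @param sam_cutoff SAM-type weight cutoff, applied to |W| (default 0.6).
#' @param p_cutoff one-tailed p-value cutoff (default 0.1).
#' @param fold_cutoff WT/EV fold-change cutoff (default 2).
#' @param rescue_min_total minimum raw WT spectral-count evidence for the
#'   rescue rule (default 4).
#' @param sam_mode \code{"as_printed"} uses the difference of group
#'   standard deviations in the denominator of W; \code{"sum_denominator"}
#'   uses their sum (the conventional SAM-like form). Default
#'   \code{"as_printed"}.
#' @param rescue_mode how \code{rescue_min_total} is applied to the WT
#'   counts: \code{"total"} (default; sum across replicates),
#'   \code{"mean"}, or \code{"per_replicate"} (every replicate).
#' @param epsilon guard for near-zero denominators (default 1e-12).
#' @return validated list of class \code{decision_thresholds}.
#' @export
decision_thresholds <- function(sam_cutoff = 0.6, p_cutoff = 0.1,
                                fold_cutoff = 2.0, rescue_min_total = 4L,
                                sam_mode = c("as_printed",
                                             "sum_denominator"),
                                rescue_mode = c("total", "mean",
                                                "per_replicate"),
                                epsilon = 1e-12) {
  th <- list(sam_cutoff = sam_cutoff, p_cutoff = p_cutoff,
             fold_cutoff = fold_cutoff,
             rescue_min_total = as.integer(rescue_min_total),
             sam_mode = match.arg(sam_mode),
             rescue_mode = match.arg(rescue_mode),
             epsilon = epsilon)
  if (th$sam_cutoff <= 0 || th$fold_cutoff <= 0 || th$epsilon <= 0 ||
      th$p_cutoff < 0 || th$p_cutoff > 1 || th$rescue_min_total < 0)
    stop("invalid decision threshold", call. = FALSE)
  class(th) <- "decision_thresholds"
  th
}

#' Per-protein group summary statistics
#'
#' Means and sample (n-1) standard deviations of the WT and EV replicate
#' values for one protein.
#'
#' @param wt_values,ev_values numeric vectors of length >= 2 (counts for
#'   the WT and EV replicates).
#' @return list of class \code{group_stats} with elements \code{mu1},
#'   \code{mu2} (group means), \code{delta1}, \code{delta2} (group SDs)
#'   and the group sizes \code{n1}, \code{n2}.
#' @export
group_stats <- function(wt_values, ev_values) {
  if (length(wt_values) < 2 || length(ev_values) < 2)
    stop("at least 2 replicates per group are required", call. = FALSE)
  if (anyNA(wt_values) || anyNA(ev_values))
    stop("missing values in replicate counts", call. = FALSE)
  structure(list(mu1 = mean(wt_values), mu2 = mean(ev_values),
                 delta1 = stats::sd(wt_values),
                 delta2 = stats::sd(ev_values),
                 n1 = length(wt_values), n2 = length(ev_values)),
            class = "group_stats")
}

#' SAM-type weight W
#'
#' \code{W = (mu1 - mu2) / (delta1 - delta2)} in \code{"as_printed"} mode,
#' or with \code{(delta1 + delta2)} in the denominator in
#' \code{"sum_denominator"} mode. When the denominator is within
#' \code{epsilon} of zero, W is 0 if the means are also equal (within
#' \code{epsilon}) and otherwise a signed infinity, which passes the
#' \code{|W| > sam_cutoff} test by construction (equal spread with separated
#' means is maximal evidence under this statistic).
#'
#' @param stats a [group_stats()].
#' @param thresholds a [decision_thresholds()] (supplies mode and epsilon).
#' @return the weight W (possibly \code{Inf} or \code{-Inf}).
#' @export
sam_weight <- function(stats, thresholds = decision_thresholds()) {
  stopifnot(inherits(stats, "group_stats"),
            inherits(thresholds, "decision_thresholds"))
  num <- stats$mu1 - stats$mu2
  den <- if (thresholds$sam_mode == "as_printed")
    stats$delta1 - stats$delta2 else stats$delta1 + stats$delta2
  if (abs(den) < thresholds$epsilon) {
    if (abs(num) < thresholds$epsilon) return(0)
    return(sign(num) * Inf)
  }
  num / den
}

#' One-tailed Welch (unequal-variance) t-test p-value
#'
#' Tests the alternative that the WT mean exceeds the EV mean using the
#' unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom. Returns \code{NA} when both groups have zero variance (the
#' statistic is undefined; such proteins are evaluated by the rescue rule
#' only).
#'
#' @inheritParams group_stats
#' @return one-tailed p-value in [0, 1], or \code{NA_real_}.
#' @export
welch_one_tailed_p <- function(wt_values, ev_values) {
  if (length(wt_values) < 2 || length(ev_values) < 2)
    stop("at least 2 replicates per group are required", call. = FALSE)
  n1 <- length(wt_values); n2 <- length(ev_values)
  v1 <- stats::var(wt_values); v2 <- stats::var(ev_values)
  if (v1 == 0 && v2 == 0) return(NA_real_)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mean(wt_values) - mean(ev_values)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  stats::pt(tstat, df, lower.tail = FALSE)
}

#' WT/EV fold change
#'
#' \code{mu1 / mu2} on normalized counts; \code{NA} when the EV mean is
#' zero (the ratio is undefined and the protein is evaluated by the rescue
#' rule instead).
#'
#' @param stats a [group_stats()] computed from normalized counts.
#' @return the fold change (>= 0) or \code{NA_real_}.
#' @export
fold_change <- function(stats) {
  stopifnot(inherits(stats, "group_stats"))
  if (stats$mu2 > 0) stats$mu1 / stats$mu2 else NA_real_
}

#' Presence/absence rescue rule
#'
#' A protein detected only in the bait pulldowns is rescued as a hit when
#' every EV count is zero and its raw WT spectral-count evidence reaches
#' \code{rescue_min_total} (by default the total across WT replicates).
#'
#' @param wt_raw,ev_raw raw (unnormalized) integer count vectors.
#' @param thresholds a [decision_thresholds()].
#' @return logical.
#' @export
rescue_eligible <- function(wt_raw, ev_raw,
                            thresholds = decision_thresholds()) {
  stopifnot(inherits(thresholds, "decision_thresholds"))
  if (!all(ev_raw == 0)) return(FALSE)
  switch(thresholds$rescue_mode,
         total = sum(wt_raw) >= thresholds$rescue_min_total,
         mean = mean(wt_raw) >= thresholds$rescue_min_total,
         per_replicate = all(wt_raw >= thresholds$rescue_min_total))
}

#' Call high-confidence interactors from raw and normalized counts
#'
#' Applies the combined decision rule to every protein: the statistical
#' path requires \code{|W| > sam_cutoff}, one-tailed Welch
#' \code{p < p_cutoff} and \code{fold change >= fold_cutoff}, all computed
#' on normalized counts; the rescue path applies [rescue_eligible()] to the
#' raw counts. A protein is a hit when either path passes; the reported
#' \code{path} is \code{"statistical"} when that path passed (taking
#' precedence when both do), \code{"rescue"} when only the rescue rule
#' passed, \code{"none"} otherwise.
#'
#' @param raw raw [count_matrix()].
#' @param normalized normalized [count_matrix()] over the same proteins and
#'   samples.
#' @param thresholds a [decision_thresholds()].
#' @return data frame with one row per protein (sorted by descending W,
#'   ties by protein id): \code{protein}, \code{W}, \code{p_value},
#'   \code{fold_change}, \code{stats_pass}, \code{rescue_pass},
#'   \code{verdict} ("hit"/"non_hit"), \code{path}.
#' @export
call_interactors <- function(raw, normalized,
                             thresholds = decision_thresholds()) {
  stopifnot(inherits(raw, "count_matrix"),
            inherits(normalized, "count_matrix"),
            inherits(thresholds, "decision_thresholds"))
  if (raw$normalized || !normalized$normalized)
    stop("`raw` must be unnormalized and `normalized` normalized",
         call. = FALSE)
  if (!identical(dimnames(raw$counts), dimnames(normalized$counts)) ||
      !identical(raw$groups, normalized$groups))
    stop("raw and normalized matrices must share proteins, samples and groups",
         call. = FALSE)
  wt <- wt_samples(raw)
  ev <- ev_samples(raw)
  proteins <- rownames(raw$counts)
  n <- length(proteins)
  if (n == 0)
    return(data.frame(protein = character(), W = numeric(),
                      p_value = numeric(), fold_change = numeric(),
                      stats_pass = logical(), rescue_pass = logical(),
                      verdict = character(), path = character(),
                      stringsAsFactors = FALSE))
  W <- p <- fc <- numeric(n)
  spass <- rpass <- logical(n)
  for (i in seq_len(n)) {
    nwt <- normalized$counts[i, wt]
    nev <- normalized$counts[i, ev]
    gs <- group_stats(nwt, nev)
    W[i] <- sam_weight(gs, thresholds)
    p[i] <- welch_one_tailed_p(nwt, nev)
    fc[i] <- fold_change(gs)
    spass[i] <- abs(W[i]) > thresholds$sam_cutoff &&
      !is.na(p[i]) && p[i] < thresholds$p_cutoff &&
      !is.na(fc[i]) && fc[i] >= thresholds$fold_cutoff
    rpass[i] <- rescue_eligible(raw$counts[i, wt], raw$counts[i, ev],
                                thresholds)
  }
  out <- data.frame(protein = proteins, W = W, p_value = p,
                    fold_change = fc, stats_pass = spass,
                    rescue_pass = rpass,
                    verdict = ifelse(spass | rpass, "hit", "non_hit"),
                    path = ifelse(spass, "statistical",
                                  ifelse(rpass, "rescue", "none")),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$W, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}
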