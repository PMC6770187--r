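test_that("group statistics use the sample (n-1) convention", {
  gs <- group_stats(c(10, 12, 8, 10), c(2, 2, 2, 2))
  expect_equal(gs$mu1, 10)
  expect_equal(gs$delta1, sqrt(8 / 3))  # SS = 8, var = 8/3
  expect_equal(gs$mu2, 2)
  expect_equal(gs$delta2, 0)
  same <- group_stats(c(3, 4, 5), c(3, 4, 5))
  expect_equal(same$mu1, same$mu2)
  expect_equal(same$delta1, same$delta2)
  expect_error(group_stats(c(1), c(1, 2)), "replicates")
})

test_that("SAM weight follows the printed difference-denominator form", {
  th <- decision_thresholds()
  eq <- structure(list(mu1 = 5, mu2 = 5, delta1 = 2, delta2 = 1,
                       n1 = 4, n2 = 4), class = "group_stats")
  expect_equal(sam_weight(eq, th), 0)
  gs <- group_stats(c(10, 12, 8, 10), c(2, 3, 1, 2))
  expect_equal(sam_weight(gs, th), 8 / (sqrt(8 / 3) - sqrt(2 / 3)))
  expect_equal(sam_weight(gs, th), 9.7979590, tolerance = 1e-6)
  # equal spreads with separated means: signed infinity, passes the cutoff
  tie <- structure(list(mu1 = 9, mu2 = 3, delta1 = 1.5, delta2 = 1.5,
                        n1 = 4, n2 = 4), class = "group_stats")
  expect_identical(sam_weight(tie, th), Inf)
  expect_true(abs(sam_weight(tie, th)) > th$sam_cutoff)
  down <- structure(list(mu1 = 3, mu2 = 9, delta1 = 1.5, delta2 = 1.5,
                         n1 = 4, n2 = 4), class = "group_stats")
  expect_identical(sam_weight(down, th), -Inf)
})

test_that("sum-denominator mode recovers the conventional SAM-like form", {
  th <- decision_thresholds(sam_mode = "sum_denominator")
  gs <- group_stats(c(10, 12, 8, 10), c(2, 3, 1, 2))
  expect_equal(sam_weight(gs, th), 8 / (sqrt(8 / 3) + sqrt(2 / 3)))
  both_zero <- group_stats(c(4, 4, 4), c(4, 4, 4))
  expect_equal(sam_weight(both_zero, th), 0)
})

test_that("one-tailed Welch p matches the reference and its symmetries", {
  expect_equal(welch_one_tailed_p(c(1, 2, 3), c(1, 2, 3)), 0.5)
  wt <- c(4, 5, 6, 5); ev <- c(1, 1, 2, 1)
  # frozen from stats::t.test(wt, ev, alternative="greater"): t = 7.8335,
  # df = 4.9726
  expect_equal(welch_one_tailed_p(wt, ev), 2.788666304e-4,
               tolerance = 1e-8)
  expect_equal(welch_one_tailed_p(wt, ev), oracle_welch_p(wt, ev),
               tolerance = 1e-12)
  expect_equal(welch_one_tailed_p(ev, wt), 1 - welch_one_tailed_p(wt, ev),
               tolerance = 1e-12)
  expect_true(is.na(welch_one_tailed_p(c(2, 2, 2), c(0, 0, 0))))
  expect_error(welch_one_tailed_p(1, c(1, 2)), "replicates")
})

test_that("fold change is the WT/EV mean ratio with a zero guard", {
  fc <- function(wt, ev) fold_change(group_stats(wt, ev))
  expect_equal(fc(c(9, 9), c(3, 3)), 3)
  expect_equal(fc(c(5, 5), c(5, 5)), 1)
  expect_true(is.na(fc(c(5, 5), c(0, 0))))
})

test_that("rescue rule needs absence from EV and enough WT evidence", {
  th <- decision_thresholds()
  expect_true(rescue_eligible(c(2, 1, 1, 0), c(0, 0, 0, 0), th))
  expect_false(rescue_eligible(c(2, 1, 0, 0), c(0, 0, 0, 0), th))
  expect_false(rescue_eligible(c(50, 50, 50, 50), c(0, 0, 1, 0), th))
  per <- decision_thresholds(rescue_mode = "per_replicate",
                             rescue_min_total = 1)
  expect_true(rescue_eligible(c(1, 1, 1, 1), c(0, 0, 0, 0), per))
  expect_false(rescue_eligible(c(2, 1, 1, 0), c(0, 0, 0, 0), per))
  mn <- decision_thresholds(rescue_mode = "mean")
  expect_true(rescue_eligible(c(4, 4, 4, 4), c(0, 0, 0, 0), mn))
  expect_false(rescue_eligible(c(2, 1, 1, 0), c(0, 0, 0, 0), mn))
})

toy_matrices <- function() {
  m <- rbind(P1 = c(10, 12, 8, 10, 2, 3, 1, 2),
             P2 = c(2, 1, 1, 0, 0, 0, 0, 0),
             P3 = c(5, 6, 4, 5, 5, 6, 4, 5))
  colnames(m) <- c(paste0("WT_", 1:4), paste0("EV_", 1:4))
  storage.mode(m) <- "integer"
  groups <- stats::setNames(rep(c("WT", "EV"), each = 4), colnames(m))
  raw <- count_matrix(m, groups)
  list(raw = raw, norm = normalize_counts(raw))
}

test_that("combined rule separates statistical, rescue and non hits", {
  tm <- toy_matrices()
  calls <- call_interactors(tm$raw, tm$norm)
  expect_equal(nrow(calls), 3)
  expect_equal(sum(calls$verdict == "hit"), 2)
  p1 <- calls[calls$protein == "P1", ]
  expect_equal(p1$verdict, "hit")
  expect_equal(p1$path, "statistical")
  p2 <- calls[calls$protein == "P2", ]
  expect_equal(p2$path, "rescue")
  expect_false(p2$stats_pass)  # EV mean 0: fold change undefined
  p3 <- calls[calls$protein == "P3", ]
  expect_equal(p3$verdict, "non_hit")
  expect_equal(p3$path, "none")
  # sorted by descending W
  expect_false(is.unsorted(rev(calls$W)))
})

test_that("degenerate inputs are handled", {
  empty <- count_matrix(matrix(integer(), 0, 8,
                               dimnames = list(NULL,
                                               c(paste0("WT_", 1:4),
                                                 paste0("EV_", 1:4)))),
                        stats::setNames(rep(c("WT", "EV"), each = 4),
                                        c(paste0("WT_", 1:4),
                                          paste0("EV_", 1:4))))
  calls <- call_interactors(empty,
                            suppressWarnings(normalize_counts(empty)))
  expect_equal(nrow(calls), 0)
  tm <- toy_matrices()
  expect_error(call_interactors(tm$norm, tm$norm), "unnormalized")
  bad <- tm$raw
  bad$counts <- bad$counts[1:2, ]
  expect_error(call_interactors(bad, tm$norm), "share")
})

test_that("every well-evidenced exclusive interactor is rescued", {
  cfg <- sim_config(n_background = 200, n_true = 20, enrichment = 8,
                    seed = 7)
  sim <- simulate_count_matrix(cfg)
  raw <- sim$matrix
  calls <- call_interactors(raw, normalize_counts(raw))
  exc <- sim$truth$protein[sim$truth$label == "true_exclusive"]
  wt <- grep("^WT_", colnames(raw$counts), value = TRUE)
  well <- exc[rowSums(raw$counts[exc, wt, drop = FALSE]) >= 4]
  verdicts <- calls$verdict[match(well, calls$protein)]
  expect_true(all(verdicts == "hit"))
})

test_that("verdicts agree with a straight-line oracle on random matrices", {
  set.seed(101)
  for (i in 1:60) {
    tm <- random_matrix_pair(n_prot = 6, lambda = sample(1:6, 1))
    calls <- call_interactors(tm$raw, tm$norm)
    wt <- paste0("WT_", 1:4); ev <- paste0("EV_", 1:4)
    for (p in calls$protein) {
      want <- oracle_verdict(tm$norm$counts[p, wt], tm$norm$counts[p, ev],
                             tm$raw$counts[p, wt], tm$raw$counts[p, ev])
      expect_identical(calls$verdict[calls$protein == p], want)
    }
  }
})

test_that("tightening any decision threshold never adds hits", {
  set.seed(55)
  n_hits <- function(tm, th) {
    sum(call_interactors(tm$raw, tm$norm, th)$verdict == "hit")
  }
  for (i in 1:20) {
    tm <- random_matrix_pair(n_prot = 12, lambda = 3)
    base <- n_hits(tm, decision_thresholds())
    expect_lte(n_hits(tm, decision_thresholds(sam_cutoff = 1.2)), base)
    expect_lte(n_hits(tm, decision_thresholds(p_cutoff = 0.05)), base)
    expect_lte(n_hits(tm, decision_thresholds(fold_cutoff = 3)), base)
    expect_lte(n_hits(tm, decision_thresholds(rescue_min_total = 8)),
               base)
  }
})
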