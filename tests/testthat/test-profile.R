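test_that("pseudo-error rates replace zero counts with half a count", {
  expect_equal(rate_with_pseudocount(0, 5000), 1e-4)
  expect_equal(rate_with_pseudocount(5, 1000), 0.005)
  expect_equal(rate_with_pseudocount(0, 1), 0.5)
  expect_equal(rate_with_pseudocount(c(0, 2), c(10, 10)), c(0.05, 0.2))
  expect_true(is.na(rate_with_pseudocount(0, 0)))
})

test_that("cell filtering applies the per-class count thresholds", {
  tl <- error_tally(40L)
  tl["30", "30", "match", "correct"] <- 999
  tl["31", "31", "match", "correct"] <- 1000
  tl["20", "25", "mismatch", "correct"] <- 99
  tl["21", "25", "mismatch", "correct"] <- 95
  tl["21", "25", "mismatch", "error"] <- 5
  out <- filter_cells(tl)
  expect_true(is.na(out$match$rate["30", "30"]))
  expect_equal(out$match$rate["31", "31"], 0.5 / 1000)
  expect_true(is.na(out$mismatch$rate["20", "25"]))
  expect_equal(out$mismatch$rate["21", "25"], 0.05)
  # fully masked tally warns
  expect_warning(filter_cells(error_tally(40L)), "below the count thresholds")
})

test_that("truth tallies classify overlap columns and conserve counts", {
  # two fragments, hand-built events
  truth_seq <- c("ACGT", "GGGG")
  ev <- data.frame(
    pair    = c(1L, 1L, 1L, 2L, 2L, 2L),
    pos     = c(0L, 1L, 2L, 0L, 1L, 2L),
    r1_base = c("A", "C", "T", "G", "G", "N"),
    r1_qual = c(30L, 25L, 20L, 30L, 12L, 2L),
    r2_base = c("A", "C", "A", "G", "T", "G"),
    r2_qual = c(30L, 20L, 30L, 30L, 10L, 30L),
    base    = c("A", "C", "A", "G", "G", "G"),
    qual    = c(35L, 25L, 10L, 38L, 2L, 30L),
    class   = c("match", "match", "mismatch", "match", "mismatch",
                "n_resolved"))
  tl <- tally_from_truth(ev, truth_seq)
  # (A,30/30) matches truth A -> match correct
  expect_equal(tl["30", "30", "match", "correct"], 2)  # also pair 2 G match
  # (C vs truth C at pos 1) -> match correct at (25,20)
  expect_equal(tl["25", "20", "match", "correct"], 1)
  # mismatch won by r2 base A, truth G at pos 2 -> mismatch error
  expect_equal(tl["20", "30", "mismatch", "error"], 1)
  # mismatch won by r1 base G == truth -> mismatch correct
  expect_equal(tl["12", "10", "mismatch", "correct"], 1)
  # N-resolved column excluded entirely; total conserved
  expect_equal(sum(tl), 5)
  # invalid pairs are skipped with a warning
  expect_warning(t2 <- tally_from_truth(ev, truth_seq, valid = c(TRUE, FALSE)),
                 "skipped")
  expect_equal(sum(t2), 3)
})

test_that("error-free merges tally no match-class errors", {
  sim <- simulate_pairs(sim_config(n_pairs = 150L, seed = 19L, n_rate = 0,
                                   error_scale = 0))
  res <- merge_pairs(sim$r1, sim$r2, align_params(allow_dovetail = TRUE),
                     events = "all")
  valid <- !is.na(res$aln$offset) & res$aln$offset == true_offsets(sim)
  tl <- tally_from_truth(res$events, sim$truth$frag_seq, valid)
  expect_gt(sum(tl[, , "match", "correct"]), 0)
  expect_equal(sum(tl[, , "match", "error"]), 0)
  expect_equal(sum(tl[, , "mismatch", ]), 0)
})

test_that("the baseline fit recovers the Phred relation from exact rates", {
  q <- 2:40
  bp <- fit_baseline(q, qual_to_error(q))
  # forward: fitted rate within 0.2 Q of the identity at every level
  qhat <- error_to_qual(predict_baseline(bp, q))
  expect_lt(max(abs(qhat - q)), 0.2)
  # inverse round trip
  expect_lt(max(abs(invert_baseline(bp, qual_to_error(q)) - q)), 0.2)
  # extrapolation continues the terminal slope
  expect_gt(invert_baseline(bp, 1e-6), 50)
})

test_that("degenerate baseline inputs fail loudly", {
  expect_error(fit_baseline(30, 1e-3), "too few quality levels")
  expect_error(fit_baseline(c(10, 20, 30), rep(1e-3, 3)), "too few")
  flat <- fit_baseline(2:40, rep(1e-3, 39))
  expect_warning(invert_baseline(flat, 1e-4), "flat")
})

test_that("matrix training recovers the additive independence surface", {
  # rates constructed directly from the independence product
  # P(both wrong) = 10^-((q1+q2)/10): entries must come back as q1+q2
  qlab <- 0:40
  rate <- outer(qlab, qlab, function(a, b) 10^(-(a + b) / 10))
  dimnames(rate) <- list(qlab, qlab)
  tot <- matrix(1e9, 41, 41, dimnames = list(qlab, qlab))
  # mismatch surface shaped like the difference scheme: worst when the
  # two claimed qualities agree
  mrate <- outer(qlab, qlab, function(a, b) 10^(-(abs(a - b) + 2) / 10))
  dimnames(mrate) <- list(qlab, qlab)
  rates <- list(match = list(rate = rate, total = tot),
                mismatch = list(rate = mrate, total = tot))
  bp <- fit_baseline(0:40, qual_to_error(0:40))
  qm <- build_matrices(rates, bp, qual_max = 80L)
  grid <- expand.grid(q1 = qlab, q2 = qlab)
  target <- pmin(grid$q1 + grid$q2, 80)
  got <- qm$match_matrix[cbind(grid$q1 + 1, grid$q2 + 1)]
  expect_lte(max(abs(got - target)), 3)
  # the match matrix is symmetric by construction
  expect_equal(qm$match_matrix, t(qm$match_matrix))
  # mismatch entries: lowest near the diagonal, rising toward corners
  xm <- qm$mismatch_matrix
  expect_lt(xm["20", "20"], xm["2", "38"])
  expect_lt(xm["30", "30"], xm["40", "2"])
  # capping
  qm40 <- build_matrices(rates, bp, qual_max = 40L)
  expect_lte(max(qm40$match_matrix), 40)
})

test_that("fully masked tables cannot be trained", {
  qlab <- 0:40
  nat <- matrix(NA_real_, 41, 41, dimnames = list(qlab, qlab))
  tot <- matrix(0, 41, 41, dimnames = list(qlab, qlab))
  rates <- list(match = list(rate = nat, total = tot),
                mismatch = list(rate = nat, total = tot))
  bp <- fit_baseline(0:40, qual_to_error(0:40))
  expect_error(build_matrices(rates, bp), "all cells are masked")
})

test_that("tallies are deterministic given a fixed input stream", {
  sim <- simulate_pairs(sim_config(n_pairs = 80L, seed = 5L))
  one <- function() {
    res <- merge_pairs(sim$r1, sim$r2, align_params(allow_dovetail = TRUE),
                       events = "all")
    valid <- !is.na(res$aln$offset) & res$aln$offset == true_offsets(sim)
    tally_from_truth(res$events, sim$truth$frag_seq, valid)
  }
  expect_identical(one(), one())
})
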