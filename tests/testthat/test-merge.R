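test_that("single-column resolution follows the base/quality rules", {
  fj <- quality_model("fastqjoin")
  expect_equal(resolve_position("A", 40, "A", 40, fj),
               list(base = "A", qual = 40L, class = "match"))
  expect_equal(resolve_position("A", 35, "C", 20, fj),
               list(base = "A", qual = 15L, class = "mismatch"))
  expect_equal(resolve_position("C", 20, "A", 35, fj),
               list(base = "A", qual = 15L, class = "mismatch"))
  expect_equal(resolve_position("N", 2, "G", 30, fj),
               list(base = "G", qual = 30L, class = "n_resolved"))
  expect_equal(resolve_position("N", 2, "N", 2, fj),
               list(base = "N", qual = 0L, class = "n_both"))
  # ambiguous equal-quality disagreement -> N
  expect_equal(resolve_position("A", 30, "C", 30, fj),
               list(base = "N", qual = 0L, class = "mismatch"))
  mm <- matrix(7, 41, 41, dimnames = list(0:40, 0:40))
  qm <- quality_model("matrix", match_matrix = mm, mismatch_matrix = mm)
  expect_equal(resolve_position("A", 30, "C", 30, qm)$qual, 7L)
  # real merged bases are floored at quality 2
  expect_equal(resolve_position("A", 10, "C", 9, fj)$qual, 2L)
})

test_that("stitching assembles the merged read geometry exactly", {
  set.seed(21)
  frag <- rand_seq(150)
  r1 <- substr(frag, 1, 100)
  r2 <- oracle_rc(substr(frag, 51, 150))
  st <- stitch(r1, rep(35L, 100), r2, rep(30L, 100), offset = 50L)
  expect_equal(nchar(st$merged$seq), 150L)
  expect_equal(st$merged$seq, frag)
  expect_equal(substr(st$merged$seq, 1, 50), substr(r1, 1, 50))
  # non-overlap qualities copied verbatim: R1 prefix 35s, R2 suffix 30s
  q <- quals(st$merged)[[1L]]
  expect_equal(q[1:50], rep(35L, 50))
  expect_equal(q[101:150], rep(30L, 50))

  # perfect full overlap: merged read equals R1
  st2 <- stitch(r1, rep(35L, 100), oracle_rc(r1), rep(35L, 100), offset = 0L)
  expect_equal(st2$merged$seq, r1)
  expect_equal(nchar(st2$merged$seq), 100L)
})

test_that("error-free simulated pairs merge back into their fragments", {
  sim <- simulate_pairs(sim_config(n_pairs = 150L, seed = 9L, n_rate = 0,
                                   error_scale = 0))
  res <- merge_pairs(sim$r1, sim$r2, align_params(allow_dovetail = TRUE))
  expect_gt(length(res$merged_idx) / nrow(sim$truth), 0.8)
  exact <- res$merged$seq == sim$truth$frag_seq[res$merged_idx]
  expect_gte(mean(exact), 0.99)
  # dovetailed fragments (shorter than the read) come back exactly, with
  # the adapter overhang excluded
  dt <- sim$truth$dovetail[res$merged_idx]
  expect_true(any(dt))
  expect_equal(nchar(res$merged$seq[dt]),
               sim$truth$frag_len[res$merged_idx][dt])
})

test_that("merged length always equals len1 + len2 - overlap_len", {
  sim <- simulate_pairs(sim_config(n_pairs = 100L, seed = 14L))
  res <- merge_pairs(sim$r1, sim$r2, align_params(allow_dovetail = TRUE))
  aln <- res$aln[res$merged_idx, ]
  len1 <- nchar(sim$r1$seq[res$merged_idx])
  len2 <- nchar(sim$r2$seq[res$merged_idx])
  # the merged read spans the two 5' ends; overhangs beyond them are
  # clipped, so its length is offset + len2 = len1 + len2 - overlap for
  # non-dovetailed placements and frag_len for dovetailed ones
  expect_equal(nchar(res$merged$seq), aln$offset + len2)
  nd <- !aln$dovetail
  expect_equal(nchar(res$merged$seq)[nd],
               (len1 + len2 - aln$overlap_len)[nd])
})

test_that("single-read Ns in the overlap are corrected", {
  sim <- simulate_pairs(sim_config(n_pairs = 400L, seed = 33L, n_rate = 5e-3))
  res <- merge_pairs(sim$r1, sim$r2, align_params(allow_dovetail = TRUE),
                     events = "all")
  ev <- res$events
  nres <- ev[ev$class == "n_resolved", ]
  expect_gt(nrow(nres), 0L)
  expect_true(all(nres$base != "N"))
  # the surviving base keeps its own quality
  expect_true(all(nres$qual == ifelse(nres$r1_base == "N",
                                      nres$r2_qual, nres$r1_qual)))
  # N in the merged read only from double-Ns or equal-quality mismatches
  isN <- ev[ev$base == "N", ]
  expect_true(all(isN$class %in% c("n_both", "mismatch")))
  expect_true(all(isN$r1_qual[isN$class == "mismatch"] ==
                  isN$r2_qual[isN$class == "mismatch"]))
})

test_that("merging reduces the overlap error rate on simulated data", {
  sim <- simulate_pairs(sim_config(n_pairs = 4000L, seed = 61L,
                                   quality = sim_quality("constant", q = 28,
                                                         noise_sd = 3)))
  res <- merge_pairs(sim$r1, sim$r2, align_params(allow_dovetail = TRUE),
                     events = "all")
  valid <- which(!is.na(res$aln$offset) &
                   res$aln$offset == true_offsets(sim))
  toe <- truth_overlap_errors(sim, valid)
  pre_rate <- mean(c(!toe$r1_ok, !toe$r2_ok))
  ev <- res$events[res$events$pair %in% valid, ]
  tb <- substring(sim$truth$frag_seq[ev$pair], ev$pos + 1, ev$pos + 1)
  post_rate <- mean(ev$base != tb)
  expect_lt(post_rate, pre_rate)
})

test_that("adapter removal clips dovetailed overhangs and is idempotent", {
  sim <- simulate_pairs(sim_config(n_pairs = 30L, seed = 71L, frag_min = 60L,
                                   frag_max = 60L, n_rate = 0,
                                   error_scale = 0))
  params <- align_params(allow_dovetail = TRUE)
  aln <- align_pairs(sim$r1, sim$r2, params)
  expect_true(all(aln$found & aln$dovetail))
  cl <- remove_adapters(sim$r1, sim$r2, aln)
  expect_equal(nchar(cl$r1$seq), rep(60L, 30L))
  expect_equal(cl$r1$seq, sim$truth$frag_seq)
  expect_equal(cl$r2$seq, reverse_complement(sim$truth$frag_seq))
  expect_equal(nchar(cl$r1$qual), rep(60L, 30L))
  # idempotence: reprocessing the clipped pairs changes nothing
  aln2 <- align_pairs(cl$r1, cl$r2, params)
  cl2 <- remove_adapters(cl$r1, cl$r2, aln2)
  expect_equal(cl2$r1$seq, cl$r1$seq)
  expect_equal(cl2$r2$seq, cl$r2$seq)
  expect_length(cl2$clipped, 0L)
})

test_that("non-overlapping and unaligned pairs pass through unchanged", {
  sim <- simulate_pairs(sim_config(n_pairs = 20L, seed = 81L, frag_min = 300L,
                                   frag_max = 300L, frag_mean = 300))
  aln <- align_pairs(sim$r1, sim$r2, align_params(allow_dovetail = TRUE))
  expect_false(any(aln$found))
  out <- remove_adapters(sim$r1, sim$r2, aln)
  expect_equal(out$r1$seq, sim$r1$seq)
  expect_equal(out$r2$seq, sim$r2$seq)
  st <- stitch_pairs(sim$r1, sim$r2, aln)
  expect_length(st$merged_idx, 0L)
  expect_length(st$failed_idx, 20L)
})
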