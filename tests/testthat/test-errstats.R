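test_that("variant application verifies reference bases", {
  g <- synthetic_phix_genome()
  expect_equal(nchar(g), 5386L)
  ed <- phix_variants()
  expect_equal(substring(g, ed$position, ed$position), ed$ref)
  g2 <- apply_variants(g)
  expect_equal(nchar(g2), 5386L)
  expect_equal(substring(g2, ed$position, ed$position), ed$alt)
  # everything else untouched
  diffs <- which(strsplit(g, "")[[1L]] != strsplit(g2, "")[[1L]])
  expect_equal(diffs, ed$position)
  # identity on empty edit list; error on a wrong claimed reference
  expect_equal(apply_variants(g, phix_variants()[0, ]), g)
  bad <- data.frame(position = 587L, ref = "T", alt = "A")
  expect_error(apply_variants(g, bad), "mismatch at position 587")
  oob <- data.frame(position = 6000L, ref = "A", alt = "G")
  expect_error(apply_variants(g, oob), "outside the genome")
})

test_that("circular extension appends the genome head", {
  g <- apply_variants(synthetic_phix_genome())
  ext <- circular_extend(g)
  expect_equal(nchar(ext), 6386L)
  expect_equal(substr(ext, 5387, 6386), substr(ext, 1, 1000))
  expect_equal(circular_extend(g, 0L), g)
  expect_error(circular_extend("ACGT", 5L), "\\[0, 4\\]")
  s <- "ACGTTG"
  expect_equal(circular_extend(s, 3L), "ACGTTGACG")
})

write_sam <- function(path, recs, rname = "ref", rlen = 100L) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", rname, rlen))
  writeLines(c(hdr, recs), path)
}

test_that("per-quality error counting walks matched bases only", {
  ref <- "ACGTACGTACGTACGTACGT"
  f <- withr::local_tempfile(fileext = ".sam")
  # perfect read at Q40 ('I'), one read with a substitution at a Q12
  # base ('-'), one with a soft-clip and an insertion
  r1 <- paste("r1", 0, "ref", 1, 60, "20M", "*", 0, 0, ref,
              strrep("I", 20), sep = "\t")
  sub <- paste0("T", substr(ref, 2, 20))
  q2 <- paste0("-", strrep("I", 19))
  r2 <- paste("r2", 0, "ref", 1, 60, "20M", "*", 0, 0, sub, q2, sep = "\t")
  ins <- paste0(substr(ref, 1, 5), "AA", substr(ref, 6, 15))
  r3 <- paste("r3", 0, "ref", 1, 60, "5M2I10M", "*", 0, 0, ins,
              strrep("I", 17), sep = "\t")
  clip <- paste0("TT", substr(ref, 1, 13))
  r4 <- paste("r4", 0, "ref", 1, 60, "2S13M", "*", 0, 0, clip,
              strrep("I", 15), sep = "\t")
  write_sam(f, c(r1, r2, r3, r4), rlen = 20L)
  out <- count_errors_by_quality(f, ref)
  q40 <- out$per_q[out$per_q$q == 40, ]
  # r1: 20; r2: 19 Q40 bases; r3: 15 of 17 (2I skipped); r4: 13 (2S skipped)
  expect_equal(q40$bases, 20 + 19 + 15 + 13)
  expect_equal(q40$errors, 0)
  q12 <- out$per_q[out$per_q$q == 12, ]
  expect_equal(q12$bases, 1)
  expect_equal(q12$errors, 1)
})

test_that("unmapped and improperly-paired records are excluded", {
  ref <- "ACGTACGTACGTACGTACGT"
  f <- withr::local_tempfile(fileext = ".sam")
  un <- paste("u1", 4, "*", 0, 0, "*", "*", 0, 0, "ACGT", "IIII", sep = "\t")
  # paired (0x1) but not properly paired (no 0x2)
  np <- paste("p1", 1, "ref", 1, 60, "4M", "*", 0, 0, "ACGT", "IIII", sep = "\t")
  # paired and proper
  pp <- paste("p2", 3, "ref", 1, 60, "4M", "*", 0, 0, "ACGT", "IIII", sep = "\t")
  write_sam(f, c(un, np, pp), rlen = 20L)
  out <- count_errors_by_quality(f, ref)
  expect_equal(sum(out$per_q$bases), 4)
  writeLines(character(), f)
  write_sam(f, un, rlen = 20L)
  expect_warning(out2 <- count_errors_by_quality(f, ref), "no mapped")
  expect_equal(nrow(out2$per_q), 0L)
})

test_that("merged-read overlap columns split into event classes", {
  # merged read of 8 bp from 6 bp reads: overlap columns 2..5 (0-based)
  ref <- "ACGTACGT"
  merged <- "ACGTACGT"
  f <- withr::local_tempfile(fileext = ".sam")
  rec <- paste("m1", 0, "ref", 1, 60, "8M", "*", 0, 0, merged,
               strrep("5", 8), sep = "\t")  # '5' = Q20
  write_sam(f, rec, rlen = 8L)
  ev <- data.frame(id = "m1", pos = 3L, class = "mismatch")
  out <- count_errors_by_quality(f, ref, event_log = ev,
                                 read_lengths = c(6L, 6L))
  pc <- out$per_class
  expect_equal(pc$bases[pc$class == "nonoverlap"], 4)
  expect_equal(pc$bases[pc$class == "match"], 3)
  expect_equal(pc$bases[pc$class == "mismatch"], 1)
  expect_error(count_errors_by_quality(f, ref, event_log = ev),
               "read_lengths")
})

test_that("simulated alignments recover the injected error rate", {
  sim <- simulate_pairs(sim_config(n_pairs = 800L, seed = 91L, n_rate = 0,
                                   quality = sim_quality("constant", q = 30,
                                                         noise_sd = 0)))
  fwd <- which(sim$truth$strand == "+")
  f <- withr::local_tempfile(fileext = ".sam")
  m <- pmin(sim$config$read_len, sim$truth$frag_len[fwd])
  cig <- ifelse(m < sim$config$read_len,
                sprintf("%dM%dS", m, sim$config$read_len - m),
                sprintf("%dM", m))
  recs <- paste(sim$truth$id[fwd], 0, "ref", sim$truth$frag_start[fwd], 60,
                cig, "*", 0, 0, sim$r1$seq[fwd], sim$r1$qual[fwd], sep = "\t")
  write_sam(f, recs, rlen = sim$config$ref_len)
  out <- count_errors_by_quality(f, sim$config$reference)
  q30 <- out$per_q[out$per_q$q == 30, ]
  expect_gt(q30$bases, 3e4)
  sd3 <- 3 * sqrt(1e-3 / q30$bases)
  expect_lt(abs(q30$rate - 1e-3), sd3)
})
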