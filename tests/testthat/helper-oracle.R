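# Independent brute-force implementations used as oracles.  These share
# no code with the package internals (scalar R, own complement table).

oracle_rc <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

oracle_better <- function(a, b) {
  da <- a$matches + a$mismatches
  db <- b$matches + b$mismatches
  fa <- a$mismatches * db
  fb <- b$mismatches * da
  if (fa != fb) return(fa < fb)
  if (a$overlap_len != b$overlap_len) return(a$overlap_len > b$overlap_len)
  if (abs(a$offset) != abs(b$offset)) return(abs(a$offset) < abs(b$offset))
  a$offset > b$offset
}

# exhaustive scorer over every placement; returns NULL or the optimum
oracle_align <- function(s1, s2, min_overlap = 20L, max_mismatch_frac = 0.1,
                         allow_dovetail = FALSE) {
  v1 <- strsplit(s1, "", fixed = TRUE)[[1L]]
  v2 <- strsplit(oracle_rc(s2), "", fixed = TRUE)[[1L]]
  len1 <- length(v1)
  len2 <- length(v2)
  best <- NULL
  for (o in (min_overlap - len2):(len1 - min_overlap)) {
    lo <- max(0L, o)
    hi <- min(len1, o + len2)
    ov <- hi - lo
    if (ov < min_overlap) next
    if (!allow_dovetail && (o < 0L || len1 - o > len2)) next
    a <- v1[(lo + 1L):hi]
    b <- v2[(lo - o + 1L):(hi - o)]
    nn <- a == "N" | b == "N"
    cand <- list(offset = o, overlap_len = ov,
                 matches = sum(!nn & a == b),
                 mismatches = sum(!nn & a != b),
                 n_positions = sum(nn))
    den <- cand$matches + cand$mismatches
    if (cand$mismatches > max_mismatch_frac * den + 1e-9) next
    if (is.null(best) || oracle_better(cand, best)) best <- cand
  }
  best
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_fastq_set <- function(n, len_range = c(5L, 60L)) {
  lens <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
  fastq_set(sprintf("read%03d", seq_len(n)),
            vapply(lens, rand_seq, character(1)),
            lapply(lens, function(l) sample(0:93, l, replace = TRUE)))
}
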