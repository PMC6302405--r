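# fast scalar helpers used in the per-pair loop (avoid Biostrings call
# overhead on 10^4-10^5 short strings)
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
rc_chars <- function(v) unname(rev(COMP[v]))

# mutate bases at idx to one of the 3 alternatives, uniformly
BASES <- c("A", "C", "G", "T")
mutate_bases <- function(v, idx) {
  if (length(idx) == 0L) return(v)
  code <- match(v[idx], BASES)
  ok <- !is.na(code)
  idx <- idx[ok]; code <- code[ok]
  if (length(idx)) {
    v[idx] <- BASES[((code - 1L + sample.int(3L, length(idx), replace = TRUE)) %% 4L) + 1L]
  }
  v
}

# split one global seed into independent per-pair streams so that
# changing n_pairs never reshuffles earlier pairs
pair_seed <- function(seed, i) {
  p <- 2147483629
  as.integer((as.numeric(seed) %% p + i * 97) %% p)
}

#' Per-base quality model for the read simulator
#'
#' Either a constant quality or a linear per-cycle ramp (Illumina-like
#' decline along the read), both with additive Gaussian noise, rounded
#' and clamped to \[2, 40\].
#'
#' @param kind `"ramp"` or `"constant"`.
#' @param q constant quality (kind `"constant"`).
#' @param q_start,q_end ramp endpoints at the first/last cycle.
#' @param noise_sd standard deviation of per-base Gaussian noise.
#' @return A list of class `sim_quality`.
#' @export
sim_quality <- function(kind = c("ramp", "constant"), q = 30,
                        q_start = 38, q_end = 30, noise_sd = 2) {
  kind <- match.arg(kind)
  structure(list(kind = kind, q = q, q_start = q_start, q_end = q_end,
                 noise_sd = noise_sd), class = "sim_quality")
}

draw_quals <- function(qm, read_len) {
  base <- if (qm$kind == "constant") rep(qm$q, read_len)
          else seq(qm$q_start, qm$q_end, length.out = read_len)
  q <- round(base + rnorm(read_len, 0, qm$noise_sd))
  pmin(pmax(as.integer(q), 2L), 40L)
}

#' Simulator configuration
#'
#' Defaults emulate a short-fragment Illumina control library sequenced
#' 2 x 100 bp: fragment lengths truncated-normal(150, 30) on \[70, 400\]
#' so that most pairs overlap and a tail of fragments is shorter than
#' the read length (dovetail, adapter read-through); standard adapter
#' read-through sequences; per-cycle declining qualities; independent
#' substitution errors at the Phred-implied rate `10^(-q/10)`; optional
#' first-strand errors shared by both reads at unreduced quality
#' (`shared_error_rate`); occasional `N` masking.
#'
#' @param reference reference sequence (character string); `NULL` draws
#'   a random genome of `ref_len` bases from the seed.
#' @param ref_len length of the random reference when `reference` is
#'   `NULL`.
#' @param n_pairs number of read pairs.
#' @param read_len read length in bp.
#' @param frag_mean,frag_sd,frag_min,frag_max truncated-normal fragment
#'   length model.
#' @param adapter1,adapter2 adapter sequences appended when the fragment
#'   is shorter than the read (defaults: the standard Illumina TruSeq
#'   read-through adapters).
#' @param quality a [sim_quality()].
#' @param shared_error_rate per-fragment-base probability of a
#'   first-strand synthesis error, copied into both reads with
#'   unreduced quality scores.
#' @param n_rate per-read-base probability of masking to `N` (quality 2).
#' @param error_scale multiplier on the per-base independent error rate
#'   (1 = the Phred-implied rate; 0 disables independent errors).
#' @param seed integer seed; identical configs give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(reference = NULL, ref_len = 5000L, n_pairs = 1000L,
                       read_len = 100L, frag_mean = 150, frag_sd = 30,
                       frag_min = 70L, frag_max = 400L,
                       adapter1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                       adapter2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT",
                       quality = sim_quality(), shared_error_rate = 0,
                       n_rate = 3e-4, error_scale = 1, seed = 1L) {
  if (shared_error_rate < 0 || shared_error_rate > 1) {
    stop("shared_error_rate must lie in [0, 1]")
  }
  if (frag_min > frag_max || frag_min < 1) stop("invalid fragment length range")
  cfg <- structure(list(reference = reference, ref_len = as.integer(ref_len),
                        n_pairs = as.integer(n_pairs),
                        read_len = as.integer(read_len),
                        frag_mean = frag_mean, frag_sd = frag_sd,
                        frag_min = as.integer(frag_min),
                        frag_max = as.integer(frag_max),
                        adapter1 = toupper(adapter1),
                        adapter2 = toupper(adapter2), quality = quality,
                        shared_error_rate = shared_error_rate,
                        n_rate = n_rate, error_scale = error_scale,
                        seed = as.integer(seed)),
                   class = "sim_config")
  cfg
}

#' Simulate paired-end reads with known truth
#'
#' For each pair a fragment is drawn from the reference (random
#' position and strand); first-strand (shared) errors are applied to the
#' fragment copy both reads are synthesised from; R1 reads the fragment
#' 5'->3' and R2 its reverse complement, each running into adapter (and
#' `A`-padding) when the fragment is shorter than the read; independent
#' substitution errors are then drawn per base at rate `10^(-q/10)` from
#' that base's quality, choosing uniformly among the 3 alternative
#' bases; finally bases are masked to `N` at `n_rate`.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_reads`: `r1`, `r2` ([fastq_set()]s),
#'   `truth` (data frame: `id`, `frag_start`, `frag_end`, `strand`,
#'   `frag_len`, `dovetail`, `frag_seq` (true fragment on R1's strand),
#'   and comma-separated 1-based position lists `r1_err`, `r2_err`
#'   (independent errors, read coordinates), `r1_n`, `r2_n` (`N` masks)
#'   and `shared` (fragment coordinates)), and `config`.
#' @export
simulate_pairs <- function(config = sim_config()) {
  cfg <- config
  if (is.null(cfg$reference)) {
    set.seed(cfg$seed)
    cfg$reference <- paste(sample(BASES, cfg$ref_len, replace = TRUE),
                           collapse = "")
  }
  genome <- toupper(cfg$reference)
  glen <- nchar(genome)
  if (glen < cfg$frag_max) {
    stop("reference (", glen, " bp) shorter than frag_max (", cfg$frag_max, ")")
  }
  gv <- strsplit(genome, "", fixed = TRUE)[[1L]]
  a1v <- strsplit(cfg$adapter1, "", fixed = TRUE)[[1L]]
  a2v <- strsplit(cfg$adapter2, "", fixed = TRUE)[[1L]]
  rl <- cfg$read_len
  n <- cfg$n_pairs
  r1s <- r2s <- character(n)
  r1q <- r2q <- character(n)
  frag_start <- frag_len <- integer(n)
  strand <- character(n)
  frag_seq <- character(n)
  r1e <- r2e <- r1n <- r2n <- shr <- character(n)
  pad <- rep("A", rl)
  for (i in seq_len(n)) {
    set.seed(pair_seed(cfg$seed, i))
    repeat {
      fl <- as.integer(round(rnorm(1L, cfg$frag_mean, cfg$frag_sd)))
      if (fl >= cfg$frag_min && fl <= cfg$frag_max) break
    }
    st <- sample.int(glen - fl + 1L, 1L)
    sv <- if (runif(1L) < 0.5) "+" else "-"
    frag <- gv[st:(st + fl - 1L)]
    if (sv == "-") frag <- rc_chars(frag)
    synth <- frag
    sh <- which(runif(fl) < cfg$shared_error_rate)
    synth <- mutate_bases(synth, sh)
    t1 <- c(synth, a1v, pad)[seq_len(rl)]
    t2 <- c(rc_chars(synth), a2v, pad)[seq_len(rl)]
    q1 <- draw_quals(cfg$quality, rl)
    q2 <- draw_quals(cfg$quality, rl)
    e1 <- which(runif(rl) < cfg$error_scale * 10^(-q1 / 10))
    e2 <- which(runif(rl) < cfg$error_scale * 10^(-q2 / 10))
    t1 <- mutate_bases(t1, e1)
    t2 <- mutate_bases(t2, e2)
    m1 <- which(runif(rl) < cfg$n_rate)
    m2 <- which(runif(rl) < cfg$n_rate)
    if (length(m1)) { t1[m1] <- "N"; q1[m1] <- 2L }
    if (length(m2)) { t2[m2] <- "N"; q2[m2] <- 2L }
    r1s[i] <- paste(t1, collapse = "")
    r2s[i] <- paste(t2, collapse = "")
    r1q[i] <- intToUtf8(q1 + 33L)
    r2q[i] <- intToUtf8(q2 + 33L)
    frag_start[i] <- st
    frag_len[i] <- fl
    strand[i] <- sv
    frag_seq[i] <- paste(frag, collapse = "")
    r1e[i] <- paste(e1, collapse = ",")
    r2e[i] <- paste(e2, collapse = ",")
    r1n[i] <- paste(m1, collapse = ",")
    r2n[i] <- paste(m2, collapse = ",")
    shr[i] <- paste(sh, collapse = ",")
  }
  ids <- sprintf("sim%06d", seq_len(n))
  truth <- data.frame(
    id = ids, frag_start = frag_start, frag_end = frag_start + frag_len - 1L,
    strand = strand, frag_len = frag_len, dovetail = frag_len < rl,
    frag_seq = frag_seq, r1_err = r1e, r2_err = r2e, r1_n = r1n, r2_n = r2n,
    shared = shr, stringsAsFactors = FALSE)
  structure(list(r1 = fastq_set(paste0(ids, "/1"), r1s, r1q),
                 r2 = fastq_set(paste0(ids, "/2"), r2s, r2q),
                 truth = truth, config = cfg),
            class = "sim_reads")
}

# parse a comma-separated position list back to integers
parse_pos <- function(s) {
  if (is.na(s) || !nzchar(s)) integer() else as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
}

#' Truth classification of overlap columns
#'
#' For each simulated pair, maps every fragment position covered by both
#' reads to whether each read's base is correct there and whether a
#' shared first-strand error sits at that position.
#'
#' @param sim a [simulate_pairs()] result.
#' @param pairs indices of pairs to expand (default all).
#' @return A data frame: `pair`, `frag_pos` (1-based fragment
#'   coordinate), `r1_base`, `r2_base` (both on the fragment strand),
#'   `true_base`, `r1_ok`, `r2_ok`, `shared`.
#' @export
truth_overlap_errors <- function(sim, pairs = seq_len(nrow(sim$truth))) {
  rl <- sim$config$read_len
  out <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    i <- pairs[k]
    fl <- sim$truth$frag_len[i]
    lo <- max(1L, fl - rl + 1L)
    hi <- min(rl, fl)
    if (hi < lo) next
    j <- lo:hi
    fragv <- strsplit(sim$truth$frag_seq[i], "", fixed = TRUE)[[1L]]
    r1v <- strsplit(sim$r1$seq[i], "", fixed = TRUE)[[1L]]
    r2v <- strsplit(sim$r2$seq[i], "", fixed = TRUE)[[1L]]
    b1 <- r1v[j]
    b2 <- unname(COMP[r2v[fl - j + 1L]])  # back onto the fragment strand
    sh <- parse_pos(sim$truth$shared[i])
    out[[k]] <- list(pair = rep.int(i, length(j)), frag_pos = j,
                     r1_base = b1, r2_base = b2, true_base = fragv[j],
                     r1_ok = b1 == fragv[j], r2_ok = b2 == fragv[j],
                     shared = j %in% sh)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  as.data.frame(data.table::rbindlist(out))
}

#' True alignment offset of simulated pairs
#'
#' The offset (rc(R2) 5' end on R1's axis) implied by the true fragment
#' geometry: `frag_len - read_len(R2)`.
#'
#' @param sim a [simulate_pairs()] result.
#' @return Integer vector of offsets (negative for dovetailed pairs).
#' @export
true_offsets <- function(sim) {
  sim$truth$frag_len - nchar(sim$r2$seq)
}

#' Per-quality error tally of the raw (unmerged) reads
#'
#' Compares every fragment-covered read base to the true fragment and
#' tallies bases and errors by the base's quality score.  `N` bases are
#' excluded.  This is the simulator-truth analogue of the baseline
#' error-rate calculation from reference-aligned reads.
#'
#' @param sim a [simulate_pairs()] result.
#' @return A data frame `q`, `bases`, `errors`, `rate`.
#' @export
baseline_tally <- function(sim) {
  rl <- sim$config$read_len
  qmax <- 93L
  bases <- errors <- numeric(qmax + 1L)
  q1l <- quals(sim$r1)
  q2l <- quals(sim$r2)
  for (i in seq_len(nrow(sim$truth))) {
    fl <- sim$truth$frag_len[i]
    m <- min(rl, fl)
    fragv <- strsplit(sim$truth$frag_seq[i], "", fixed = TRUE)[[1L]]
    r1v <- strsplit(sim$r1$seq[i], "", fixed = TRUE)[[1L]]
    r2v <- strsplit(sim$r2$seq[i], "", fixed = TRUE)[[1L]]
    # R1 covers fragment positions 1..m
    b1 <- r1v[seq_len(m)]
    k1 <- b1 != "N"
    q1 <- q1l[[i]][seq_len(m)][k1]
    e1 <- b1[k1] != fragv[seq_len(m)][k1]
    # R2 covers fragment positions fl-m+1..fl; read position j reads
    # fragment position fl - j + 1
    b2 <- unname(COMP[r2v[seq_len(m)]])
    f2 <- fragv[fl - seq_len(m) + 1L]
    k2 <- b2 != "N"
    q2 <- q2l[[i]][seq_len(m)][k2]
    e2 <- b2[k2] != f2[k2]
    t1 <- tabulate(q1 + 1L, qmax + 1L)
    t2 <- tabulate(q2 + 1L, qmax + 1L)
    bases <- bases + t1 + t2
    errors <- errors + tabulate(q1[e1] + 1L, qmax + 1L) +
      tabulate(q2[e2] + 1L, qmax + 1L)
  }
  keep <- bases > 0
  data.frame(q = (0:qmax)[keep], bases = bases[keep], errors = errors[keep],
             rate = errors[keep] / bases[keep])
}
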