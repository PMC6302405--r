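# Precompute merged-quality lookup tables for fast column resolution.
# Returns matrices indexed [q1+1, q2+1] over 0..qtop.  For matrix-kind
# models qtop is the table's own range; qualities beyond it error out at
# lookup (no silent extrapolation).
quality_lookup_tables <- function(model, qtop = QUAL_ABS_MAX) {
  if (model$kind == "matrix") {
    labs <- as.integer(rownames(model$match_matrix))
    if (!identical(labs, seq.int(min(labs), max(labs))) || min(labs) != 0L) {
      # general label sets fall back to per-call lookup
      return(NULL)
    }
    list(match = pmin(model$match_matrix, model$qual_max),
         mismatch = pmin(model$mismatch_matrix, model$qual_max),
         qtop = max(labs))
  } else {
    q <- 0:qtop
    list(
      match = outer(q, q, function(a, b) {
        pmin(merged_quality(model, a, b, TRUE, cap = FALSE), model$qual_max)
      }),
      mismatch = outer(q, q, function(a, b) {
        pmin(merged_quality(model, a, b, FALSE, cap = FALSE), model$qual_max)
      }),
      qtop = qtop
    )
  }
}

#' Resolve one overlap column
#'
#' The rule for a single column of the overlap: agreeing bases keep the
#' base with the match-model quality; disagreeing bases keep the
#' higher-quality base with the mismatch-model quality; a lone `N` is
#' replaced by its mate's base at that base's own quality (an "N
#' corrected"); two `N`s stay `N` at quality 0.  A disagreement between
#' equal-quality bases is ambiguous and yields `N` with the mismatch
#' quality (the difference scheme gives such columns quality 0).
#' Resolved real bases are floored at quality 2.
#'
#' @param b1,b2 the R1 and R2 bases at the column (R2 already
#'   reverse-complemented onto R1's strand).
#' @param q1,q2 their quality scores.
#' @param model a [quality_model()].
#' @return A list `base`, `qual`, `class` (one of `match`, `mismatch`,
#'   `n_resolved`, `n_both`).
#' @export
resolve_position <- function(b1, q1, b2, q2, model = quality_model("fastqjoin")) {
  stopifnot(length(b1) == 1L)
  if (b1 == "N" && b2 == "N") {
    return(list(base = "N", qual = 0L, class = "n_both"))
  }
  if (b1 == "N" || b2 == "N") {
    if (b1 == "N") return(list(base = b2, qual = q2, class = "n_resolved"))
    return(list(base = b1, qual = q1, class = "n_resolved"))
  }
  if (b1 == b2) {
    return(list(base = b1,
                qual = max(2L, as.integer(merged_quality(model, q1, q2, TRUE))),
                class = "match"))
  }
  mq <- as.integer(merged_quality(model, q1, q2, FALSE))
  if (q1 == q2) {
    return(list(base = "N", qual = mq, class = "mismatch"))
  }
  list(base = if (q1 > q2) b1 else b2, qual = max(2L, mq), class = "mismatch")
}

# vectorised column resolution used by stitch(); operates on parallel
# base/quality vectors and the precomputed lookup tables
resolve_columns <- function(b1, qa, b2, qb, lut) {
  n <- length(b1)
  base <- character(n)
  qual <- integer(n)
  cls <- character(n)
  if (any(qa > lut$qtop | qb > lut$qtop)) {
    stop("quality score above the model's supported range (", lut$qtop, ")")
  }
  isn1 <- b1 == "N"; isn2 <- b2 == "N"
  nb <- isn1 & isn2
  nr1 <- isn1 & !isn2
  nr2 <- isn2 & !isn1
  mt <- !isn1 & !isn2 & b1 == b2
  mm <- !isn1 & !isn2 & b1 != b2
  base[nb] <- "N"; qual[nb] <- 0L; cls[nb] <- "n_both"
  base[nr1] <- b2[nr1]; qual[nr1] <- qb[nr1]; cls[nr1] <- "n_resolved"
  base[nr2] <- b1[nr2]; qual[nr2] <- qa[nr2]; cls[nr2] <- "n_resolved"
  if (any(mt)) {
    base[mt] <- b1[mt]
    qual[mt] <- pmax(2L, as.integer(lut$match[cbind(qa[mt] + 1L, qb[mt] + 1L)]))
    cls[mt] <- "match"
  }
  if (any(mm)) {
    mq <- as.integer(lut$mismatch[cbind(qa[mm] + 1L, qb[mm] + 1L)])
    w1 <- qa[mm] > qb[mm]
    tie <- qa[mm] == qb[mm]
    bm <- ifelse(tie, "N", ifelse(w1, b1[mm], b2[mm]))
    base[mm] <- bm
    qual[mm] <- ifelse(tie, mq, pmax(2L, mq))
    cls[mm] <- "mismatch"
  }
  list(base = base, qual = qual, class = cls)
}

#' Stitch one aligned read pair into a merged read
#'
#' Builds the single read spanning from R1's 5' end to R2's 5' end.
#' Non-overlap columns are copied verbatim (the R2 contribution
#' reverse-complemented, qualities reversed); overlap columns go through
#' [resolve_position()]; dovetail 3' overhangs (adapter sequence) are
#' excluded.
#'
#' @param r1_seq,r1_qual,r2_seq,r2_qual sequences and integer quality
#'   vectors of the two reads (original orientations).
#' @param offset the alignment offset (from [find_best_alignment()]).
#' @param model a [quality_model()].
#' @param id identifier for the merged read.
#' @param events log every overlap column?
#' @return A list `merged` (a one-row [fastq_set()]) and `events` (a
#'   data frame of overlap columns: 0-based position in the merged read,
#'   both input bases/quals, the chosen base/qual and the column class),
#'   or `events = NULL` when not requested.
#' @export
stitch <- function(r1_seq, r1_qual, r2_seq, r2_qual, offset,
                   model = quality_model("fastqjoin"), id = "merged",
                   events = FALSE) {
  st <- stitch_pairs(fastq_set(id, r1_seq, list(as.integer(r1_qual))),
                     fastq_set(id, r2_seq, list(as.integer(r2_qual))),
                     data.frame(found = TRUE, offset = as.integer(offset)),
                     model = model,
                     events = if (events) "all" else "none")
  list(merged = st$merged,
       events = if (events) st$events else NULL)
}

#' Stitch many aligned read pairs
#'
#' @param r1,r2 [fastq_set()]s of equal length.
#' @param aln alignment table from [align_pairs()] (columns `found`,
#'   `offset`).
#' @param model a [quality_model()].
#' @param events `"none"` (default), `"diff"` (log only mismatch and `N`
#'   overlap columns, as the `-j`/`-b` log) or `"all"` (log every
#'   overlap column; required for profile training).
#' @return A list: `merged` ([fastq_set()] of the stitched reads),
#'   `merged_idx` (indices of the input pairs that merged), `failed_idx`
#'   (pairs with no qualifying alignment), and `events` (data frame, or
#'   `NULL`).  Event positions are 0-based positions in the merged read;
#'   the merged read id is R1's name with any comment dropped.
#' @export
stitch_pairs <- function(r1, r2, aln, model = quality_model("fastqjoin"),
                         events = c("none", "diff", "all")) {
  events <- match.arg(events)
  stopifnot(nrow(r1) == nrow(r2), nrow(aln) == nrow(r1))
  lut <- quality_lookup_tables(model)
  if (is.null(lut)) stop("matrix model labels must be contiguous from 0")
  idx <- which(aln$found)
  rc2 <- reverse_complement(r2$seq)
  q1l <- quals(r1)
  q2l <- quals(r2)
  nmerged <- length(idx)
  out_seq <- character(nmerged)
  out_qual <- character(nmerged)
  ev <- if (events == "none") NULL else vector("list", nmerged)
  for (k in seq_len(nmerged)) {
    i <- idx[k]
    s1 <- r1$seq[i]
    s2 <- rc2[i]
    len1 <- nchar(s1); len2 <- nchar(s2)
    off <- aln$offset[i]
    q1 <- q1l[[i]]
    q2r <- rev(q2l[[i]])
    lo <- max(0L, off)                      # overlap start, 0-based
    hi <- min(len1, off + len2)             # overlap end, exclusive
    if (hi <= lo || hi - lo < 1L) {
      stop("alignment offset ", off, " inconsistent with read lengths for pair ", i)
    }
    b1 <- strsplit(substr(s1, lo + 1L, hi), "", fixed = TRUE)[[1L]]
    b2 <- strsplit(substr(s2, lo - off + 1L, hi - off), "", fixed = TRUE)[[1L]]
    qa <- q1[(lo + 1L):hi]
    qb <- q2r[(lo - off + 1L):(hi - off)]
    res <- resolve_columns(b1, qa, b2, qb, lut)
    left_seq <- if (lo > 0L) substr(s1, 1L, lo) else ""
    right_seq <- if (hi - off < len2) substr(s2, hi - off + 1L, len2) else ""
    out_seq[k] <- paste0(left_seq, paste(res$base, collapse = ""), right_seq)
    qv <- c(if (lo > 0L) q1[1:lo], res$qual,
            if (hi - off < len2) q2r[(hi - off + 1L):len2])
    out_qual[k] <- encode_quals(list(qv))
    if (!is.null(ev)) {
      keep <- if (events == "all") rep(TRUE, length(res$class))
              else res$class != "match"
      if (any(keep)) {
        ev[[k]] <- list(pair = rep.int(i, sum(keep)),
                        pos = (lo:(hi - 1L))[keep],
                        r1_base = b1[keep], r1_qual = qa[keep],
                        r2_base = b2[keep], r2_qual = qb[keep],
                        base = res$base[keep], qual = res$qual[keep],
                        class = res$class[keep])
      }
    }
  }
  merged <- fastq_set(sub("[ \t].*$", "", r1$id[idx]), out_seq, out_qual)
  evdf <- NULL
  if (!is.null(ev)) {
    ev <- ev[!vapply(ev, is.null, logical(1))]
    evdf <- if (length(ev)) {
      as.data.frame(data.table::rbindlist(ev))
    } else {
      data.frame(pair = integer(), pos = integer(), r1_base = character(),
                 r1_qual = integer(), r2_base = character(),
                 r2_qual = integer(), base = character(), qual = integer(),
                 class = character())
    }
    evdf$id <- sub("[ \t].*$", "", r1$id[evdf$pair])
  }
  list(merged = merged, merged_idx = idx,
       failed_idx = which(!aln$found), events = evdf)
}

#' Remove 3' adapter overhangs from dovetailed pairs
#'
#' Pairs whose optimal alignment is dovetailed have read 3' ends that
#' extend past the mate's 5' end; those overhangs are adapter sequence
#' and are clipped.  Non-dovetailed or unaligned pairs are returned
#' unchanged.  The operation is idempotent.
#'
#' @param r1,r2 [fastq_set()]s.
#' @param aln alignment table from [align_pairs()] run with
#'   `allow_dovetail = TRUE`.
#' @return A list `r1`, `r2` of clipped [fastq_set()]s and `clipped`,
#'   the indices of modified pairs.
#' @export
remove_adapters <- function(r1, r2, aln) {
  stopifnot(nrow(r1) == nrow(r2), nrow(aln) == nrow(r1))
  len1 <- nchar(r1$seq)
  len2 <- nchar(r2$seq)
  dove <- !is.na(aln$found) & aln$found &
    offset_is_dovetail(ifelse(is.na(aln$offset), 0L, aln$offset), len1, len2)
  clip <- which(dove)
  for (i in clip) {
    off <- aln$offset[i]
    keep1 <- min(len1[i], off + len2[i])     # R1 keeps up to mate's 5' end
    keep2 <- len2[i] - max(0L, -off)         # R2 loses bases left of R1's 5'
    r1$seq[i] <- substr(r1$seq[i], 1L, keep1)
    r1$qual[i] <- substr(r1$qual[i], 1L, keep1)
    r2$seq[i] <- substr(r2$seq[i], 1L, keep2)
    r2$qual[i] <- substr(r2$qual[i], 1L, keep2)
  }
  list(r1 = r1, r2 = r2, clipped = clip)
}

#' Align and merge paired reads (stitch mode)
#'
#' Convenience wrapper: [align_pairs()] then [stitch_pairs()].
#'
#' @param r1,r2 [fastq_set()]s.
#' @param params an [align_params()].
#' @param model a [quality_model()].
#' @param events event logging mode (see [stitch_pairs()]).
#' @return As [stitch_pairs()], plus the alignment table `aln` and a
#'   `stats` list (pairs, merged, failed, ns_corrected).
#' @export
merge_pairs <- function(r1, r2, params = align_params(),
                        model = quality_model("fastqjoin"),
                        events = "none") {
  aln <- align_pairs(r1, r2, params)
  st <- stitch_pairs(r1, r2, aln, model = model, events = events)
  ns <- if (!is.null(st$events)) sum(st$events$class == "n_resolved") else NA_integer_
  st$aln <- aln
  st$stats <- list(pairs = nrow(r1), merged = length(st$merged_idx),
                   failed = length(st$failed_idx), ns_corrected = ns)
  st
}
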