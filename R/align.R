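#' Alignment parameters
#'
#' Parameters of the exhaustive gapless overlap search.  Defaults mirror
#' the tool's command-line defaults: a minimum overlap of 20 bp and at
#' most 10% mismatches in the overlap region (`-m 20 -p 0.1`); dovetailed
#' configurations are only considered with `allow_dovetail = TRUE`
#' (`-d`), and always in adapter-removal mode.
#'
#' @param min_overlap minimum geometric overlap length in bp (counts all
#'   overlap columns, including `N` columns); must be >= 1.
#' @param max_mismatch_frac maximum fraction of mismatched columns among
#'   non-`N` overlap columns, in \[0, 1\].
#' @param allow_dovetail consider alignments in which a read's 3' end
#'   extends past its mate's 5' end (adapter read-through).
#' @return A list of class `align_params`.
#' @export
align_params <- function(min_overlap = 20L, max_mismatch_frac = 0.1,
                         allow_dovetail = FALSE) {
  min_overlap <- as.integer(min_overlap)
  if (is.na(min_overlap) || min_overlap < 1L) {
    stop("min_overlap must be an integer >= 1")
  }
  if (!is.numeric(max_mismatch_frac) || is.na(max_mismatch_frac) ||
      max_mismatch_frac < 0 || max_mismatch_frac > 1) {
    stop("max_mismatch_frac must lie in [0, 1]")
  }
  structure(list(min_overlap = min_overlap,
                 max_mismatch_frac = max_mismatch_frac,
                 allow_dovetail = isTRUE(allow_dovetail)),
            class = "align_params")
}

# dovetail predicate on the offset geometry
offset_is_dovetail <- function(offset, len1, len2) {
  offset < 0L | (len1 - offset) > len2
}

# geometric overlap implied by an offset
offset_overlap_len <- function(offset, len1, len2) {
  pmin(len1, offset + len2) - pmax(0L, offset)
}

#' Enumerate candidate alignment offsets
#'
#' All relative placements of the reverse-complemented R2 on R1 whose
#' geometric overlap reaches `min_overlap`.  Offsets are 0-based
#' positions of rc(R2)'s 5' end on R1's axis; negative offsets and
#' offsets leaving an R1 3' overhang are dovetailed and only returned
#' when `params$allow_dovetail` is set.
#'
#' @param len1,len2 read lengths in bp.
#' @param params an [align_params()].
#' @return Sorted integer vector of offsets (possibly empty).
#' @export
enumerate_offsets <- function(len1, len2, params = align_params()) {
  len1 <- as.integer(len1); len2 <- as.integer(len2)
  if (len1 < 1L || len2 < 1L) stop("read lengths must be >= 1")
  cand <- seq.int(params$min_overlap - len2, len1 - params$min_overlap)
  if (length(cand) == 0L) return(integer())
  keep <- offset_overlap_len(cand, len1, len2) >= params$min_overlap
  if (!params$allow_dovetail) {
    keep <- keep & !offset_is_dovetail(cand, len1, len2)
  }
  cand[keep]
}

#' Score one overlap placement
#'
#' Counts matches, mismatches and `N` columns over the overlap implied by
#' `offset`.  A column in which either read has `N` is neither a match
#' nor a mismatch; it increments `n_positions` only.
#'
#' @param seq1 R1 sequence.
#' @param rc2 reverse complement of the R2 sequence.
#' @param offset candidate offset (see [enumerate_offsets()]).
#' @return Named integer vector `matches`, `mismatches`, `n_positions`,
#'   `overlap_len`.
#' @export
score_overlap <- function(seq1, rc2, offset) {
  cpp_score_overlap(seq1, rc2, as.integer(offset))
}

# assemble an alignment result row list from counts
alignment_result <- function(offset, overlap_len, matches, mismatches,
                             n_positions, len1, len2) {
  den <- matches + mismatches
  structure(list(
    offset = offset, overlap_len = overlap_len, matches = matches,
    mismatches = mismatches, n_positions = n_positions,
    mismatch_frac = if (den > 0L) mismatches / den else 0,
    dovetail = offset_is_dovetail(offset, len1, len2)
  ), class = "alignment_result")
}

#' Find the best gapless alignment of one read pair
#'
#' Scans every candidate offset and returns the placement with the lowest
#' mismatch fraction among those with overlap >= `min_overlap` and
#' mismatch fraction <= `max_mismatch_frac`.  Ties are broken toward the
#' larger overlap, then the smaller absolute offset, then the
#' non-negative offset.
#'
#' @param r1_seq,r2_seq the two read sequences (R2 in its original
#'   orientation; it is reverse-complemented internally).
#' @param params an [align_params()].
#' @return An `alignment_result` (offset, overlap_len, matches,
#'   mismatches, n_positions, mismatch_frac, dovetail) or `NULL` when no
#'   placement qualifies.
#' @export
find_best_alignment <- function(r1_seq, r2_seq, params = align_params()) {
  res <- align_pairs(r1_seq, r2_seq, params)
  if (!res$found[1L]) return(NULL)
  alignment_result(res$offset[1L], res$overlap_len[1L], res$matches[1L],
                   res$mismatches[1L], res$n_positions[1L],
                   nchar(r1_seq), nchar(r2_seq))
}

#' Align many read pairs
#'
#' Vectorised exhaustive alignment over parallel vectors of sequences
#' (or two [fastq_set()]s).
#'
#' @param r1,r2 character vectors of R1/R2 sequences, or `fastq_set`s.
#' @param params an [align_params()].
#' @return A data frame with one row per pair: `found`, `offset`,
#'   `overlap_len`, `matches`, `mismatches`, `n_positions`,
#'   `mismatch_frac`, `dovetail` (the last columns are `NA` where
#'   `found` is `FALSE`).
#' @export
align_pairs <- function(r1, r2, params = align_params()) {
  s1 <- if (is.data.frame(r1)) r1$seq else r1
  s2 <- if (is.data.frame(r2)) r2$seq else r2
  if (length(s1) != length(s2)) stop("r1 and r2 must have equal length")
  rc2 <- reverse_complement(s2)
  res <- cpp_best_alignments(s1, rc2, params$min_overlap,
                             params$max_mismatch_frac,
                             params$allow_dovetail)
  den <- res$matches + res$mismatches
  out <- data.frame(
    found = res$found, offset = res$offset, overlap_len = res$overlap_len,
    matches = res$matches, mismatches = res$mismatches,
    n_positions = res$n_positions,
    mismatch_frac = ifelse(is.na(den) | den == 0L, ifelse(res$found, 0, NA),
                           res$mismatches / den),
    dovetail = ifelse(res$found,
                      offset_is_dovetail(res$offset, nchar(s1), nchar(s2)),
                      NA)
  )
  out
}
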