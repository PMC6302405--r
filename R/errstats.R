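#' The five observed PhiX genome variants
#'
#' Sequence variants from the canonical NCBI PhiX reference
#' (NC_001422.1) observed at >= 95% allele frequency in control
#' sequencing runs.  Positions are 1-based.  Correcting the reference
#' for these removes most of the apparent inflation of high-end quality
#' scores.
#'
#' @return A data frame `position`, `ref`, `alt`.
#' @export
phix_variants <- function() {
  data.frame(position = c(587L, 833L, 2731L, 2811L, 3133L),
             ref = c("G", "G", "A", "C", "C"),
             alt = c("A", "A", "G", "T", "T"),
             stringsAsFactors = FALSE)
}

#' Apply substitution variants to a genome
#'
#' Each edit's reference base is verified against the genome before any
#' substitution is made; the sequence length is unchanged.
#'
#' @param genome character string (the sequence).
#' @param edits data frame with columns `position` (1-based), `ref`,
#'   `alt`; default [phix_variants()].
#' @return The edited sequence.
#' @export
apply_variants <- function(genome, edits = phix_variants()) {
  genome <- toupper(genome)
  n <- nchar(genome)
  if (nrow(edits) == 0L) return(genome)
  if (any(edits$position < 1L | edits$position > n)) {
    stop("edit position outside the genome (length ", n, ")")
  }
  have <- substring(genome, edits$position, edits$position)
  bad <- have != toupper(edits$ref)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("reference base mismatch at position ", edits$position[i],
         ": genome has ", have[i], ", edit expects ", edits$ref[i])
  }
  for (i in seq_len(nrow(edits))) {
    substr(genome, edits$position[i], edits$position[i]) <- toupper(edits$alt[i])
  }
  genome
}

#' Circularly extend a genome
#'
#' Appends the first `ext_len` bases to the end, so alignments spanning
#' the origin of a circular genome are representable linearly.  For the
#' 5386-bp PhiX genome and the default 1-kb extension the result is
#' 6386 bp.
#'
#' @param genome character string.
#' @param ext_len extension length in bp (default 1000); must not exceed
#'   the genome length.
#' @return The extended sequence.
#' @export
circular_extend <- function(genome, ext_len = 1000L) {
  n <- nchar(genome)
  ext_len <- as.integer(ext_len)
  if (ext_len < 0L || ext_len > n) {
    stop("ext_len must lie in [0, ", n, "]")
  }
  if (ext_len == 0L) return(genome)
  paste0(genome, substr(genome, 1L, ext_len))
}

#' Synthetic stand-in for the PhiX control genome
#'
#' A deterministic 5386-bp sequence with the canonical NCBI reference
#' bases placed at the five variant positions of [phix_variants()].  It
#' is NOT the real NC_001422.1 sequence -- it exists so the
#' variant-correction and circular-extension pipeline can run and be
#' tested without downloading the accession.  Substitute the real FASTA
#' (e.g. via [read_fasta_seq()]) for genuine PhiX analyses.
#'
#' @return A character string of length 5386.
#' @export
synthetic_phix_genome <- function() {
  n <- 5386L
  # minimal-standard Lehmer generator; independent of R's RNG state
  x <- 20181220
  m <- 2147483647
  v <- integer(n)
  for (i in seq_len(n)) {
    x <- (16807 * x) %% m
    v[i] <- x %% 4L
  }
  g <- paste(BASES[v + 1L], collapse = "")
  for (i in seq_len(nrow(phix_variants()))) {
    ed <- phix_variants()[i, ]
    substr(g, ed$position, ed$position) <- ed$ref
  }
  g
}

#' Read one sequence from a FASTA file
#'
#' @param path FASTA file (Biostrings handles plain or gzipped input).
#' @param which index or name of the record (default first).
#' @return Character string of the sequence, named by its FASTA header.
#' @export
read_fasta_seq <- function(path, which = 1L) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss[[which]]), names(ss)[which])
}

#' Write a sequence to a FASTA file
#'
#' @param seq character string.
#' @param path output path.
#' @param name FASTA header.
#' @return Invisibly, `path`.
#' @export
write_fasta_seq <- function(seq, path, name = "seq") {
  ss <- Biostrings::DNAStringSet(seq)
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---- SAM handling -----------------------------------------------------

# parse the mandatory fields of a plain-text SAM file
parse_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      cigar = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(f) < 11L
  if (any(short)) {
    stop("malformed SAM record at data line ", which(short)[1L], " of '",
         path, "'")
  }
  data.frame(qname = vapply(f, `[[`, "", 1L),
             flag = as.integer(vapply(f, `[[`, "", 2L)),
             rname = vapply(f, `[[`, "", 3L),
             pos = as.integer(vapply(f, `[[`, "", 4L)),
             cigar = vapply(f, `[[`, "", 6L),
             seq = toupper(vapply(f, `[[`, "", 10L)),
             qual = vapply(f, `[[`, "", 11L), stringsAsFactors = FALSE)
}

read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("BAM input requires the Rsamtools package; supply SAM text instead")
    }
    b <- Rsamtools::scanBam(path)[[1L]]
    return(data.frame(qname = b$qname, flag = b$flag,
                      rname = as.character(b$rname), pos = b$pos,
                      cigar = b$cigar, seq = as.character(b$seq),
                      qual = as.character(b$qual), stringsAsFactors = FALSE))
  }
  parse_sam(path)
}

# expand a CIGAR string into op letters and lengths
parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  if (m[1L] == -1L) stop("unparsable CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  list(op = substring(toks, nchar(toks), nchar(toks)),
       len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

#' Per-quality-score error rates from SAM alignments
#'
#' Walks every aligned (non-clipped, non-inserted) base of the mapped
#' records, compares it to the reference, and tallies bases and errors
#' (base != reference) by the base's quality score.  Records must be
#' mapped, and properly paired when they carry the paired flag;
#' insertions and soft-clips are excluded and deletions are not counted
#' as base errors.  With a merge event log and the original read
#' lengths, overlap columns of merged reads are additionally split into
#' match / mismatch / N classes.
#'
#' @param path SAM (text) or BAM file of alignments.
#' @param reference reference sequence: a character string, or a named
#'   vector matched against the records' reference names.
#' @param event_log optional event table (from [stitch_pairs()], modes
#'   `"diff"`/`"all"`, or read back from the `-j` TSV): columns `id`,
#'   `pos`, `class`.
#' @param read_lengths optional integer vector `c(len1, len2)` of the
#'   original read lengths, required with `event_log` to locate the
#'   overlap region inside each merged read.
#' @param offset Phred ASCII offset of the SAM qualities.
#' @return A list: `per_q` (data frame `q`, `bases`, `errors`, `rate`)
#'   and, when the event log is given, `per_class` (the same split by
#'   overlap column class, plus `nonoverlap`).
#' @export
count_errors_by_quality <- function(path, reference, event_log = NULL,
                                    read_lengths = NULL, offset = 33L) {
  recs <- read_alignments(path)
  mapped <- bitwAnd(recs$flag, 4L) == 0L
  paired <- bitwAnd(recs$flag, 1L) != 0L
  proper <- bitwAnd(recs$flag, 2L) != 0L
  recs <- recs[mapped & (!paired | proper), , drop = FALSE]
  if (nrow(recs) == 0L) {
    warning("no mapped (properly-paired) records in '", path, "'")
    empty <- data.frame(q = integer(), bases = numeric(), errors = numeric(),
                        rate = numeric())
    return(list(per_q = empty, per_class = NULL))
  }
  if (!is.null(event_log) && is.null(read_lengths)) {
    stop("read_lengths (len1, len2) are required with an event_log")
  }
  classes <- c("match", "mismatch", "n", "nonoverlap")
  qmax <- QUAL_ABS_MAX
  bases <- errors <- numeric(qmax + 1L)
  cb <- ce <- matrix(0, nrow = length(classes), ncol = qmax + 1L,
                     dimnames = list(classes, 0:qmax))
  ev_by_id <- NULL
  if (!is.null(event_log)) {
    ev_by_id <- split(event_log[, c("pos", "class")], event_log$id)
  }
  for (i in seq_len(nrow(recs))) {
    ref <- if (length(reference) > 1L || !is.null(names(reference))) {
      r <- reference[recs$rname[i]]
      if (is.na(r)) next
      r
    } else reference
    cg <- parse_cigar(recs$cigar[i])
    sv <- strsplit(recs$seq[i], "", fixed = TRUE)[[1L]]
    qv <- utf8ToInt(recs$qual[i]) - as.integer(offset)
    L <- length(sv)
    revstrand <- bitwAnd(recs$flag[i], 16L) != 0L
    qp <- 1L
    rp <- recs$pos[i]
    qpos_cls <- NULL
    if (!is.null(ev_by_id)) {
      # class of each merged-read coordinate (0-based, original
      # orientation): overlap spans [L - len2, len1)
      qpos_cls <- rep("nonoverlap", L)
      ov <- seq.int(max(0L, L - read_lengths[2L]),
                    min(L, read_lengths[1L]) - 1L)
      qpos_cls[ov + 1L] <- "match"
      evs <- ev_by_id[[recs$qname[i]]]
      if (!is.null(evs)) {
        cls <- ifelse(startsWith(evs$class, "n"), "n", evs$class)
        qpos_cls[evs$pos + 1L] <- cls
      }
    }
    for (k in seq_along(cg$op)) {
      op <- cg$op[k]; len <- cg$len[k]
      if (op %in% c("M", "=", "X")) {
        qi <- qp:(qp + len - 1L)
        rb <- strsplit(substr(ref, rp, rp + len - 1L), "", fixed = TRUE)[[1L]]
        err <- sv[qi] != rb
        qq <- qv[qi]
        bases <- bases + tabulate(qq + 1L, qmax + 1L)
        errors <- errors + tabulate(qq[err] + 1L, qmax + 1L)
        if (!is.null(qpos_cls)) {
          # map SAM orientation back to the merged read's own coordinates
          mpos <- if (revstrand) L - qi else qi - 1L
          cl <- qpos_cls[mpos + 1L]
          for (cname in classes) {
            sel <- cl == cname
            if (any(sel)) {
              cb[cname, ] <- cb[cname, ] + tabulate(qq[sel] + 1L, qmax + 1L)
              ce[cname, ] <- ce[cname, ] + tabulate(qq[sel & err] + 1L, qmax + 1L)
            }
          }
        }
        qp <- qp + len; rp <- rp + len
      } else if (op %in% c("I", "S")) {
        qp <- qp + len
      } else if (op %in% c("D", "N")) {
        rp <- rp + len
      }
    }
  }
  keep <- bases > 0
  per_q <- data.frame(q = (0:qmax)[keep], bases = bases[keep],
                      errors = errors[keep],
                      rate = errors[keep] / bases[keep])
  per_class <- NULL
  if (!is.null(ev_by_id)) {
    per_class <- do.call(rbind, lapply(classes, function(cn) {
      k <- cb[cn, ] > 0
      if (!any(k)) return(NULL)
      data.frame(class = cn, q = (0:qmax)[k], bases = cb[cn, k],
                 errors = ce[cn, k], rate = ce[cn, k] / cb[cn, k])
    }))
    rownames(per_class) <- NULL
  }
  list(per_q = per_q, per_class = per_class)
}
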