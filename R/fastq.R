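#' Construct a set of FASTQ records
#'
#' A `fastq_set` is the package's in-memory representation of sequencing
#' reads: a data frame with columns `id` (read identifier, the text after
#' `@`), `seq` (upper-case bases over `A`,`C`,`G`,`T`,`N`) and `qual`
#' (per-base Phred quality scores, stored as an ASCII-encoded string at a
#' fixed offset so that a record is a single row).  Use [quals()] to
#' recover integer quality vectors and [encode_quals()] to build the
#' encoded strings from integers.
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of base strings; lower case is accepted and
#'   uppercased.
#' @param qual either a character vector of offset-encoded quality strings
#'   or a list of integer vectors (one per read, values 0-93).
#' @param offset integer ASCII offset used when `qual` is given as integer
#'   vectors (default 33, i.e. Phred+33).
#' @return A data frame of class `fastq_set`.
#' @examples
#' fq <- fastq_set("r1", "ACGT", list(c(40L, 40L, 40L, 40L)))
#' quals(fq)[[1]]
#' @export
fastq_set <- function(id, seq, qual, offset = 33L) {
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("invalid base characters in sequence(s): ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  if (is.list(qual)) {
    qual <- encode_quals(qual, offset = offset)
  }
  if (!is.character(qual)) stop("'qual' must be a character vector or a list of integer vectors")
  if (length(id) != length(seq) || length(seq) != length(qual)) {
    stop("id, seq and qual must have equal lengths")
  }
  if (any(nchar(seq) != nchar(qual))) {
    stop("sequence and quality lengths differ for record(s): ",
         paste(utils::head(which(nchar(seq) != nchar(qual)), 3L), collapse = ", "))
  }
  structure(
    data.frame(id = as.character(id), seq = seq, qual = qual,
               stringsAsFactors = FALSE),
    class = c("fastq_set", "data.frame")
  )
}

#' Decode per-read quality strings to integer vectors
#'
#' @param x a `fastq_set`.
#' @param offset ASCII offset of the encoding (default 33).
#' @return A list of integer vectors, one per read.
#' @export
quals <- function(x, offset = 33L) {
  lapply(x$qual, function(s) utf8ToInt(s) - as.integer(offset))
}

#' Encode integer quality vectors as ASCII strings
#'
#' @param q a list of integer vectors (or a single integer vector).
#' @param offset ASCII offset (default 33).
#' @return Character vector of encoded quality strings.
#' @export
encode_quals <- function(q, offset = 33L) {
  if (!is.list(q)) q <- list(q)
  vapply(q, function(v) {
    v <- as.integer(v)
    if (length(v) == 0L) return("")
    if (any(v < 0L | v > QUAL_ABS_MAX)) {
      stop("quality scores must lie in [0, ", QUAL_ABS_MAX, "]")
    }
    intToUtf8(v + as.integer(offset))
  }, character(1))
}

# open a connection that transparently handles gzip (gzfile sniffs the
# magic bytes and reads plain text unchanged)
open_text <- function(path) {
  con <- gzfile(path, open = "rt")
  con
}

#' Read a FASTQ file
#'
#' Reads a 4-line-per-record FASTQ file, plain or gzip-compressed
#' (detected from the file content, not the name).  Sequences are
#' uppercased; qualities are validated against the offset and stored
#' encoded.
#'
#' @param path path to the FASTQ file.
#' @param offset Phred ASCII offset (default 33).
#' @return A [fastq_set()].
#' @export
read_fastq <- function(path, offset = 33L) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record in '", path, "': file has ", n,
         " lines (line ", (n %/% 4L) * 4L + 1L, " starts an incomplete record)")
  }
  if (n == 0L) return(fastq_set(character(), character(), character()))
  hdr <- lines[seq(1L, n, by = 4L)]
  seq <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad_hdr <- !startsWith(hdr, "@")
  if (any(bad_hdr)) {
    stop("malformed FASTQ header at line ",
         (which(bad_hdr)[1L] - 1L) * 4L + 1L, " of '", path, "'")
  }
  bad_plus <- !startsWith(plus, "+")
  if (any(bad_plus)) {
    stop("malformed FASTQ separator at line ",
         (which(bad_plus)[1L] - 1L) * 4L + 3L, " of '", path, "'")
  }
  if (any(nchar(seq) != nchar(qual))) {
    i <- which(nchar(seq) != nchar(qual))[1L]
    stop("sequence/quality length mismatch in record ", i, " of '", path, "'")
  }
  # validate encoding: no quality character may fall below the offset
  minchar <- min(vapply(qual[nchar(qual) > 0L],
                        function(s) min(utf8ToInt(s)), integer(1)),
                 QUAL_ABS_MAX + as.integer(offset))
  if (minchar < offset) {
    stop("quality character below ASCII offset ", offset, " in '", path,
         "': is the file Phred+", offset, "?")
  }
  if (offset != 33L) {
    # records are stored Phred+33 internally
    qual <- encode_quals(lapply(qual, function(s) utf8ToInt(s) - as.integer(offset)))
  }
  fastq_set(sub("^@", "", hdr), seq, qual)
}

# strip a trailing pair suffix ("/1", "/2", ".1", ".2") or a
# space-delimited comment from a read identifier
strip_pair_suffix <- function(id) {
  id <- sub("[ \t].*$", "", id)
  sub("[/.][12]$", "", id)
}

#' Read paired FASTQ files
#'
#' Reads two FASTQ files in parallel and checks that the files pair up:
#' equal record counts and matching read names after stripping one
#' trailing `/1`-`/2` (or `.1`-`.2`) suffix or a space-delimited comment.
#'
#' @param path1,path2 the R1 and R2 FASTQ files (plain or gzipped).
#' @param offset Phred ASCII offset (default 33).
#' @return A list with elements `r1` and `r2`, both [fastq_set()]s of
#'   equal length.
#' @export
read_fastq_pairs <- function(path1, path2, offset = 33L) {
  r1 <- read_fastq(path1, offset = offset)
  r2 <- read_fastq(path2, offset = offset)
  if (nrow(r1) != nrow(r2)) {
    stop("pairing error: ", nrow(r1), " records in '", path1, "' vs ",
         nrow(r2), " in '", path2, "'")
  }
  n1 <- strip_pair_suffix(r1$id)
  n2 <- strip_pair_suffix(r2$id)
  if (any(n1 != n2)) {
    i <- which(n1 != n2)[1L]
    stop("pairing error at record ", i, ": read names '", r1$id[i],
         "' and '", r2$id[i], "' do not match")
  }
  list(r1 = r1, r2 = r2)
}

#' Read an interleaved paired FASTQ file
#'
#' R1/R2 records alternate in a single file.
#'
#' @inheritParams read_fastq
#' @return As [read_fastq_pairs()].
#' @export
read_fastq_interleaved <- function(path, offset = 33L) {
  all <- read_fastq(path, offset = offset)
  if (nrow(all) %% 2L != 0L) {
    stop("interleaved file '", path, "' has an odd number of records")
  }
  i1 <- seq(1L, nrow(all), by = 2L)
  r1 <- all[i1, , drop = FALSE]
  r2 <- all[i1 + 1L, , drop = FALSE]
  n1 <- strip_pair_suffix(r1$id)
  n2 <- strip_pair_suffix(r2$id)
  if (any(n1 != n2)) {
    i <- which(n1 != n2)[1L]
    stop("pairing error at interleaved pair ", i, ": '", r1$id[i],
         "' vs '", r2$id[i], "'")
  }
  rownames(r1) <- rownames(r2) <- NULL
  list(r1 = structure(r1, class = c("fastq_set", "data.frame")),
       r2 = structure(r2, class = c("fastq_set", "data.frame")))
}

#' Write a FASTQ file
#'
#' Writes 4-line records; the output is bit-compatible with standard
#' FASTQ parsers and round-trips through [read_fastq()].
#'
#' @param x a [fastq_set()].
#' @param path output path; a name ending in `.gz` is written
#'   gzip-compressed.
#' @param offset Phred ASCII offset (default 33).  Records are stored at
#'   offset 33 internally; a different offset re-encodes on the fly.
#' @return Invisibly, the number of records written.
#' @export
write_fastq <- function(x, path, offset = 33L) {
  qual <- x$qual
  if (offset != 33L) {
    qual <- encode_quals(quals(x), offset = offset)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(x) > 0L) {
    out <- character(4L * nrow(x))
    out[seq(1L, length(out), 4L)] <- paste0("@", x$id)
    out[seq(2L, length(out), 4L)] <- x$seq
    out[seq(3L, length(out), 4L)] <- "+"
    out[seq(4L, length(out), 4L)] <- qual
    writeLines(out, con)
  }
  invisible(nrow(x))
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed; `N` maps to `N`.  Vectorised over
#' input strings (delegates to Biostrings).
#'
#' @param seq character vector over the alphabet `A`,`C`,`G`,`T`,`N`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AANC")  # "GNTT"
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character())
  if (any(grepl("[^ACGTNacgtn]", seq))) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(seq))))
}
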