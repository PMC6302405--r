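#' Convert a Phred quality score to an error probability
#'
#' `Q = -10 * log10(P)`, so `P = 10^(-Q/10)`: a Q40 base should be wrong
#' 1 time in 10,000.
#'
#' @param q non-negative quality score(s); need not be integer.
#' @return Error probabilities in (0, 1\].
#' @examples
#' qual_to_error(40)  # 1e-4
#' @export
qual_to_error <- function(q) {
  if (any(q < 0)) stop("quality scores must be non-negative")
  10^(-q / 10)
}

#' Convert an error probability to a Phred quality score
#'
#' Inverse of [qual_to_error()]: `Q = -10 * log10(P)`.
#'
#' @param p probabilities in (0, 1\].
#' @return Quality scores (real-valued).
#' @export
error_to_qual <- function(p) {
  if (any(p <= 0 | p > 1)) stop("probabilities must lie in (0, 1]")
  -10 * log10(p)
}

#' Merged-base quality model
#'
#' A rule mapping the two reads' quality scores and whether their bases
#' agree to the merged base's quality score.  Three kinds are supported:
#'
#' * `"fastqjoin"` -- the difference scheme: the higher score on a match,
#'   the absolute difference on a mismatch.  Conservative over most of
#'   the score range; the package default.
#' * `"sum"` -- scores add on a match (the independence model, under
#'   which the merged base is wrong only if both reads are wrong); on a
#'   mismatch the surviving base keeps the higher score, approximating
#'   schemes that do not reduce mismatch qualities.
#' * `"matrix"` -- empirical match/mismatch lookup tables, typically
#'   trained with [build_matrices()] or loaded from files with
#'   [quality_model_from_files()].
#'
#' @param kind one of `"fastqjoin"`, `"sum"`, `"matrix"`.
#' @param match_matrix,mismatch_matrix numeric matrices indexed by
#'   (R1 quality, R2 quality), with dimnames giving the quality labels;
#'   required for `kind = "matrix"`.
#' @param qual_max cap applied to output qualities; defaults to 40 for
#'   `fastqjoin`/`matrix` and 80 for `sum`.
#' @return A list of class `quality_model`.
#' @export
quality_model <- function(kind = c("fastqjoin", "sum", "matrix"),
                          match_matrix = NULL, mismatch_matrix = NULL,
                          qual_max = NULL) {
  kind <- match.arg(kind)
  if (is.null(qual_max)) qual_max <- if (kind == "sum") 80L else 40L
  qual_max <- as.integer(qual_max)
  if (qual_max < 2L || qual_max > QUAL_ABS_MAX) {
    stop("qual_max must lie in [2, ", QUAL_ABS_MAX, "]")
  }
  if (kind == "matrix") {
    for (m in list(match_matrix, mismatch_matrix)) {
      if (is.null(m) || !is.matrix(m) || is.null(rownames(m)) ||
          is.null(colnames(m))) {
        stop("matrix models need match and mismatch matrices with quality dimnames")
      }
    }
    if (!identical(dim(match_matrix), dim(mismatch_matrix))) {
      stop("match and mismatch matrices must have identical shape")
    }
  } else {
    match_matrix <- mismatch_matrix <- NULL
  }
  structure(list(kind = kind, match_matrix = match_matrix,
                 mismatch_matrix = mismatch_matrix, qual_max = qual_max),
            class = "quality_model")
}

# matrix lookup with an explicit range check: no silent extrapolation
matrix_lookup <- function(m, q1, q2) {
  i <- match(as.character(q1), rownames(m))
  j <- match(as.character(q2), colnames(m))
  if (any(is.na(i)) || any(is.na(j))) {
    bad <- which(is.na(i) | is.na(j))[1L]
    stop("quality pair (", q1[bad], ", ", q2[bad],
         ") outside the model's matrix range [", rownames(m)[1L], ", ",
         rownames(m)[nrow(m)], "]")
  }
  m[cbind(i, j)]
}

#' Merged quality score for one overlap column
#'
#' Applies the model's rule for a column where the reads' bases agree
#' (`is_match = TRUE`) or disagree.  Vectorised over `q1`, `q2`.
#'
#' @param model a [quality_model()].
#' @param q1,q2 the R1 and R2 base quality scores.
#' @param is_match do the two bases agree?
#' @param cap apply the model's `qual_max` cap (set `FALSE` to inspect
#'   the raw rule value).
#' @return Merged quality score(s); integer-valued for integer inputs.
#' @examples
#' merged_quality(quality_model("fastqjoin"), 40, 40, TRUE)  # 40
#' merged_quality(quality_model("sum"), 40, 40, TRUE)        # 80
#' @export
merged_quality <- function(model, q1, q2, is_match, cap = TRUE) {
  if (any(q1 < 0) || any(q2 < 0)) stop("quality scores must be non-negative")
  n <- max(length(q1), length(q2), length(is_match))
  q1 <- rep_len(q1, n); q2 <- rep_len(q2, n)
  is_match <- rep_len(is_match, n)
  out <- switch(model$kind,
    fastqjoin = ifelse(is_match, pmax(q1, q2), abs(q1 - q2)),
    sum = ifelse(is_match, q1 + q2, pmax(q1, q2)),
    matrix = ifelse(is_match,
                    matrix_lookup(model$match_matrix, q1, q2),
                    matrix_lookup(model$mismatch_matrix, q1, q2))
  )
  out <- pmax(out, 0)
  if (cap) out <- pmin(out, model$qual_max)
  out
}

#' Read a quality-profile matrix file
#'
#' Format: lines starting with `#` are comments; the first non-comment
#' line is a tab-separated header of R2 quality labels; each following
#' line is an R1 quality label followed by one value per R2 quality.
#'
#' @param path path to the matrix file.
#' @return A numeric matrix with quality-label dimnames.
#' @export
read_matrix_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) {
    stop("matrix file '", path, "': missing header or data rows")
  }
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (anyNA(suppressWarnings(as.numeric(hdr)))) {
    stop("matrix file '", path, "': header at line ", lineno[1L],
         " must be numeric quality labels")
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != length(hdr) + 1L)) {
    bad <- which(widths != length(hdr) + 1L)[1L]
    stop("matrix file '", path, "': line ", lineno[bad + 1L], " has ",
         widths[bad] - 1L, " values, expected ", length(hdr))
  }
  rlab <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(x) as.numeric(x[-1L]), numeric(length(hdr))))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2L, any))[1L]
    stop("matrix file '", path, "': non-numeric cell at line ",
         lineno[bad + 1L])
  }
  m <- t(vals)
  dimnames(m) <- list(rlab, hdr)
  m
}

#' Write a quality-profile matrix file
#'
#' @param m numeric matrix with quality-label dimnames.
#' @param path output path.
#' @param comment optional comment line(s) written with a `#` prefix.
#' @return Invisibly, `path`.
#' @export
write_matrix_file <- function(m, path, comment = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(colnames(m), collapse = "\t"), con)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' Build a matrix quality model from two profile files
#'
#' @param match_path,mismatch_path matrix files in the
#'   [read_matrix_file()] format (CLI flags `-w`/`-x`).
#' @param qual_max output quality cap (CLI flag `-u`; default 40).
#' @return A [quality_model()] of kind `"matrix"`.
#' @export
quality_model_from_files <- function(match_path, mismatch_path,
                                     qual_max = 40L) {
  quality_model("matrix",
                match_matrix = read_matrix_file(match_path),
                mismatch_matrix = read_matrix_file(mismatch_path),
                qual_max = qual_max)
}

#' Default empirical quality model shipped with the package
#'
#' Loads the match/mismatch matrices stored under `inst/extdata`.  These
#' were trained with [train_quality_profile()] on this package's own
#' read simulator (independent errors plus a small correlated
#' first-strand error component); they are synthetic stand-ins, not
#' instrument-derived profiles, and are provided so the matrix code path
#' has a ready default.  For production use train matrices on control
#' reads from your own instrument.
#'
#' @param qual_max output quality cap (default 40).
#' @return A [quality_model()] of kind `"matrix"`.
#' @export
synthetic_profile_model <- function(qual_max = 40L) {
  quality_model_from_files(
    system.file("extdata", "synthetic_profile_match.tsv",
                package = "pairstitch", mustWork = TRUE),
    system.file("extdata", "synthetic_profile_mismatch.tsv",
                package = "pairstitch", mustWork = TRUE),
    qual_max = qual_max)
}
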