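#' Three-dimensional error tally
#'
#' Counts of correct and erroneous merged overlap bases indexed by the
#' R1 quality, the R2 quality and whether the input bases agreed.
#'
#' @param qmax top of the tallied quality range (cells cover 0..qmax).
#' @return An `error_tally`: a 4-d array
#'   `[q1 + 1, q2 + 1, class (match/mismatch), outcome (correct/error)]`.
#' @export
error_tally <- function(qmax = 40L) {
  qmax <- as.integer(qmax)
  structure(array(0, dim = c(qmax + 1L, qmax + 1L, 2L, 2L),
                  dimnames = list(q1 = 0:qmax, q2 = 0:qmax,
                                  class = c("match", "mismatch"),
                                  outcome = c("correct", "error"))),
            qmax = qmax, class = "error_tally")
}

#' Tally overlap columns against per-fragment truth
#'
#' Classifies every logged overlap column of stitched reads
#' (match/mismatch by the input bases, correct/error by comparing the
#' merged base to the true fragment) and accumulates the 3-d tally.
#' `N` columns are excluded from both classes, as are equal-quality
#' mismatches (their merged base is `N`).  Only pairs whose alignment
#' recovered the true fragment geometry contribute; columns from other
#' pairs are skipped and counted in the `skipped` attribute.
#'
#' @param events event table from [stitch_pairs()] with
#'   `events = "all"` (event positions in the merged read equal
#'   fragment positions when the alignment is correct).
#' @param truth_seq character vector of true fragment sequences, indexed
#'   by the `pair` column of `events`.
#' @param valid logical vector (per pair): does the pair's alignment
#'   match the truth geometry?  Default: all valid.
#' @param qmax top of the tallied quality range.
#' @return An [error_tally()] with attribute `skipped` (number of
#'   columns dropped for invalid pairs).
#' @export
tally_from_truth <- function(events, truth_seq,
                             valid = rep(TRUE, length(truth_seq)),
                             qmax = 40L) {
  tl <- error_tally(qmax)
  ok <- valid[events$pair]
  skipped <- sum(!ok)
  if (skipped > 0L) {
    warning(skipped, " overlap columns skipped (alignment does not match truth)")
  }
  ev <- events[ok & events$class %in% c("match", "mismatch") &
                 events$base != "N", , drop = FALSE]
  if (nrow(ev) > 0L) {
    tb <- substring(truth_seq[ev$pair], ev$pos + 1L, ev$pos + 1L)
    err <- ev$base != tb
    cls <- ifelse(ev$class == "match", 0L, 1L)
    if (any(ev$r1_qual > qmax | ev$r2_qual > qmax)) {
      stop("quality score above tally range qmax = ", qmax)
    }
    k <- 1L + ev$r1_qual + (qmax + 1L) * ev$r2_qual +
      (qmax + 1L)^2 * (cls + 2L * as.integer(err))
    counts <- tabulate(k, 4L * (qmax + 1L)^2)
    tl[] <- tl + array(counts, dim = dim(tl))
  }
  attr(tl, "skipped") <- skipped
  tl
}

#' Error rate with a half-count pseudo-error
#'
#' `errors / total`; cells with zero observed errors get a pseudo-error
#' count of 0.5, yielding `0.5 / total`, so that rates stay positive and
#' log-transformable.
#'
#' @param errors,total non-negative counts (vectorised); `total` must be
#'   positive (zero-count cells are excluded upstream).
#' @return Error rates in (0, 1\].
#' @export
rate_with_pseudocount <- function(errors, total) {
  ifelse(total > 0, ifelse(errors > 0, errors / total, 0.5 / total), NA_real_)
}

#' Mask thinly-observed tally cells
#'
#' Converts an [error_tally()] into per-class rate tables, masking cells
#' observed fewer times than the class threshold (defaults: 1000 counts
#' for the match table, 100 for the sparser mismatch table).  Masked
#' cells are filled only by smoothing, never by their own noisy rate.
#'
#' @param tally an [error_tally()].
#' @param min_match,min_mismatch minimum cell totals.
#' @return A list per class: `rate` (matrix, `NA` where masked) and
#'   `total` (matrix of cell totals).
#' @export
filter_cells <- function(tally, min_match = 1000L, min_mismatch = 100L) {
  out <- list()
  thr <- c(match = min_match, mismatch = min_mismatch)
  for (cl in c("match", "mismatch")) {
    tot <- tally[, , cl, "correct"] + tally[, , cl, "error"]
    rate <- rate_with_pseudocount(tally[, , cl, "error"], tot)
    rate[tot < thr[[cl]]] <- NA_real_
    out[[cl]] <- list(rate = rate, total = tot)
  }
  if (all(is.na(out$match$rate)) && all(is.na(out$mismatch$rate))) {
    warning("all tally cells fall below the count thresholds")
  }
  out
}

# linear interpolation with linear extrapolation from the terminal slopes
lin_interp_extrap <- function(x, y, x0) {
  n <- length(x)
  out <- approx(x, y, xout = x0, rule = 2, ties = "ordered")$y
  lo <- x0 < x[1L]
  hi <- x0 > x[n]
  if (any(lo)) out[lo] <- y[1L] + (y[2L] - y[1L]) / (x[2L] - x[1L]) * (x0[lo] - x[1L])
  if (any(hi)) out[hi] <- y[n] + (y[n] - y[n - 1L]) / (x[n] - x[n - 1L]) * (x0[hi] - x[n])
  out
}

#' Fit the baseline quality/error-rate profile
#'
#' Local regression of `log10(error rate)` on the claimed quality score,
#' followed by an isotonic (non-increasing) projection so the fit is
#' invertible.  This smoothed curve is the bridge used to express
#' merged-base error rates back on the instrument's own quality scale.
#'
#' @param q quality scores with observed rates.
#' @param rate observed error rates (use [rate_with_pseudocount()]).
#' @param weights optional fit weights, typically the per-quality base
#'   counts.
#' @param span local-regression bandwidth as a fraction of points
#'   (default 0.3).
#' @return A `baseline_profile`: grid `q`, fitted `log10_rate`, and the
#'   inputs.
#' @export
fit_baseline <- function(q, rate, weights = NULL, span = 0.3) {
  keep <- !is.na(rate)
  q <- q[keep]; rate <- rate[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(unique(q)) < 5L) {
    stop("too few quality levels (", length(unique(q)), ") to fit a ",
         "baseline profile; consider the theoretical relation ",
         "qual_to_error() instead")
  }
  o <- order(q)
  q <- q[o]; rate <- rate[o]
  if (!is.null(weights)) weights <- weights[o]
  y <- log10(rate)
  span <- max(span, 4.5 / length(q))  # keep enough points in each window
  fit <- stats::loess(y ~ q, weights = weights, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq.int(min(q), max(q))
  pred <- predict(fit, newdata = data.frame(q = grid))
  # isotonic projection: log10(rate) non-increasing in q
  iso <- -isoreg(grid, -pred)$yf
  structure(list(q = grid, log10_rate = iso, span = span,
                 input = data.frame(q = q, rate = rate)),
            class = "baseline_profile")
}

#' Predict the baseline error rate at given quality scores
#'
#' @param profile a [fit_baseline()] result.
#' @param q quality scores (extrapolated linearly in log10-rate outside
#'   the fitted range).
#' @return Error rates.
#' @export
predict_baseline <- function(profile, q) {
  10^lin_interp_extrap(profile$q, profile$log10_rate, q)
}

#' Invert the baseline profile: error rate to quality score
#'
#' @param profile a [fit_baseline()] result.
#' @param rate error rates.
#' @return Real-valued quality scores on the instrument's scale; rates
#'   outside the fitted range follow the linear extension of the
#'   terminal slope.  A degenerate (flat) profile maps every rate to the
#'   fitted range boundary with a warning.
#' @export
invert_baseline <- function(profile, rate) {
  y <- profile$log10_rate
  x <- profile$q
  keep <- !duplicated(y)   # flat isotonic segments: keep the first point
  y2 <- y[keep]; x2 <- x[keep]
  if (length(y2) >= 2L && y2[1L] - y2[length(y2)] < 1e-6) y2 <- y2[1L]
  if (length(y2) < 2L) {
    warning("baseline profile is flat; mapping all rates to the range boundary")
    return(rep(x[1L], length(rate)))
  }
  # y2 is strictly decreasing; invert on the reversed axis
  lin_interp_extrap(rev(y2), rev(x2), log10(rate))
}

#' Train empirical match/mismatch quality matrices
#'
#' Smooths the masked per-cell error rates with a two-dimensional local
#' regression of `log10(rate)` over `(q1, q2)`, converts the smoothed
#' rates to quality scores through the inverse baseline profile, floors
#' at 2, caps at `qual_max`, symmetrises the match matrix (the two reads
#' are physically exchangeable; the mismatch matrix is left asymmetric
#' because `(q1, q2)` encodes which read won) and rounds to integers.
#'
#' @param rates output of [filter_cells()].
#' @param baseline a [fit_baseline()] profile.
#' @param span 2-d local-regression bandwidth (default 0.3).
#' @param qual_max cap on matrix entries (default 40).
#' @return A [quality_model()] of kind `"matrix"`.
#' @export
build_matrices <- function(rates, baseline, span = 0.3, qual_max = 40L) {
  qlab <- as.integer(rownames(rates$match$rate))
  grid <- expand.grid(q1 = qlab, q2 = qlab)
  smooth_one <- function(tab) {
    obs <- which(!is.na(tab$rate), arr.ind = TRUE)
    if (nrow(obs) == 0L) {
      stop("cannot build matrices: all cells are masked")
    }
    df <- data.frame(q1 = qlab[obs[, 1L]], q2 = qlab[obs[, 2L]],
                     y = log10(tab$rate[obs]), w = tab$total[obs])
    if (nrow(df) < 10L) {
      # too few cells for a 2-d local fit: weighted-mean constant surface
      warning("only ", nrow(df), " unmasked cells; fitting a constant surface")
      const <- sum(df$y * df$w) / sum(df$w)
      return(matrix(const, nrow = length(qlab), ncol = length(qlab),
                    dimnames = list(qlab, qlab)))
    }
    sp <- max(span, 7 / nrow(df))
    fit <- stats::loess(y ~ q1 + q2, data = df, weights = df$w, span = sp,
                        degree = 1, normalize = FALSE,
                        control = stats::loess.control(surface = "direct"))
    pred <- predict(fit, newdata = grid)
    matrix(pred, nrow = length(qlab), dimnames = list(qlab, qlab))
  }
  to_qual <- function(log10_rate_mat) {
    qv <- invert_baseline(baseline, 10^log10_rate_mat)
    m <- matrix(pmin(pmax(qv, 2), qual_max), nrow = nrow(log10_rate_mat),
                dimnames = dimnames(log10_rate_mat))
    m
  }
  mm <- to_qual(smooth_one(rates$match))
  mm <- round((mm + t(mm)) / 2)
  xm <- round(to_qual(smooth_one(rates$mismatch)))
  quality_model("matrix", match_matrix = mm, mismatch_matrix = xm,
                qual_max = qual_max)
}

#' End-to-end profile training on simulated reads
#'
#' Aligns and stitches the simulated pairs (logging every overlap
#' column), tallies the columns against the simulator truth, fits the
#' baseline profile from the raw reads, masks thin cells and builds the
#' empirical match/mismatch matrices.
#'
#' @param sim a [simulate_pairs()] result.
#' @param params alignment parameters (dovetail is enabled by default
#'   here, as short fragments are part of the training data).
#' @param model quality model used while stitching (only the choice of
#'   winning base matters for the tally).
#' @param min_match,min_mismatch cell-count thresholds, see
#'   [filter_cells()].
#' @param span smoother bandwidth for both the baseline and the 2-d fit.
#' @param qual_max cap on trained matrix entries.
#' @return A list: `model` (the trained matrix [quality_model()]),
#'   `tally`, `rates`, `baseline`, and `n_used`/`n_skipped` pair counts.
#' @export
train_quality_profile <- function(sim,
                                  params = align_params(allow_dovetail = TRUE),
                                  model = quality_model("fastqjoin"),
                                  min_match = 1000L, min_mismatch = 100L,
                                  span = 0.3, qual_max = 40L) {
  aln <- align_pairs(sim$r1, sim$r2, params)
  st <- stitch_pairs(sim$r1, sim$r2, aln, model = model, events = "all")
  valid <- !is.na(aln$offset) & aln$offset == true_offsets(sim)
  tally <- suppressWarnings(
    tally_from_truth(st$events, sim$truth$frag_seq, valid, qmax = 40L))
  bl_tab <- baseline_tally(sim)
  bl <- fit_baseline(bl_tab$q, rate_with_pseudocount(bl_tab$errors, bl_tab$bases),
                     weights = bl_tab$bases, span = span)
  rates <- filter_cells(tally, min_match = min_match,
                        min_mismatch = min_mismatch)
  trained <- build_matrices(rates, bl, span = span, qual_max = qual_max)
  list(model = trained, tally = tally, rates = rates, baseline = bl,
       n_used = sum(valid), n_skipped = sum(!valid))
}
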