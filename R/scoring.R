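# Scoring pipeline: normalized frequencies f, inferred non-selective matrix,
# enrichment s, auto-activation-corrected s', per-ORF-pair scores, and
# MCC-calibrated calls.

#' Normalize a count matrix to frequencies
#'
#' `f[b, p] = (counts[b, p] + pseudocount) / sum(counts + pseudocount)`;
#' the result sums to 1.
#'
#' @param counts A [bfg_counts()] matrix or plain non-negative matrix.
#' @param pseudocount Non-negative value added to every cell (default 0).
#' @return A numeric frequency matrix with the same dimnames.
#' @export
normalize_counts <- function(counts, pseudocount = 0) {
  m <- unclass(counts) + pseudocount
  tot <- sum(m)
  if (tot <= 0) stop("all-zero matrix cannot be normalized without pseudocount")
  m / tot
}

#' Infer the non-selective pair matrix from marginals
#'
#' Models the expected non-selective abundance of every bait-prey pair as the
#' outer product of the bait (row) and prey (column) marginal frequencies of
#' the non-selective (+His) matrix. Rank-1 matrices are fixed points, and the
#' output marginals equal the input marginals exactly.
#'
#' @param f A frequency matrix (sums to 1).
#' @return A frequency matrix of the same shape, summing to 1.
#' @export
infer_nonselective <- function(f) {
  outer(rowSums(f), colSums(f))
}

#' Selective enrichment signal s
#'
#' `s[b, p] = f_sel[b, p] / max(f_inf[b, p], floor)`: the frequency of a pair
#' under selection relative to its inferred non-selective frequency. The
#' floor keeps dropout cells finite; the default sits below the smallest
#' frequency resolvable at typical sequencing depth.
#'
#' @param f_sel Frequency matrix of a selective condition.
#' @param f_inf Inferred non-selective matrix with identical axes.
#' @param floor Positive lower bound on the denominator (default 1e-9).
#' @return A non-negative finite matrix of enrichment signals.
#' @export
enrichment_s <- function(f_sel, f_inf, floor = 1e-9) {
  if (!identical(dim(f_sel), dim(f_inf)) ||
      !identical(dimnames(f_sel), dimnames(f_inf))) {
    stop("f_sel and f_inf axes differ")
  }
  if (floor <= 0) stop("floor must be > 0")
  f_sel / pmax(f_inf, floor)
}

#' Auto-activation background correction (s to s')
#'
#' An auto-activating bait drives the reporter without an interacting prey
#' and inflates its whole row of `s`. Each bait's background level is
#' estimated as the `background_quantile` of its row (the bulk of preys do
#' not interact, so an upper-middle quantile tracks background, not signal),
#' and the row is rescaled: `s'[b, p] = s[b, p] / max(B_b, floor)`. A bait
#' with a constant positive row (the pure auto-activator pattern) maps to
#' `s' == 1`. With `margin = 2` the same correction runs column-wise, for
#' prey-side background.
#'
#' @param s Enrichment matrix from [enrichment_s()] (`NA`s allowed for
#'   masked strains).
#' @param background_quantile Quantile of the row used as background
#'   (default 0.75).
#' @param floor Positive lower bound on the background level (default 1e-3).
#' @param margin 1 to correct bait rows (default), 2 for prey columns.
#' @return The corrected matrix `s'`.
#' @export
correct_autoactivation <- function(s, background_quantile = 0.75,
                                   floor = 1e-3, margin = 1L) {
  if (floor <= 0) stop("floor must be > 0")
  if (margin == 2L) {
    return(t(correct_autoactivation(t(s), background_quantile, floor,
                                    margin = 1L)))
  }
  bg <- apply(s, 1L, stats::quantile, probs = background_quantile,
              na.rm = TRUE, names = FALSE, type = 7)
  bg[is.na(bg)] <- 0
  s / pmax(bg, floor)
}

#' Mask strains with insufficient non-selective coverage
#'
#' Strains whose marginal frequency in the non-selective (+His) pool falls
#' below `min_marginal` cannot be quantified reliably (their denominator in
#' `s` is sampling noise); every pair involving them is left unscored.
#'
#' @param f_his Non-selective frequency matrix.
#' @param min_marginal Minimum marginal frequency; 0 masks nothing.
#' @return A list with logical vectors `baits` and `preys` (`TRUE` =
#'   masked), named by strain.
#' @export
filter_covered_strains <- function(f_his, min_marginal) {
  baits <- rowSums(f_his) < min_marginal
  preys <- colSums(f_his) < min_marginal
  if (all(baits) || all(preys)) {
    stop("min_marginal masks an entire library; nothing left to score")
  }
  list(baits = baits, preys = preys)
}

#' Combine replicate measurements into one score per pair
#'
#' @param measurements Numeric matrix (pairs x measurements) or vector;
#'   `NA`s mark missing (masked) measurements and are excluded.
#' @param method Combining function over a pair's measurements.
#' @return A data.frame with `score` (NA when no measurement survives) and
#'   `n_measurements`.
#' @export
combine_scores <- function(measurements,
                           method = c("mean", "median", "min", "max")) {
  method <- match.arg(method)
  m <- if (is.matrix(measurements)) measurements else
    matrix(measurements, nrow = 1L)
  fun <- switch(method, mean = mean, median = stats::median,
                min = min, max = max)
  n <- rowSums(!is.na(m))
  score <- rep(NA_real_, nrow(m))
  has <- n > 0L
  score[has] <- apply(m[has, , drop = FALSE], 1L, fun, na.rm = TRUE)
  data.frame(score = score, n_measurements = n,
             row.names = rownames(m) %||% NULL)
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the standard
#' convention that any zero factor in the denominator yields 0.
#'
#' @param tp,fp,fn,tn Non-negative counts (vectorized).
#' @return MCC values in `[-1, 1]`.
#' @export
mcc <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) < 0)) stop("confusion counts must be >= 0")
  if (any(tp + fp + fn + tn == 0)) stop("empty confusion table")
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  num <- tp * tn - fp * fn
  ifelse(den2 == 0, 0, num / sqrt(den2))
}

.as_pair_keys <- function(x) {
  if (inherits(x, "bfg_reference")) x$pairs else as.character(x)
}

#' MCC-optimal score cutoff
#'
#' Ranks pairs by descending score and scans every candidate rank cutoff
#' (cutoffs fall only between distinct score values, so tied pairs stay
#' together; the empty call set is also a candidate), scoring each against
#' the reference restricted to the tested space. Returns the cutoff
#' maximizing MCC (smallest cutoff on MCC ties) together with the full
#' rank-vs-MCC profile. Pairs with `NA` scores stay in the tested space but
#' can never be called.
#'
#' @param scores Named numeric vector (names are canonical pair keys from
#'   [canonical_pair()]), or a data.frame with `orf_a`, `orf_b`, `score`.
#' @param reference A [reference_set()] or character vector of canonical
#'   keys.
#' @param tested_space Canonical keys of all pairs the screen interrogated
#'   (defaults to the scored pairs).
#' @param homodimer_weight Weight of homodimeric reference pairs in the
#'   confusion table (1 = count once, the default; 2 = count both
#'   orientations).
#' @return An object of class `bfg_threshold`: fields `rank_cutoff`,
#'   `score_cutoff`, `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `mcc`,
#'   `calls` (keys above the cutoff) and `profile` (data.frame over all
#'   candidate cutoffs).
#' @export
optimize_threshold <- function(scores, reference, tested_space = NULL,
                               homodimer_weight = 1) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score,
                              canonical_pair(scores$orf_a, scores$orf_b))
  }
  if (is.null(names(scores))) stop("scores must be named by pair key")
  ref <- .as_pair_keys(reference)
  tested <- unique(tested_space %||% names(scores))
  scores <- scores[names(scores) %in% tested]
  ref <- intersect(ref, tested)
  if (length(ref) == 0L) {
    stop("reference set does not overlap the tested space")
  }
  wt <- function(keys) {
    m <- split_pair(keys)
    sum(ifelse(m[, 1L] == m[, 2L], homodimer_weight, 1))
  }
  pos_total <- wt(ref)
  neg_total <- wt(setdiff(tested, ref))

  ranked <- sort(scores[!is.na(scores)], decreasing = TRUE)
  # candidate cutoffs: after each run of tied scores, plus the empty set
  ends <- which(!duplicated(ranked, fromLast = TRUE))
  ks <- c(0L, ends)
  is_ref <- names(ranked) %in% ref
  m <- split_pair(names(ranked))
  w <- ifelse(m[, 1L] == m[, 2L], homodimer_weight, 1)
  cum_tp <- cumsum(w * is_ref)
  cum_fp <- cumsum(w * !is_ref)
  tp <- c(0, cum_tp)[match(ks, c(0L, seq_along(ranked)))]
  fp <- c(0, cum_fp)[match(ks, c(0L, seq_along(ranked)))]
  fn <- pos_total - tp
  tn <- neg_total - fp
  prof <- data.frame(
    rank_cutoff = ks,
    score_cutoff = c(Inf, ranked[ends]),
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    recall = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
    mcc = mcc(tp, fp, fn, tn))
  best <- which.max(prof$mcc)  # first (= smallest k) of tied maxima
  res <- as.list(prof[best, , drop = FALSE])
  res$calls <- names(ranked)[seq_len(res$rank_cutoff)]
  res$profile <- prof
  res$n_tested <- length(tested)
  class(res) <- "bfg_threshold"
  res
}

#' @export
print.bfg_threshold <- function(x, ...) {
  cat(sprintf(
    "MCC-optimal cutoff: top %d pairs (score >= %.4g)\n", x$rank_cutoff,
    x$score_cutoff))
  cat(sprintf(
    "  tp=%d fp=%d fn=%d tn=%d | precision %.3f, recall %.3f, MCC %.3f\n",
    x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$mcc))
  invisible(x)
}
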