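#' Fit interaction scores for a BFG-Y2H screen
#'
#' The central fitting function of the package. Takes the screen's raw
#' fused-barcode count matrices (one per condition x fusion type x
#' replicate) and produces a quantitative interaction score per ORF pair,
#' with an MCC-calibrated call threshold when a reference set is supplied.
#'
#' For each fusion type and replicate the pipeline is: (1) normalize the
#' non-selective (+His) matrix to frequencies and model the expected
#' non-selective abundance of every pair as the outer product of its bait
#' and prey marginals ([infer_nonselective()]); (2) normalize each selective
#' matrix and form the enrichment `s = f_sel / max(f_inf, floor)`
#' ([enrichment_s()]); (3) rescale rows (and, by default, then columns) by
#' their background quantile to remove bait auto-activation background,
#' yielding `s'` ([correct_autoactivation()]); (4) average `s'` over the
#' barcode replicates of each ORF pair; (5) combine all measurements
#' (selective conditions x fusion types x replicates) into one score per
#' ORF pair ([combine_scores()]). Strains under-covered in the +His pool
#' can be masked out first ([filter_covered_strains()]); their pairs are
#' reported unscored, not zero. Scores of the two screen orientations
#' (X as bait vs Y as bait) are reduced to one orientation-free score per
#' canonical pair by taking the stronger orientation.
#'
#' @param counts List of [bfg_counts()] matrices covering at least the
#'   non-selective condition and one selective condition for every fusion
#'   type x replicate to be scored.
#' @param design The [bfg_design()].
#' @param reference Optional [reference_set()] used to calibrate the call
#'   threshold by MCC ([optimize_threshold()]).
#' @param conditions Selective conditions to use (default: every condition
#'   present except `nonselective`).
#' @param nonselective Label of the non-selective control condition.
#' @param combine Method combining measurements per ORF pair (default
#'   `"mean"`).
#' @param pseudocount Pseudocount for [normalize_counts()] (default 0).
#' @param freq_floor Denominator floor for [enrichment_s()] (default 1e-9).
#' @param background_quantile,background_floor Parameters of
#'   [correct_autoactivation()].
#' @param prey_background Also apply the background correction column-wise
#'   after the bait-wise step (default TRUE).
#' @param min_marginal Minimum +His marginal frequency per strain; 0 (the
#'   default) masks nothing.
#' @param homodimer_weight Passed to [optimize_threshold()].
#' @return An object of class `bfg_score`; see [coef.bfg_score()],
#'   [summary.bfg_score()], [plot.bfg_score()]. Its `pairs` element is a
#'   data.frame with one row per canonical ORF pair: `orf_a`, `orf_b`,
#'   `score`, `n_measurements`, `in_reference`, `call`.
#' @export
score_screen <- function(counts, design, reference = NULL,
                         conditions = NULL, nonselective = "+His",
                         combine = c("mean", "median", "min", "max"),
                         pseudocount = 0, freq_floor = 1e-9,
                         background_quantile = 0.75, background_floor = 1e-3,
                         prey_background = TRUE, min_marginal = 0,
                         homodimer_weight = 1) {
  stopifnot(inherits(design, "bfg_design"))
  combine <- match.arg(combine)
  if (inherits(counts, "bfg_counts")) counts <- list(counts)
  meta <- data.frame(
    condition = vapply(counts, attr, "", "condition"),
    fusion_type = vapply(counts, attr, "", "fusion_type"),
    replicate = vapply(counts, attr, "", "replicate"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(meta)) stop("duplicate (condition, fusion, replicate)")
  sel_conditions <- conditions %||%
    setdiff(unique(meta$condition), nonselective)
  if (length(sel_conditions) == 0L) stop("no selective condition to score")

  bait_orf <- design$baits$orf_id
  prey_orf <- design$preys$orf_id
  groups <- unique(meta[meta$condition %in% sel_conditions,
                        c("fusion_type", "replicate")])
  s_prime <- list()
  f_average_acc <- list()
  masked <- list(baits = character(), preys = character())

  for (g in seq_len(nrow(groups))) {
    ft <- groups$fusion_type[g]; rp <- groups$replicate[g]
    i_his <- which(meta$condition == nonselective &
                   meta$fusion_type == ft & meta$replicate == rp)
    if (length(i_his) != 1L) {
      stop("need exactly one ", nonselective, " matrix for ", ft, "/", rp)
    }
    f_his <- normalize_counts(counts[[i_his]], pseudocount)
    mask <- filter_covered_strains(f_his, min_marginal)
    masked$baits <- union(masked$baits, names(which(mask$baits)))
    masked$preys <- union(masked$preys, names(which(mask$preys)))
    f_inf <- infer_nonselective(f_his)
    f_average_acc[[nonselective]] <- c(f_average_acc[[nonselective]],
                                       list(.orf_average(f_his, bait_orf, prey_orf)))
    for (cond in sel_conditions) {
      i_sel <- which(meta$condition == cond & meta$fusion_type == ft &
                     meta$replicate == rp)
      if (length(i_sel) != 1L) next
      f_sel <- normalize_counts(counts[[i_sel]], pseudocount)
      f_average_acc[[cond]] <- c(f_average_acc[[cond]],
                                 list(.orf_average(f_sel, bait_orf, prey_orf)))
      s <- enrichment_s(f_sel, f_inf, floor = freq_floor)
      s[mask$baits, ] <- NA_real_
      s[, mask$preys] <- NA_real_
      sp <- correct_autoactivation(s, background_quantile, background_floor)
      if (prey_background) {
        sp <- correct_autoactivation(sp, background_quantile,
                                     background_floor, margin = 2L)
      }
      s_prime[[paste(cond, ft, rp, sep = "|")]] <- sp
    }
  }
  if (length(s_prime) == 0L) stop("no selective measurements found")

  # barcode-replicate averaging precedes cross-replicate combining
  orf_meas <- lapply(s_prime, .orf_average, bait_orf, prey_orf)
  borfs <- rownames(orf_meas[[1L]]); porfs <- colnames(orf_meas[[1L]])
  flat <- vapply(orf_meas, as.vector, numeric(length(borfs) * length(porfs)))
  combined <- combine_scores(flat, method = combine)

  ordered <- expand.grid(bait_orf = borfs, prey_orf = porfs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ordered$score <- combined$score
  ordered$n_measurements <- combined$n_measurements
  ordered$key <- canonical_pair(ordered$bait_orf, ordered$prey_orf)

  # orientation-free score per canonical pair: the stronger orientation
  o <- order(ordered$key, -ifelse(is.na(ordered$score), -Inf, ordered$score))
  first <- o[!duplicated(ordered$key[o])]
  pairs <- ordered[first, c("key", "score", "n_measurements")]
  n_by_key <- rowsum(ordered$n_measurements, ordered$key)
  pairs$n_measurements <- n_by_key[pairs$key, 1L]
  km <- split_pair(pairs$key)
  pairs <- data.frame(orf_a = km[, 1L], orf_b = km[, 2L],
                      score = pairs$score,
                      n_measurements = pairs$n_measurements,
                      key = pairs$key, stringsAsFactors = FALSE,
                      row.names = NULL)

  threshold <- NULL
  pairs$in_reference <- FALSE
  pairs$call <- NA
  if (!is.null(reference)) {
    sc <- stats::setNames(pairs$score, pairs$key)
    threshold <- optimize_threshold(sc, reference, tested_space = pairs$key,
                                    homodimer_weight = homodimer_weight)
    pairs$in_reference <- pairs$key %in% .as_pair_keys(reference)
    pairs$call <- pairs$key %in% threshold$calls
  }

  f_average <- lapply(f_average_acc, function(lst) {
    Reduce(`+`, lst) / length(lst)
  })

  structure(
    list(pairs = pairs, ordered = ordered, s_prime = s_prime,
         measurements = flat, f_average = f_average, masked = masked,
         threshold = threshold,
         params = list(conditions = sel_conditions,
                       nonselective = nonselective, combine = combine,
                       pseudocount = pseudocount, freq_floor = freq_floor,
                       background_quantile = background_quantile,
                       background_floor = background_floor,
                       prey_background = prey_background,
                       min_marginal = min_marginal,
                       homodimer_weight = homodimer_weight),
         reference_name = if (!is.null(reference) &&
                              inherits(reference, "bfg_reference"))
           reference$name else NULL),
    class = "bfg_score")
}

# mean over barcode replicates: strain-level matrix -> ORF-level matrix,
# NA-aware (masked strains drop out of the average)
.orf_average <- function(m, bait_orf, prey_orf) {
  w <- !is.na(m)
  a <- m
  a[!w] <- 0
  num <- t(rowsum(t(rowsum(a, bait_orf)), prey_orf))
  den <- t(rowsum(t(rowsum(w + 0, bait_orf)), prey_orf))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' @export
print.bfg_score <- function(x, ...) {
  cat(sprintf(
    "BFG-Y2H interaction scores: %d ORF pairs (%d scored) from %d s' measurements\n",
    nrow(x$pairs), sum(!is.na(x$pairs$score)), ncol(x$measurements)))
  cat("  conditions:", paste(x$params$conditions, collapse = ", "),
      "| combine:", x$params$combine, "\n")
  if (!is.null(x$threshold)) {
    print(x$threshold)
  }
  invisible(x)
}

#' Extract per-pair interaction scores
#'
#' @param object A [score_screen()] fit.
#' @param ... Unused.
#' @return Named numeric vector of scores (canonical pair keys as names).
#' @export
coef.bfg_score <- function(object, ...) {
  stats::setNames(object$pairs$score, object$pairs$key)
}

#' Summarize a screen fit
#'
#' @param object A [score_screen()] fit.
#' @param ... Unused.
#' @return The object, invisibly, after printing measurement counts, masked
#'   strains, top pairs and any calibration result.
#' @export
summary.bfg_score <- function(object, ...) {
  print(object)
  if (length(object$masked$baits) || length(object$masked$preys)) {
    cat(sprintf("  masked strains: %d baits, %d preys\n",
                length(object$masked$baits), length(object$masked$preys)))
  }
  top <- object$pairs[order(-ifelse(is.na(object$pairs$score), -Inf,
                                    object$pairs$score)), ]
  cat("  top pairs:\n")
  print(utils::head(top[, c("orf_a", "orf_b", "score", "n_measurements")],
                    5L), row.names = FALSE)
  invisible(object)
}

#' Plot the rank-vs-MCC calibration profile
#'
#' @param x A [score_screen()] fit with a calibrated threshold.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bfg_score <- function(x, ...) {
  if (is.null(x$threshold)) stop("fit has no calibration (no reference set)")
  prof <- x$threshold$profile
  graphics::plot(prof$rank_cutoff, prof$mcc, type = "l",
                 xlab = "rank cutoff (pairs called)", ylab = "MCC", ...)
  graphics::abline(v = x$threshold$rank_cutoff, lty = 2)
  invisible(x)
}

#' Write a score table as TSV
#'
#' Columns: `orf_a`, `orf_b`, `score`, `n_measurements`, `call`,
#' `in_reference`.
#'
#' @param fit A [score_screen()] fit.
#' @param path Output TSV path.
#' @export
write_scores <- function(fit, path) {
  stopifnot(inherits(fit, "bfg_score"))
  df <- fit$pairs[, c("orf_a", "orf_b", "score", "n_measurements", "call",
                      "in_reference")]
  df$call <- as.integer(df$call)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select the best scoring configuration by MCC
#'
#' Evaluates a grid of candidate scoring configurations (selective-condition
#' subsets x combine methods x background quantiles), fitting each with
#' [score_screen()] and calibrating against the reference, and returns the
#' configuration maximizing MCC. Candidates are evaluated in a fixed,
#' deterministic order; MCC ties are broken toward the simpler
#' configuration (fewer conditions, then mean combine), which is the order
#' the grid is laid out in.
#'
#' @param counts,design,reference As in [score_screen()].
#' @param condition_sets List of selective-condition subsets (default: each
#'   selective condition alone, then both together).
#' @param combine_methods Combine methods to try (default mean, median).
#' @param quantiles Background quantiles to try (default 0.75).
#' @param ... Further arguments passed to [score_screen()].
#' @return A list with `best` (the winning [score_screen()] fit), `config`
#'   (its parameters) and `table` (per-configuration MCC data.frame).
#' @export
select_scoring_model <- function(counts, design, reference,
                                 condition_sets = NULL,
                                 combine_methods = c("mean", "median"),
                                 quantiles = 0.75, ...) {
  if (is.null(condition_sets)) {
    conds <- setdiff(unique(vapply(counts, attr, "", "condition")), "+His")
    condition_sets <- c(as.list(conds),
                        if (length(conds) > 1L) list(conds))
  }
  grid <- expand.grid(i_cond = seq_along(condition_sets),
                      combine = combine_methods, quantile = quantiles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # simpler first: fewer conditions, then mean before the alternatives
  grid <- grid[order(lengths(condition_sets)[grid$i_cond],
                     match(grid$combine, c("mean", combine_methods))), ]
  fits <- vector("list", nrow(grid))
  res <- data.frame(conditions = character(nrow(grid)),
                    combine = grid$combine, quantile = grid$quantile,
                    mcc = NA_real_, rank_cutoff = NA_integer_,
                    stringsAsFactors = FALSE)
  err <- character()
  for (i in seq_len(nrow(grid))) {
    cs <- condition_sets[[grid$i_cond[i]]]
    res$conditions[i] <- paste(cs, collapse = "+")
    fit <- tryCatch(
      score_screen(counts, design, reference = reference, conditions = cs,
                   combine = grid$combine[i],
                   background_quantile = grid$quantile[i], ...),
      error = function(e) e)
    if (inherits(fit, "error")) {
      err <- c(err, conditionMessage(fit))
      next
    }
    fits[[i]] <- fit
    res$mcc[i] <- fit$threshold$mcc
    res$rank_cutoff[i] <- fit$threshold$rank_cutoff
  }
  if (all(is.na(res$mcc))) {
    stop("every candidate configuration failed: ",
         paste(unique(err), collapse = "; "))
  }
  best <- which.max(res$mcc)  # first of ties = simplest config
  list(best = fits[[best]],
       config = res[best, , drop = FALSE],
       table = res)
}
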