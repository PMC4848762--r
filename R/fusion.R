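# Estimation of in-vivo barcode fusion efficiency from shotgun reads
# spanning lox junctions: the 7-bp flanks of each lox site identify whether
# the junction is parental (both flanks from the same plasmid) or chimeric
# (one bait-derived, one prey-derived flank, i.e. a Cre crossover product).

#' Cre recombination site sequences
#'
#' The 34-bp loxP and lox2272 sites. Cre recombines like with like, so the
#' two orthogonal sites force a clean barcode swap rather than arbitrary
#' exchange.
#'
#' @format Named character vector with elements `loxP` and `lox2272`.
#' @export
LOX_MOTIFS <- c(
  loxP    = "ATAACTTCGTATAATGTATGCTATACGAAGTTAT",
  lox2272 = "ATAACTTCGTATAAAGTATCCTATACGAAGTTAT")

#' Default junction flank reference
#'
#' Synthetic 7-bp sequences flanking each lox site on the parental bait and
#' prey plasmids, as used by [simulate_junction_reads()]. Real screens
#' supply the heptamers of their own plasmid maps.
#'
#' @return Nested list: `[[site]][[side]]` is a character vector with
#'   elements `bait` and `prey` (side is `upstream` or `downstream`).
#' @export
default_flank_refs <- function() {
  list(
    loxP = list(
      upstream = c(bait = "GCTAGCA", prey = "TTGACCT"),
      downstream = c(bait = "CAGGTTC", prey = "ACCTGAA")),
    lox2272 = list(
      upstream = c(bait = "GGATCCA", prey = "CTTAAGT"),
      downstream = c(bait = "TACCGGT", prey = "AGTCATC")))
}

.classify_flank <- function(obs, refs, max_mm) {
  origin <- rep("unknown", length(obs))
  full <- nchar(obs) == 7L
  for (who in names(refs)) {
    hit <- full & if (max_mm == 0L) obs == refs[[who]] else
      .hamming_to_ref(obs, refs[[who]]) <= max_mm
    origin[hit] <- who
  }
  origin
}

.find_motif <- function(reads, motif, max_mm) {
  pos <- as.integer(regexpr(motif, reads, fixed = TRUE))
  if (max_mm > 0L) {
    miss <- which(pos < 0L)
    w <- nchar(motif)
    for (i in miss) {
      ln <- nchar(reads[i])
      if (ln < w) next
      starts <- seq_len(ln - w + 1L)
      d <- .hamming_to_ref(substring(reads[i], starts, starts + w - 1L),
                           motif)
      j <- which(d <= max_mm)
      if (length(j)) pos[i] <- starts[j[1L]]
    }
  }
  pos
}

#' Tally lox-junction flank combinations
#'
#' Scans reads for each lox motif on either strand (reads matching on the
#' reverse strand are normalized to the plasmid forward strand first),
#' extracts the 7-bp flanks immediately up- and downstream of the site, and
#' assigns each flank to bait, prey or unknown origin. Reads without a lox
#' site are ignored; flanks extending past the read end count as unknown.
#'
#' @param reads Character vector of read sequences or a FASTQ path.
#' @param flank_refs Flank reference as from [default_flank_refs()].
#' @param lox_motifs Named motif sequences (default [LOX_MOTIFS]).
#' @param max_mismatch Mismatches tolerated when locating a lox motif
#'   (default 0; exact search is vectorized and fast).
#' @param flank_mismatch Mismatches tolerated in heptamer classification
#'   (default 0: 7 bp leaves little room for tolerant matching).
#' @return An object of class `bfg_junction_tally`: a `counts` array indexed
#'   `[site, upstream origin, downstream origin]` plus `n_reads_with_lox`.
#' @export
tally_junctions <- function(reads, flank_refs = default_flank_refs(),
                            lox_motifs = LOX_MOTIFS, max_mismatch = 0L,
                            flank_mismatch = 0L) {
  if (length(reads) == 1L && file.exists(reads)) reads <- .read_fastq(reads)
  origins <- c("bait", "prey", "unknown")
  counts <- array(0L, dim = c(length(lox_motifs), 3L, 3L),
                  dimnames = list(site = names(lox_motifs),
                                  upstream = origins, downstream = origins))
  rc <- .revcomp(reads)
  n_with_lox <- 0L
  for (site in names(lox_motifs)) {
    motif <- lox_motifs[[site]]
    w <- nchar(motif)
    pos_f <- .find_motif(reads, motif, max_mismatch)
    use_rc <- pos_f < 0L
    pos_r <- .find_motif(rc[use_rc], motif, max_mismatch)
    seqs <- reads
    seqs[use_rc] <- rc[use_rc]
    pos <- pos_f
    pos[use_rc] <- pos_r
    hit <- which(pos > 0L)
    if (!length(hit)) next
    n_with_lox <- n_with_lox + length(hit)
    up <- substr(seqs[hit], pos[hit] - 7L, pos[hit] - 1L)
    up[pos[hit] <= 7L] <- ""  # flank truncated by read start
    dn <- substr(seqs[hit], pos[hit] + w, pos[hit] + w + 6L)
    up_o <- .classify_flank(up, flank_refs[[site]]$upstream, flank_mismatch)
    dn_o <- .classify_flank(dn, flank_refs[[site]]$downstream,
                            flank_mismatch)
    tab <- table(factor(up_o, levels = origins),
                 factor(dn_o, levels = origins))
    counts[site, , ] <- counts[site, , ] + unclass(tab)
  }
  structure(list(counts = counts, n_reads_with_lox = n_with_lox),
            class = "bfg_junction_tally")
}

#' @export
print.bfg_junction_tally <- function(x, ...) {
  cat("Lox junction tally:", x$n_reads_with_lox, "reads with a lox site\n")
  for (site in dimnames(x$counts)$site) {
    cat(" ", site, "\n")
    print(x$counts[site, , ])
  }
  invisible(x)
}

#' Estimate the barcode fusion fraction
#'
#' Chimeric junctions (one bait- and one prey-derived flank) are Cre
#' crossover products; parental junctions carry same-origin flanks. The
#' fused fraction is `chimeric / (chimeric + parental)`, pooled over both
#' lox sites, with a Wilson 95% confidence interval. Interpreting this
#' junction-level fraction as the fraction of cells yielding fused barcodes
#' assumes equal bait/prey plasmid copy number per cell and all-or-nothing
#' double-crossover per cell.
#'
#' @param tally A [tally_junctions()] result.
#' @return An object of class `bfg_fusion_estimate`: `fraction_fused`,
#'   `ci_low`, `ci_high` (Wilson 95%), `n_parental`, `n_chimeric`,
#'   `per_site` (data.frame of per-site estimates), `assumption`.
#' @export
estimate_fusion_fraction <- function(tally) {
  stopifnot(inherits(tally, "bfg_junction_tally"))
  chim_of <- function(m) m["bait", "prey"] + m["prey", "bait"]
  par_of <- function(m) m["bait", "bait"] + m["prey", "prey"]
  sites <- dimnames(tally$counts)$site
  per_site <- data.frame(
    site = sites,
    n_chimeric = vapply(sites, function(s) chim_of(tally$counts[s, , ]), 0L),
    n_parental = vapply(sites, function(s) par_of(tally$counts[s, , ]), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  per_site$fraction <- with(per_site,
                            ifelse(n_chimeric + n_parental > 0,
                                   n_chimeric / (n_chimeric + n_parental),
                                   NA_real_))
  ch <- sum(per_site$n_chimeric)
  pa <- sum(per_site$n_parental)
  if (ch + pa == 0L) stop("no classifiable junctions")
  ci <- if (ch == 0L || ch == ch + pa) {
    # prop.test degenerates at the boundary; Wilson closed form still holds
    .wilson_ci(ch, ch + pa)
  } else {
    as.numeric(stats::prop.test(ch, ch + pa, correct = FALSE)$conf.int)
  }
  structure(
    list(fraction_fused = ch / (ch + pa), ci_low = ci[1L], ci_high = ci[2L],
         n_parental = pa, n_chimeric = ch, per_site = per_site,
         assumption = paste("cell-level interpretation assumes equal",
                            "bait/prey plasmid copy number and",
                            "all-or-nothing double-crossover per cell")),
    class = "bfg_fusion_estimate")
}

.wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ph <- x / n
  den <- 1 + z^2 / n
  center <- (ph + z^2 / (2 * n)) / den
  half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' @export
print.bfg_fusion_estimate <- function(x, ...) {
  cat(sprintf(
    "Barcode fusion efficiency: %.1f%% fused (95%% CI %.1f-%.1f%%; %d chimeric / %d parental junctions)\n",
    100 * x$fraction_fused, 100 * x$ci_low, 100 * x$ci_high,
    x$n_chimeric, x$n_parental))
  invisible(x)
}

#' Simulate shotgun reads spanning lox junctions
#'
#' Generates reads from a plasmid pool in which a fraction
#' `fusion_probability` of barcode loci are Cre-fused: fused junctions get
#' one bait- and one prey-derived flank, parental junctions same-origin
#' flanks (both orientations equally likely in each case). The lox site is
#' drawn uniformly, random sequence pads both ends, and each read is
#' reverse-complemented with probability 1/2.
#'
#' @param n_reads Number of reads.
#' @param fusion_probability True chimeric fraction.
#' @param flank_refs Flank reference (default [default_flank_refs()]).
#' @param pad Random bases added on each side (default 8).
#' @param seed Optional integer seed.
#' @return A list with `reads` and `ledger` (data.frame `site`,
#'   `up_origin`, `down_origin`, `chimeric` per read).
#' @export
simulate_junction_reads <- function(n_reads, fusion_probability,
                                    flank_refs = default_flank_refs(),
                                    pad = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sites <- sample(names(LOX_MOTIFS), n_reads, replace = TRUE)
  chim <- stats::runif(n_reads) < fusion_probability
  flip <- stats::runif(n_reads) < 0.5
  up_o <- ifelse(chim, ifelse(flip, "bait", "prey"),
                 ifelse(flip, "bait", "prey"))
  dn_o <- ifelse(chim, ifelse(flip, "prey", "bait"),
                 ifelse(flip, "bait", "prey"))
  up7 <- mapply(function(s, o) flank_refs[[s]]$upstream[[o]], sites, up_o)
  dn7 <- mapply(function(s, o) flank_refs[[s]]$downstream[[o]], sites, dn_o)
  rnd <- function(k) {
    vapply(seq_len(k), function(i) {
      paste(sample(.BASES, pad, replace = TRUE), collapse = "")
    }, "")
  }
  reads <- paste0(rnd(n_reads), up7, LOX_MOTIFS[sites], dn7, rnd(n_reads))
  rc <- stats::runif(n_reads) < 0.5
  reads[rc] <- .revcomp(reads[rc])
  list(reads = unname(reads),
       ledger = data.frame(site = sites, up_origin = up_o,
                           down_origin = dn_o, chimeric = chim,
                           stringsAsFactors = FALSE))
}
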