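#' Fused-barcode amplicon scheme
#'
#' Describes the fixed layout of a fused-barcode amplicon read:
#' `upstream_anchor | bait barcode (25 bp) | spacer_anchor | prey barcode
#' (25 bp) | downstream_anchor`. The spacer is the lox-derived sequence left
#' between the two barcodes by the Cre-mediated fusion; the outer anchors are
#' fragments of the common priming sites. Anchors are located at fixed
#' offsets with a bounded number of mismatches; barcodes are then matched to
#' the design dictionaries by bounded Hamming distance.
#'
#' @param upstream_anchor,spacer_anchor,downstream_anchor Non-empty DNA
#'   strings.
#' @param fusion_type `"BC1BC1"` or `"BC2BC2"` (which barcode locus this
#'   amplicon reads out).
#' @param max_mismatch_anchor Mismatches tolerated per anchor (default 3).
#' @param max_mismatch_barcode Mismatches tolerated per barcode (default 2).
#' @param orientation `"forward"` if reads run 5'->3' over the layout,
#'   `"reverse"` if reads are the reverse complement.
#' @return An object of class `bfg_scheme`.
#' @export
amplicon_scheme <- function(upstream_anchor, spacer_anchor, downstream_anchor,
                            fusion_type = c("BC1BC1", "BC2BC2"),
                            max_mismatch_anchor = 3L,
                            max_mismatch_barcode = 2L,
                            orientation = c("forward", "reverse")) {
  fusion_type <- match.arg(fusion_type)
  orientation <- match.arg(orientation)
  anchors <- c(upstream_anchor, spacer_anchor, downstream_anchor)
  if (any(!nzchar(anchors)) || !all(.is_dna(anchors))) {
    stop("anchors must be non-empty DNA strings")
  }
  if (max_mismatch_anchor < 0 || max_mismatch_barcode < 0) {
    stop("mismatch limits must be >= 0")
  }
  structure(
    list(upstream_anchor = upstream_anchor, spacer_anchor = spacer_anchor,
         downstream_anchor = downstream_anchor, fusion_type = fusion_type,
         max_mismatch_anchor = as.integer(max_mismatch_anchor),
         max_mismatch_barcode = as.integer(max_mismatch_barcode),
         orientation = orientation),
    class = "bfg_scheme")
}

#' Read an amplicon scheme from a YAML file
#'
#' @param path YAML file with the fields of [amplicon_scheme()].
#' @return A `bfg_scheme` object.
#' @export
read_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(amplicon_scheme, cfg)
}

#' Match observed barcodes against a dictionary by bounded Hamming distance
#'
#' For each observed 25-mer, finds the dictionary entry within
#' `max_mismatch` substitutions. The match must be unique at the minimum
#' qualifying distance: ties are reported as `"ambiguous"` and discarded by
#' the counting step (conservative unique-best-hit behaviour). Exact hits are
#' resolved by hashing; only inexact ones pay for the distance scan.
#'
#' @param observed Character vector of barcode-length sequences.
#' @param dictionary Named character vector (names are barcode ids) or
#'   unnamed (sequences identify themselves).
#' @param max_mismatch Maximum substitutions allowed (default 2).
#' @return A data.frame with columns `id` (barcode id or `NA`) and `status`
#'   (`matched`, `none`, `ambiguous`).
#' @export
match_barcode <- function(observed, dictionary, max_mismatch = 2L) {
  if (length(dictionary) < 1L) stop("dictionary must be non-empty")
  if (is.null(names(dictionary))) names(dictionary) <- dictionary
  w <- nchar(dictionary[[1L]])
  if (any(nchar(dictionary) != w)) stop("dictionary entries differ in length")
  if (any(nchar(observed) != w)) {
    stop("observed sequences must have the dictionary's barcode length")
  }
  id <- rep(NA_character_, length(observed))
  status <- rep("none", length(observed))

  hit <- match(observed, dictionary)
  exact <- !is.na(hit)
  id[exact] <- names(dictionary)[hit[exact]]
  status[exact] <- "matched"

  rest <- which(!exact)
  if (length(rest) && max_mismatch > 0L) {
    d <- .hamming_matrix(observed[rest], unname(dictionary))
    dmin <- apply(d, 1L, min)
    nmin <- rowSums(d == dmin)
    ok <- dmin <= max_mismatch
    amb <- ok & nmin > 1L
    uni <- ok & nmin == 1L
    status[rest[amb]] <- "ambiguous"
    status[rest[uni]] <- "matched"
    id[rest[uni]] <- names(dictionary)[
      max.col(-d[uni, , drop = FALSE], ties.method = "first")]
  }
  data.frame(id = id, status = status, stringsAsFactors = FALSE)
}

.anchor_ok <- function(reads, anchor, offset, max_mm) {
  frag <- substr(reads, offset, offset + nchar(anchor) - 1L)
  nchar(frag) == nchar(anchor) & .hamming_to_ref(frag, anchor) <= max_mm
}

#' Parse fused-barcode reads into per-read barcode calls
#'
#' Locates the scheme's three anchors at their fixed offsets (each with at
#' most `max_mismatch_anchor` substitutions), extracts the two 25-mers
#' between them, and matches each against the appropriate barcode dictionary
#' of the design (bait dictionary for the first barcode, prey for the
#' second; BC1 or BC2 locus according to the scheme's fusion type). Reads
#' failing any anchor (including truncated reads) are `unmatched-anchor`;
#' reads whose barcode has no unique dictionary hit are `unmatched-barcode`
#' or `ambiguous`.
#'
#' @param reads Character vector of read sequences, or a FASTQ file path
#'   (optionally gzipped).
#' @param scheme An [amplicon_scheme()].
#' @param design A [bfg_design()].
#' @param reads2 Optional second mate for paired-end data: mate 1 must carry
#'   `upstream_anchor | bait barcode | spacer_anchor` and mate 2 the reverse
#'   complement of `spacer_anchor | prey barcode | downstream_anchor`.
#' @return A data.frame with one row per read: `bait_barcode`,
#'   `prey_barcode` (barcode ids or `NA`) and `status` (`matched`,
#'   `unmatched-anchor`, `unmatched-barcode`, `ambiguous`).
#' @export
parse_fused_reads <- function(reads, scheme, design, reads2 = NULL) {
  stopifnot(inherits(scheme, "bfg_scheme"), inherits(design, "bfg_design"))
  if (length(reads) == 1L && file.exists(reads)) reads <- .read_fastq(reads)
  if (!is.null(reads2) && length(reads2) == 1L && file.exists(reads2)) {
    reads2 <- .read_fastq(reads2)
  }
  slot <- if (scheme$fusion_type == "BC1BC1") "bc1" else "bc2"
  bait_dict <- stats::setNames(design$baits[[paste0(slot, "_seq")]],
                               design$baits[[paste0(slot, "_id")]])
  prey_dict <- stats::setNames(design$preys[[paste0(slot, "_seq")]],
                               design$preys[[paste0(slot, "_id")]])

  if (is.null(reads2)) {
    if (scheme$orientation == "reverse") reads <- .revcomp(reads)
    up <- scheme$upstream_anchor
    sp <- scheme$spacer_anchor
    dn <- scheme$downstream_anchor
    o_bc1 <- nchar(up) + 1L
    o_sp <- o_bc1 + .BARCODE_LENGTH
    o_bc2 <- o_sp + nchar(sp)
    o_dn <- o_bc2 + .BARCODE_LENGTH
    min_len <- o_dn + nchar(dn) - 1L
    mm <- scheme$max_mismatch_anchor
    long_enough <- nchar(reads) >= min_len
    anchors_ok <- long_enough &
      .anchor_ok(reads, up, 1L, mm) &
      .anchor_ok(reads, sp, o_sp, mm) &
      .anchor_ok(reads, dn, o_dn, mm)
    bait_obs <- substr(reads, o_bc1, o_bc1 + .BARCODE_LENGTH - 1L)
    prey_obs <- substr(reads, o_bc2, o_bc2 + .BARCODE_LENGTH - 1L)
  } else {
    if (length(reads) != length(reads2)) stop("mates differ in length")
    m1 <- if (scheme$orientation == "reverse") .revcomp(reads) else reads
    m2 <- .revcomp(reads2)  # mate 2 reads the bottom strand of the tail
    up <- scheme$upstream_anchor
    sp <- scheme$spacer_anchor
    dn <- scheme$downstream_anchor
    mm <- scheme$max_mismatch_anchor
    o_bc1 <- nchar(up) + 1L
    o_sp1 <- o_bc1 + .BARCODE_LENGTH
    min1 <- o_sp1 + nchar(sp) - 1L
    # mate 2, forward-strand coordinates: spacer | prey barcode | downstream
    o_bc2 <- nchar(sp) + 1L
    o_dn <- o_bc2 + .BARCODE_LENGTH
    min2 <- o_dn + nchar(dn) - 1L
    anchors_ok <- nchar(m1) >= min1 & nchar(m2) >= min2 &
      .anchor_ok(m1, up, 1L, mm) & .anchor_ok(m1, sp, o_sp1, mm) &
      .anchor_ok(m2, sp, 1L, mm) & .anchor_ok(m2, dn, o_dn, mm)
    bait_obs <- substr(m1, o_bc1, o_bc1 + .BARCODE_LENGTH - 1L)
    prey_obs <- substr(m2, o_bc2, o_bc2 + .BARCODE_LENGTH - 1L)
  }

  n <- length(bait_obs)
  out <- data.frame(bait_barcode = rep(NA_character_, n),
                    prey_barcode = rep(NA_character_, n),
                    status = rep("unmatched-anchor", n),
                    stringsAsFactors = FALSE)
  keep <- which(anchors_ok)
  if (length(keep)) {
    bm <- match_barcode(bait_obs[keep], bait_dict, scheme$max_mismatch_barcode)
    pm <- match_barcode(prey_obs[keep], prey_dict, scheme$max_mismatch_barcode)
    st <- ifelse(bm$status == "matched" & pm$status == "matched", "matched",
          ifelse(bm$status == "ambiguous" | pm$status == "ambiguous",
                 "ambiguous", "unmatched-barcode"))
    out$status[keep] <- st
    ok <- st == "matched"
    out$bait_barcode[keep[ok]] <- bm$id[ok]
    out$prey_barcode[keep[ok]] <- pm$id[ok]
  }
  out
}

#' Tally per-read barcode calls into a count matrix
#'
#' Each `matched` call increments the cell of the strain pair owning the two
#' barcode ids; every other status goes to the `unmatched` tally, so the
#' total number of reads is conserved (`sum(counts) + unmatched == n`).
#' Matched barcode ids that are absent from the design are counted as
#' unmatched with a warning.
#'
#' @param calls Data frame from [parse_fused_reads()].
#' @param design A [bfg_design()].
#' @param condition,fusion_type,replicate Labels for the resulting matrix.
#' @return A [bfg_counts()] matrix over the design's strains.
#' @export
tally_counts <- function(calls, design, condition, fusion_type, replicate) {
  stopifnot(inherits(design, "bfg_design"))
  slot <- if (fusion_type == "BC1BC1") "bc1_id" else "bc2_id"
  bait_of <- stats::setNames(design$baits$strain_id, design$baits[[slot]])
  prey_of <- stats::setNames(design$preys$strain_id, design$preys[[slot]])
  m <- matrix(0L, nrow = nrow(design$baits), ncol = nrow(design$preys),
              dimnames = list(design$baits$strain_id, design$preys$strain_id))
  ok <- calls$status == "matched"
  bi <- bait_of[calls$bait_barcode[ok]]
  pi <- prey_of[calls$prey_barcode[ok]]
  known <- !is.na(bi) & !is.na(pi)
  if (any(!known)) {
    warning(sum(!known), " matched reads carry barcode ids not in the design")
  }
  if (any(known)) {
    tab <- table(factor(bi[known], levels = rownames(m)),
                 factor(pi[known], levels = colnames(m)))
    m <- m + unclass(tab)
    storage.mode(m) <- "integer"
  }
  bfg_counts(m, condition, fusion_type, replicate,
             unmatched = nrow(calls) - sum(known))
}

#' Count fused-barcode reads straight from FASTQ
#'
#' Convenience wrapper chaining [parse_fused_reads()] and [tally_counts()].
#'
#' @inheritParams parse_fused_reads
#' @inheritParams tally_counts
#' @return A [bfg_counts()] matrix.
#' @export
count_fused_reads <- function(reads, scheme, design, condition,
                              fusion_type = scheme$fusion_type,
                              replicate = "r1", reads2 = NULL) {
  calls <- parse_fused_reads(reads, scheme, design, reads2 = reads2)
  tally_counts(calls, design, condition, fusion_type, replicate)
}
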