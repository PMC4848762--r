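#' Row-column-plate (RCP) demultiplexing scheme
#'
#' RCP-PCR tags every well's amplicon with a plate, row and column index so a
#' single sequencing run reveals the barcode content of each well in a plate
#' stack. Reads are laid out as
#' `plate_tag | row_tag | col_tag | bc1 (25 bp) | bc2 (25 bp)`; each index
#' tier is matched with a bounded number of mismatches.
#'
#' @param plate_tags,row_tags,col_tags Named character vectors of index
#'   sequences (names are the plate/row/column labels); unique within each
#'   tier and of uniform length per tier. A 384-well layout uses 16 row and
#'   24 column tags.
#' @param bc1_len,bc2_len Barcode lengths (default 25).
#' @param max_mismatch_tag Mismatches tolerated per index tag (default 1).
#' @param purity_threshold Wells whose consensus is supported by a fraction
#'   of reads below this value are flagged `mixed` (default 0.8).
#' @return An object of class `bfg_rcp_scheme`.
#' @export
rcp_scheme <- function(plate_tags, row_tags, col_tags,
                       bc1_len = 25L, bc2_len = 25L,
                       max_mismatch_tag = 1L, purity_threshold = 0.8) {
  for (tier in list(plate_tags, row_tags, col_tags)) {
    if (is.null(names(tier)) || anyDuplicated(tier) ||
        length(unique(nchar(tier))) != 1L) {
      stop("each tag tier must be a named, unique, fixed-width set")
    }
  }
  if (purity_threshold < 0 || purity_threshold > 1) {
    stop("purity_threshold must be in [0, 1]")
  }
  structure(
    list(plate_tags = plate_tags, row_tags = row_tags, col_tags = col_tags,
         bc1_len = as.integer(bc1_len), bc2_len = as.integer(bc2_len),
         max_mismatch_tag = as.integer(max_mismatch_tag),
         purity_threshold = purity_threshold),
    class = "bfg_rcp_scheme")
}

.match_tag <- function(obs, tags, max_mm) {
  lab <- names(tags)[match(obs, tags)]
  rest <- which(is.na(lab))
  if (length(rest) && max_mm > 0L) {
    d <- .hamming_matrix(obs[rest], unname(tags))
    dmin <- apply(d, 1L, min)
    uni <- dmin <= max_mm & rowSums(d == dmin) == 1L
    lab[rest[uni]] <- names(tags)[
      max.col(-d[uni, , drop = FALSE], ties.method = "first")]
  }
  lab
}

#' Demultiplex RCP-PCR reads into per-well barcode tallies
#'
#' Every read is assigned to exactly one (plate, row, column) well or
#' dropped; a read is dropped when any index tier has no unique tag within
#' `max_mismatch_tag`, or when the read is too short to carry both barcodes.
#'
#' @param reads Character vector of read sequences or a FASTQ path.
#' @param scheme An [rcp_scheme()].
#' @return A list with `tallies` (data.frame `plate`, `row`, `col`, `bc1`,
#'   `bc2`, `n`: distinct barcode-pair observations per well) and `dropped`
#'   (named integer vector of drop reasons).
#' @export
demultiplex_rcp <- function(reads, scheme) {
  stopifnot(inherits(scheme, "bfg_rcp_scheme"))
  if (length(reads) == 1L && file.exists(reads)) reads <- .read_fastq(reads)
  pl <- nchar(scheme$plate_tags[1L])
  rl <- nchar(scheme$row_tags[1L])
  cl <- nchar(scheme$col_tags[1L])
  min_len <- pl + rl + cl + scheme$bc1_len + scheme$bc2_len
  long_enough <- nchar(reads) >= min_len
  n_short <- sum(!long_enough)
  reads <- reads[long_enough]

  plate <- .match_tag(substr(reads, 1L, pl), scheme$plate_tags,
                      scheme$max_mismatch_tag)
  row <- .match_tag(substr(reads, pl + 1L, pl + rl), scheme$row_tags,
                    scheme$max_mismatch_tag)
  col <- .match_tag(substr(reads, pl + rl + 1L, pl + rl + cl),
                    scheme$col_tags, scheme$max_mismatch_tag)
  o_bc1 <- pl + rl + cl + 1L
  bc1 <- substr(reads, o_bc1, o_bc1 + scheme$bc1_len - 1L)
  bc2 <- substr(reads, o_bc1 + scheme$bc1_len,
                o_bc1 + scheme$bc1_len + scheme$bc2_len - 1L)

  dropped <- c(truncated = n_short,
               plate_tag = sum(is.na(plate)),
               row_tag = sum(!is.na(plate) & is.na(row)),
               col_tag = sum(!is.na(plate) & !is.na(row) & is.na(col)))
  ok <- !is.na(plate) & !is.na(row) & !is.na(col)
  tallies <- as.data.frame(
    table(plate = plate[ok], row = row[ok], col = col[ok],
          bc = paste(bc1[ok], bc2[ok], sep = "|")),
    stringsAsFactors = FALSE)
  tallies <- tallies[tallies$Freq > 0L, , drop = FALSE]
  bcm <- matrix(unlist(strsplit(tallies$bc, "|", fixed = TRUE),
                       use.names = FALSE), ncol = 2L, byrow = TRUE)
  tallies <- data.frame(plate = tallies$plate, row = tallies$row,
                        col = tallies$col,
                        bc1 = if (nrow(tallies)) bcm[, 1L] else character(),
                        bc2 = if (nrow(tallies)) bcm[, 2L] else character(),
                        n = tallies$Freq, stringsAsFactors = FALSE)
  list(tallies = tallies, dropped = dropped)
}

#' Call consensus barcodes per well
#'
#' For every well of the scheme's plate stack, the consensus is the most
#' frequent (bc1, bc2) pair among the well's reads and the purity is the
#' fraction of reads supporting it. Wells with no reads are flagged `empty`;
#' wells whose purity falls below the scheme's threshold are `mixed`.
#'
#' @param demux Output of [demultiplex_rcp()] (or its `tallies` component).
#' @param scheme The [rcp_scheme()] used for demultiplexing.
#' @return A data.frame with one row per well: `plate`, `row`, `col`,
#'   `consensus_bc1`, `consensus_bc2`, `purity`, `n_reads`, `flag`.
#' @export
call_well_barcodes <- function(demux, scheme) {
  stopifnot(inherits(scheme, "bfg_rcp_scheme"))
  tallies <- if (is.data.frame(demux)) demux else demux$tallies
  wells <- expand.grid(plate = names(scheme$plate_tags),
                       row = names(scheme$row_tags),
                       col = names(scheme$col_tags),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(wells,
                    consensus_bc1 = NA_character_,
                    consensus_bc2 = NA_character_,
                    purity = NA_real_, n_reads = 0L, flag = "empty",
                    stringsAsFactors = FALSE)
  if (nrow(tallies)) {
    key <- paste(tallies$plate, tallies$row, tallies$col, sep = "\x1f")
    wkey <- paste(out$plate, out$row, out$col, sep = "\x1f")
    for (k in unique(key)) {
      sub <- tallies[key == k, , drop = FALSE]
      top <- which.max(sub$n)  # deterministic: first of tied maxima
      i <- match(k, wkey)
      out$consensus_bc1[i] <- sub$bc1[top]
      out$consensus_bc2[i] <- sub$bc2[top]
      out$n_reads[i] <- sum(sub$n)
      out$purity[i] <- sub$n[top] / sum(sub$n)
      out$flag[i] <- if (out$purity[i] < scheme$purity_threshold)
        "mixed" else "clean"
    }
  }
  out
}
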