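#' Fused-barcode count matrices
#'
#' A count matrix holds raw fused-barcode read counts for one condition x
#' fusion-type x replicate, indexed by bait strain (rows) and prey strain
#' (columns), plus a tally of reads that could not be assigned to a strain
#' pair.
#'
#' @param counts Non-negative integer matrix; dimnames give bait and prey
#'   strain ids (row then column).
#' @param condition,fusion_type,replicate Labels identifying the library.
#' @param unmatched Number of discarded reads (non-negative).
#' @return An integer matrix of class `bfg_counts` with metadata attributes.
#' @export
bfg_counts <- function(counts, condition, fusion_type, replicate,
                       unmatched = 0L) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry bait/prey strain ids as dimnames")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (unmatched < 0) stop("unmatched must be >= 0")
  storage.mode(counts) <- "integer"
  structure(counts,
            condition = as.character(condition),
            fusion_type = as.character(fusion_type),
            replicate = as.character(replicate),
            unmatched = as.integer(unmatched),
            class = c("bfg_counts", "matrix", "array"))
}

#' @export
print.bfg_counts <- function(x, ...) {
  cat(sprintf(
    "Fused-barcode counts [%s | %s | %s]: %d baits x %d preys, %s reads matched, %d unmatched\n",
    attr(x, "condition"), attr(x, "fusion_type"), attr(x, "replicate"),
    nrow(x), ncol(x), format(sum(x), big.mark = ","), attr(x, "unmatched")))
  invisible(x)
}

#' Read / write a count matrix as TSV
#'
#' The file starts with metadata header lines `#condition=`, `#fusion_type=`,
#' `#replicate=` and `#unmatched=`, followed by a tab-separated table with
#' bait strain ids in the first column and prey strain ids as column names.
#' The round-trip is lossless for valid matrices.
#'
#' @param x A [bfg_counts()] matrix.
#' @param path TSV file path.
#' @param design Optional [bfg_design()]; if given, the axes read from disk
#'   must match the design's strain ids.
#' @return `read_counts` returns a `bfg_counts`; `write_counts` returns
#'   `path` invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "bfg_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#condition=", attr(x, "condition")),
    paste0("#fusion_type=", attr(x, "fusion_type")),
    paste0("#replicate=", attr(x, "replicate")),
    paste0("#unmatched=", attr(x, "unmatched"))), con)
  tab <- data.frame(bait = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, design = NULL) {
  hdr <- .read_meta_header(path)
  for (k in c("condition", "fusion_type", "replicate")) {
    if (is.null(hdr[[k]])) stop("counts file lacks #", k, "= header")
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (!is.null(design)) {
    if (!identical(sort(rownames(m)), sort(design$baits$strain_id)) ||
        !identical(sort(colnames(m)), sort(design$preys$strain_id))) {
      stop("count matrix axes do not match the design")
    }
    m <- m[design$baits$strain_id, design$preys$strain_id, drop = FALSE]
  }
  bfg_counts(m, hdr$condition, hdr$fusion_type, hdr$replicate,
             unmatched = as.integer(hdr$unmatched %||% 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
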