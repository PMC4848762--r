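#' Canonical unordered ORF-pair key
#'
#' Reference interaction sets are orientation-free while a screen tests X-Y and
#' Y-X separately; scoring and calibration therefore work on canonical
#' unordered keys. The key is stable across runs and identical for `(a, b)`
#' and `(b, a)`; homodimer keys `(a, a)` are valid and distinct from any
#' heterodimer.
#'
#' @param orf_a,orf_b Character vectors of ORF identifiers (recycled).
#' @return A character vector of pair keys.
#' @seealso [split_pair()] to recover the two identifiers.
#' @examples
#' canonical_pair("TP53", "MDM2") == canonical_pair("MDM2", "TP53")
#' @export
canonical_pair <- function(orf_a, orf_b) {
  if (any(!nzchar(orf_a)) || any(!nzchar(orf_b)) ||
      anyNA(orf_a) || anyNA(orf_b)) {
    stop("ORF ids must be non-empty")
  }
  a <- as.character(orf_a)
  b <- as.character(orf_b)
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  paste(lo, hi, sep = "\x1f")
}

#' Split canonical pair keys back into a two-column matrix
#'
#' @param key Character vector of keys from [canonical_pair()].
#' @return A character matrix with columns `orf_a`, `orf_b`.
#' @export
split_pair <- function(key) {
  parts <- strsplit(key, "\x1f", fixed = TRUE)
  out <- matrix(unlist(parts, use.names = FALSE), ncol = 2L, byrow = TRUE)
  colnames(out) <- c("orf_a", "orf_b")
  out
}

.BARCODE_LENGTH <- 25L

.validate_library <- function(df, role) {
  need <- c("strain_id", "orf_id", "bc1_id", "bc1_seq", "bc2_id", "bc2_seq")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing design columns for ", role, ": ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)[need]
  rownames(df) <- NULL
  if (nrow(df) < 1L) stop("design needs at least one ", role, " strain")
  if (anyDuplicated(df$strain_id)) {
    stop("duplicate ", role, " strain_id")
  }
  for (slot in c("bc1", "bc2")) {
    seqs <- df[[paste0(slot, "_seq")]]
    if (any(nchar(seqs) != .BARCODE_LENGTH)) {
      stop(role, " ", slot, " barcodes must be ", .BARCODE_LENGTH, " bp")
    }
    if (!all(.is_dna(seqs))) {
      stop(role, " ", slot, " barcodes must be over {A,C,G,T}")
    }
    if (anyDuplicated(seqs)) {
      stop("duplicate ", role, " ", slot, " barcode sequence within locus")
    }
    ids <- df[[paste0(slot, "_id")]]
    if (anyDuplicated(ids)) stop("duplicate ", role, " ", slot, " barcode id")
  }
  if (anyDuplicated(paste(df$bc1_seq, df$bc2_seq))) {
    stop("duplicate (bc1, bc2) pair within ", role, " library")
  }
  df
}

#' Construct a screen design
#'
#' A screen design holds the bait and prey libraries (one row per barcoded
#' strain; one ORF may appear in several rows, i.e. barcode replicates), the
#' condition and replicate structure of the screen, and optional calibration
#' pairs. Strain identity is the (ORF, barcode-pair) combination, not the ORF:
#' barcode replicates are scored separately before per-ORF-pair averaging.
#'
#' @param baits,preys Data frames with columns `strain_id`, `orf_id`,
#'   `bc1_id`, `bc1_seq`, `bc2_id`, `bc2_seq`. Barcodes are 25-bp ACGT
#'   sequences, unique within their locus.
#' @param conditions Character vector of condition labels; the first is taken
#'   as the non-selective control unless stated otherwise downstream.
#' @param replicates Character vector of replicate labels.
#' @param calibration_pairs Optional character vector of canonical pair keys
#'   (see [canonical_pair()]) spiked into the screen for calibration.
#' @param autoactivator_orfs Optional character vector of bait ORF ids known
#'   to auto-activate the reporter.
#' @return An object of class `bfg_design`.
#' @export
bfg_design <- function(baits, preys,
                       conditions = c("+His", "-His", "3AT"),
                       replicates = "r1",
                       calibration_pairs = character(),
                       autoactivator_orfs = character()) {
  baits <- .validate_library(baits, "bait")
  preys <- .validate_library(preys, "prey")
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions)) stop("condition labels must be unique")
  structure(
    list(baits = baits, preys = preys,
         conditions = conditions,
         replicates = as.character(replicates),
         fusion_types = c("BC1BC1", "BC2BC2"),
         calibration_pairs = as.character(calibration_pairs),
         autoactivator_orfs = as.character(autoactivator_orfs)),
    class = "bfg_design")
}

#' @export
print.bfg_design <- function(x, ...) {
  cat(sprintf(
    "BFG-Y2H screen design: %d bait strains (%d ORFs) x %d prey strains (%d ORFs)\n",
    nrow(x$baits), length(unique(x$baits$orf_id)),
    nrow(x$preys), length(unique(x$preys$orf_id))))
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  replicates:", paste(x$replicates, collapse = ", "), "\n")
  if (length(x$calibration_pairs)) {
    cat("  calibration pairs:", length(x$calibration_pairs), "\n")
  }
  invisible(x)
}

#' Read / write a screen design as TSV
#'
#' One row per strain with columns `strain_id`, `role` (`bait` or `prey`),
#' `orf_id`, `bc1_id`, `bc1_seq`, `bc2_id`, `bc2_seq`. `write_design` followed
#' by `load_design` is the identity on valid designs (condition/replicate
#' structure is carried in `#condition=` / `#replicate=` header lines).
#'
#' @param path TSV file path.
#' @param design A [bfg_design()] object.
#' @return `load_design` returns a `bfg_design`; `write_design` returns `path`
#'   invisibly.
#' @export
load_design <- function(path) {
  hdr <- .read_meta_header(path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"role" %in% names(df)) stop("design file lacks a 'role' column")
  bad <- setdiff(unique(df$role), c("bait", "prey"))
  if (length(bad)) stop("unknown role: ", paste(bad, collapse = ", "))
  bfg_design(
    baits = df[df$role == "bait", , drop = FALSE],
    preys = df[df$role == "prey", , drop = FALSE],
    conditions = if (!is.null(hdr$conditions))
      strsplit(hdr$conditions, ",", fixed = TRUE)[[1L]] else c("+His", "-His", "3AT"),
    replicates = if (!is.null(hdr$replicates))
      strsplit(hdr$replicates, ",", fixed = TRUE)[[1L]] else "r1")
}

#' @rdname load_design
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "bfg_design"))
  b <- cbind(design$baits[, "strain_id", drop = FALSE], role = "bait",
             design$baits[, -1L, drop = FALSE])
  p <- cbind(design$preys[, "strain_id", drop = FALSE], role = "prey",
             design$preys[, -1L, drop = FALSE])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#conditions=", paste(design$conditions, collapse = ",")),
    paste0("#replicates=", paste(design$replicates, collapse = ","))), con)
  utils::write.table(rbind(b, p), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.read_meta_header <- function(path) {
  lines <- readLines(path, n = 10L)
  lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) out[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
  }
  out
}

#' Reference interaction sets
#'
#' A reference set is a named collection of unordered positive ORF pairs
#' (for example a literature-curated benchmark) used for MCC calibration.
#' Pairs are canonicalized and de-duplicated; homodimers are allowed.
#'
#' @param orf_a,orf_b Character vectors of ORF ids, or `orf_a` may be a vector
#'   of canonical keys (with `orf_b` missing).
#' @param name Label for the set.
#' @return An object of class `bfg_reference` (fields `pairs`, `name`).
#' @export
reference_set <- function(orf_a, orf_b = NULL, name = "reference") {
  keys <- if (is.null(orf_b)) as.character(orf_a) else canonical_pair(orf_a, orf_b)
  structure(list(pairs = unique(keys), name = name), class = "bfg_reference")
}

#' @export
print.bfg_reference <- function(x, ...) {
  cat(sprintf("Reference set '%s': %d unordered pairs\n", x$name,
              length(x$pairs)))
  invisible(x)
}

#' @rdname reference_set
#' @param path TSV with columns `orf_a`, `orf_b` and optionally `source`.
#' @export
read_reference <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("orf_a", "orf_b") %in% names(df))) {
    stop("reference file needs columns orf_a, orf_b")
  }
  reference_set(df$orf_a, df$orf_b, name = name)
}

#' @rdname reference_set
#' @param ref A `bfg_reference` object.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "bfg_reference"))
  m <- split_pair(ref$pairs)
  utils::write.table(
    data.frame(orf_a = m[, 1L], orf_b = m[, 2L], source = ref$name),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
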