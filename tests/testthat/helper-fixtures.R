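# Fixtures are built in code: random barcodes, small designs, and a tiny
# deterministic design used across the I/O and read-parsing tests.

rand_barcodes <- function(n, len = 25L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

make_library <- function(prefix, n_orfs, barcodes_per_orf = 1L) {
  orf <- rep(sprintf("%s%02d", prefix, seq_len(n_orfs)),
             each = barcodes_per_orf)
  idx <- rep(seq_len(barcodes_per_orf), times = n_orfs)
  data.frame(strain_id = sprintf("%s.%d", orf, idx), orf_id = orf,
             bc1_id = sprintf("%s.%d.bc1", orf, idx),
             bc1_seq = rand_barcodes(n_orfs * barcodes_per_orf),
             bc2_id = sprintf("%s.%d.bc2", orf, idx),
             bc2_seq = rand_barcodes(n_orfs * barcodes_per_orf),
             stringsAsFactors = FALSE)
}

make_design <- function(n_bait = 2L, n_prey = 2L, barcodes_per_orf = 1L,
                        seed = 42L, ...) {
  set.seed(seed)
  bfg_design(make_library("B", n_bait, barcodes_per_orf),
             make_library("P", n_prey, barcodes_per_orf), ...)
}

# independent brute-force minimum-Hamming search (byte comparison route,
# distinct from the package's character-matrix scan)
brute_force_match <- function(query, dict, max_mm) {
  d <- vapply(dict, function(s) {
    sum(charToRaw(query) != charToRaw(s))
  }, 0L)
  dmin <- min(d)
  if (dmin > max_mm) return(list(id = NA_character_, status = "none"))
  if (sum(d == dmin) > 1L) return(list(id = NA_character_,
                                       status = "ambiguous"))
  list(id = names(dict)[which.min(d)], status = "matched")
}

# independent exhaustive rank-cutoff scan used against optimize_threshold
exhaustive_threshold_scan <- function(scores, ref) {
  vals <- sort(unique(scores[!is.na(scores)]), decreasing = TRUE)
  best <- list(mcc = -2)
  for (v in c(Inf, vals)) {
    call <- !is.na(scores) & scores >= v
    tp <- sum(call & names(scores) %in% ref)
    fp <- sum(call) - tp
    fn <- sum(names(scores) %in% ref) - tp
    tn <- length(scores) - tp - fp - fn
    m <- mcc(tp, fp, fn, tn)
    if (m > best$mcc) best <- list(mcc = m, k = sum(call), tp = tp, fp = fp)
  }
  best
}

make_rcp_scheme <- function(n_plates = 1L, purity_threshold = 0.8) {
  set.seed(424)
  rcp_scheme(
    plate_tags = setNames(rand_barcodes(n_plates, 6),
                          sprintf("P%d", seq_len(n_plates))),
    row_tags = setNames(rand_barcodes(16, 6), sprintf("R%02d", 1:16)),
    col_tags = setNames(rand_barcodes(24, 6), sprintf("C%02d", 1:24)),
    purity_threshold = purity_threshold)
}

rcp_read <- function(scheme, plate, row, col, bc1, bc2) {
  paste0(scheme$plate_tags[[plate]], scheme$row_tags[[row]],
         scheme$col_tags[[col]], bc1, bc2)
}

random_network <- function(n_nodes = 20, n_edges = 40, seed = 1,
                           categories = NULL) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  keys <- character(0)
  while (length(keys) < n_edges) {
    a <- sample(nodes, n_edges, TRUE)
    b <- sample(nodes, n_edges, TRUE)
    keys <- unique(c(keys, canonical_pair(a, b)[a != b]))
  }
  interaction_network(keys[seq_len(n_edges)], categories)
}

degree_seq <- function(net) {
  e <- net$edges[!net$homodimer, , drop = FALSE]
  sort(table(factor(c(e[, 1], e[, 2]), levels = net$nodes)))
}

counts_equal <- function(a, b) {
  ma <- matrix(as.integer(a), nrow(a), dimnames = dimnames(a))
  mb <- matrix(as.integer(b), nrow(b), dimnames = dimnames(b))
  identical(ma, mb[rownames(ma), colnames(ma)])
}
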