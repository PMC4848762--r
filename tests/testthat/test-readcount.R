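test_that("barcode matching equals exhaustive minimum-Hamming search", {
  set.seed(21)
  dict <- setNames(rand_barcodes(10000), sprintf("bc%05d", 1:10000))

  # exact hit
  expect_identical(match_barcode(dict[[5]], dict, 2)$id, "bc00005")

  # planted mismatches and random queries, checked against brute force
  mutate <- function(s, k) {
    pos <- sample(25, k)
    chars <- strsplit(s, "")[[1]]
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                              chars[p]), 1)
    paste(chars, collapse = "")
  }
  queries <- c(vapply(sample(dict, 10), mutate, "", k = 1),
               vapply(sample(dict, 10), mutate, "", k = 2),
               vapply(sample(dict, 5), mutate, "", k = 3),
               rand_barcodes(5))
  got <- match_barcode(unname(queries), dict, max_mismatch = 2)
  for (i in seq_along(queries)) {
    want <- brute_force_match(queries[[i]], dict, 2)
    expect_identical(got$status[i], want$status)
    expect_identical(got$id[i], want$id)
  }
})

test_that("ties at the minimum distance are ambiguous, not guessed", {
  base <- strrep("A", 25)
  d1 <- paste0("C", strrep("A", 24))
  d2 <- paste0(strrep("A", 24), "C")
  dict <- c(x = d1, y = d2)
  expect_identical(match_barcode(base, dict, 2)$status, "ambiguous")
  # distance 3 beyond tolerance 2
  far <- paste0("CCC", strrep("A", 22))
  expect_identical(match_barcode(far, c(only = base), 2)$status, "none")
  expect_error(match_barcode("ACGT", dict, 2), "length")
})

test_that("fused reads parse into calls and conserve every read", {
  d <- make_design(3, 3, seed = 7)
  sch <- default_amplicon_scheme("BC1BC1")
  good <- paste0(sch$upstream_anchor, d$baits$bc1_seq[1],
                 sch$spacer_anchor, d$preys$bc1_seq[2],
                 sch$downstream_anchor)
  scrambled <- paste0(sch$upstream_anchor, d$baits$bc1_seq[1],
                      paste(rev(strsplit(sch$spacer_anchor, "")[[1]]),
                            collapse = ""),
                      d$preys$bc1_seq[2], sch$downstream_anchor)
  truncated <- substr(good, 1, 40)
  alien <- paste0(sch$upstream_anchor, rand_barcodes(1),
                  sch$spacer_anchor, d$preys$bc1_seq[2],
                  sch$downstream_anchor)
  calls <- parse_fused_reads(c(good, scrambled, truncated, alien), sch, d)
  expect_identical(calls$status,
                   c("matched", "unmatched-anchor", "unmatched-anchor",
                     "unmatched-barcode"))
  expect_identical(calls$bait_barcode[1], d$baits$bc1_id[1])
  expect_identical(calls$prey_barcode[1], d$preys$bc1_id[2])

  cm <- tally_counts(calls, d, "-His", "BC1BC1", "r1")
  expect_identical(sum(cm) + attr(cm, "unmatched"), 4L)
  expect_identical(cm[d$baits$strain_id[1], d$preys$strain_id[2]], 1L)
})

test_that("five identical calls land in a single cell; ambiguity zeroes out", {
  d <- make_design(2, 2)
  calls <- data.frame(
    bait_barcode = rep(d$baits$bc1_id[2], 5),
    prey_barcode = rep(d$preys$bc1_id[1], 5),
    status = "matched", stringsAsFactors = FALSE)
  cm <- tally_counts(calls, d, "-His", "BC1BC1", "r1")
  expect_identical(cm[d$baits$strain_id[2], d$preys$strain_id[1]], 5L)
  expect_identical(sum(cm), 5L)

  amb <- data.frame(bait_barcode = NA_character_,
                    prey_barcode = NA_character_,
                    status = rep("ambiguous", 4), stringsAsFactors = FALSE)
  cm2 <- tally_counts(amb, d, "-His", "BC1BC1", "r1")
  expect_identical(sum(cm2), 0L)
  expect_identical(attr(cm2, "unmatched"), 4L)
})

test_that("counting is order-independent and matches the simulator ledger", {
  p <- sim_params(n_bait_orfs = 6, n_prey_orfs = 6, barcodes_per_orf = 2,
                  mating_cells = 1e5, plated_cells = 1e5,
                  extraction_molecules = 5e4, pcr_template_molecules = 5e4,
                  read_depth = 1e4, replicates = 1, seed = 5)
  sim <- simulate_screen(p)
  cm <- sim$counts[["-His|BC2BC2|r1"]]
  er <- emit_reads(cm, sim$design, error_rate = 0, seed = 6)
  sch <- default_amplicon_scheme("BC2BC2")

  tc <- count_fused_reads(er$reads, sch, sim$design, "-His",
                          replicate = "r1")
  expect_true(counts_equal(tc, cm))
  expect_identical(attr(tc, "unmatched"), 0L)

  set.seed(11)
  shuffled <- sample(er$reads)
  tc2 <- count_fused_reads(shuffled, sch, sim$design, "-His",
                           replicate = "r1")
  expect_true(counts_equal(tc2, tc))
})

test_that("paired-end mates resolve one barcode each", {
  d <- make_design(3, 3, seed = 13)
  sch <- default_amplicon_scheme("BC1BC1")
  m1 <- paste0(sch$upstream_anchor, d$baits$bc1_seq[3], sch$spacer_anchor)
  tail_fwd <- paste0(sch$spacer_anchor, d$preys$bc1_seq[1],
                     sch$downstream_anchor)
  m2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(tail_fwd)))
  calls <- parse_fused_reads(m1, sch, d, reads2 = m2)
  expect_identical(calls$status, "matched")
  expect_identical(calls$bait_barcode, d$baits$bc1_id[3])
  expect_identical(calls$prey_barcode, d$preys$bc1_id[1])
})

test_that("reverse-orientation reads give identical counts", {
  p <- sim_params(n_bait_orfs = 4, n_prey_orfs = 4, mating_cells = 1e4,
                  plated_cells = 1e4, extraction_molecules = 5e3,
                  pcr_template_molecules = 5e3, read_depth = 2e3,
                  replicates = 1, seed = 8)
  sim <- simulate_screen(p)
  cm <- sim$counts[["+His|BC1BC1|r1"]]
  er <- emit_reads(cm, sim$design, error_rate = 0, seed = 9)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(er$reads)))
  fwd <- default_amplicon_scheme("BC1BC1")
  rev <- amplicon_scheme(fwd$upstream_anchor, fwd$spacer_anchor,
                         fwd$downstream_anchor, fusion_type = "BC1BC1",
                         orientation = "reverse")
  t_f <- count_fused_reads(er$reads, fwd, sim$design, "+His")
  t_r <- count_fused_reads(rc, rev, sim$design, "+His")
  expect_true(counts_equal(t_f, t_r))
})

test_that("FASTQ files feed the parser directly", {
  d <- make_design(2, 2, seed = 3)
  sch <- default_amplicon_scheme("BC1BC1")
  reads <- paste0(sch$upstream_anchor, d$baits$bc1_seq[c(1, 2)],
                  sch$spacer_anchor, d$preys$bc1_seq[c(2, 1)],
                  sch$downstream_anchor)
  fq <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@r", 1:2), reads, "+",
                             strrep("I", nchar(reads[1])))), fq)
  cm <- count_fused_reads(fq, sch, d, "+His")
  expect_identical(sum(cm), 2L)
})
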