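small_params <- function(read_depth = 5e4, replicates = 2, ...) {
  sim_params(n_bait_orfs = 8, n_prey_orfs = 8, barcodes_per_orf = 2,
             mating_cells = 2e5, plated_cells = 2e5,
             extraction_molecules = 1e5, pcr_template_molecules = 1e5,
             read_depth = read_depth, replicates = replicates, ...)
}

test_that("identical seeds give bit-identical screens", {
  a <- simulate_screen(small_params(seed = 11))
  b <- simulate_screen(small_params(seed = 11))
  expect_identical(a$ledger, b$ledger)
  expect_identical(lapply(a$counts, unclass), lapply(b$counts, unclass))
  c_ <- simulate_screen(small_params(seed = 12))
  expect_false(identical(unclass(a$counts[[2]]), unclass(c_$counts[[2]])))
})

test_that("without interactions, auto-activation or leakage nothing survives", {
  p <- small_params(true_interaction_density = 0,
                    autoactivator_fraction = 0, leakage = 0, seed = 4)
  sim <- simulate_screen(p)
  sel <- sim$counts[grep("^\\+His", names(sim$counts), invert = TRUE)]
  expect_true(all(vapply(sel, sum, 0L) == 0L))
  his <- sim$counts[grep("^\\+His", names(sim$counts))]
  expect_true(all(vapply(his, sum, 0L) == p$read_depth))
})

test_that("every multinomial stage conserves its total", {
  p <- small_params(seed = 21)
  sim <- simulate_screen(p)
  st <- sim$ledger$stages$r1[["-His"]]
  expect_equal(sum(st$diploid), p$mating_cells)
  expect_equal(sum(st$plated), p$plated_cells)
  expect_true(all(st$fused <= st$plated))
  expect_equal(sum(st$extracted), min(p$extraction_molecules,
                                      sum(st$fused)))
  expect_equal(sum(st$pcr), min(p$pcr_template_molecules,
                                sum(st$extracted)))
  for (ft in c("BC1BC1", "BC2BC2")) {
    expect_equal(sum(sim$counts[[paste0("-His|", ft, "|r1")]]),
                 as.integer(p$read_depth))
  }
})

test_that("with selection disabled, selective and +His pools are exchangeable", {
  fails <- 0L
  for (s in 1:20) {
    # bottlenecks kept non-restrictive so the two conditions' read vectors
    # are (near-)multinomial draws from the same diploid pool
    p <- sim_params(n_bait_orfs = 5, n_prey_orfs = 5, barcodes_per_orf = 2,
                    true_interaction_density = 0,
                    autoactivator_fraction = 0, interaction_strength = 0,
                    leakage = 1, fusion_probability = 1,
                    mating_cells = 2e6, plated_cells = 2e6,
                    extraction_molecules = 2e6,
                    pcr_template_molecules = 2e6, read_depth = 1e4,
                    replicates = 1, seed = 900 + s)
    sim <- simulate_screen(p)
    v1 <- as.vector(unclass(sim$counts[["+His|BC1BC1|r1"]]))
    v2 <- as.vector(unclass(sim$counts[["-His|BC1BC1|r1"]]))
    pval <- suppressWarnings(chisq.test(rbind(v1, v2))$p.value)
    if (pval < 0.01) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("normalized frequencies stabilize as read depth grows", {
  base <- small_params(seed = 31, read_depth = 2e4)
  deep <- small_params(seed = 31, read_depth = 2e5)
  f1 <- normalize_counts(simulate_screen(base)$counts[["+His|BC1BC1|r1"]])
  f2 <- normalize_counts(simulate_screen(deep)$counts[["+His|BC1BC1|r1"]])
  # same underlying pool (same seed up to the read draw): deeper sampling
  # tracks the pool frequencies more tightly
  pool <- simulate_screen(small_params(seed = 31, read_depth = 2e4))
  truth <- pool$ledger$stages$r1[["+His"]]$pcr
  truth <- truth / sum(truth)
  expect_lt(max(abs(f2 - truth)), max(abs(f1 - truth)))
})

test_that("emitted reads with errors still mostly match within tolerance", {
  p <- small_params(seed = 41, read_depth = 1e4, replicates = 1)
  sim <- simulate_screen(p)
  cm <- sim$counts[["-His|BC1BC1|r1"]]
  er <- emit_reads(cm, sim$design, error_rate = 0.01, seed = 42)
  calls <- parse_fused_reads(er$reads, default_amplicon_scheme("BC1BC1"),
                             sim$design)
  # with 2 mismatches allowed per 25-bp barcode and 3 per anchor, the
  # binomial error model loses well under 1% of reads
  expect_gte(mean(calls$status == "matched"), 0.99)
  # and the intended pair is recovered for the matched reads
  ok <- which(calls$status == "matched")
  bait_of <- setNames(sim$design$baits$strain_id, sim$design$baits$bc1_id)
  expect_true(all(bait_of[calls$bait_barcode[ok]] ==
                  er$truth$bait_strain[ok]))
})

test_that("bottleneck coverage matches the analytic expectation", {
  # uniform abundances: a stage of N molecules over P pairs averages N/P
  p <- sim_params(n_bait_orfs = 50, n_prey_orfs = 50, barcodes_per_orf = 2,
                  abundance_sigma = 0,
                  bait_abundance = rep(1, 100), prey_abundance = rep(1, 100),
                  mating_cells = 1e6, plated_cells = 1e6,
                  fusion_probability = 0.5,
                  extraction_molecules = 2e5, pcr_template_molecules = 1e5,
                  read_depth = 1e4, replicates = 1, seed = 51)
  cov <- bottleneck_coverage(p, n_monte_carlo = 3)
  expect_equal(unname(cov$mean_coverage["diploid"]), 1e6 / 1e4)
  expect_equal(unname(cov$mean_coverage["extracted"]), 2e5 / 1e4)
  expect_equal(unname(cov$mean_coverage["pcr"]), 1e5 / 1e4)
  # two sequential subsamples: the later, smaller stage is the minimum
  expect_identical(cov$min_stage, "pcr")
  # successive subsampling stages are monotone non-increasing
  stages <- c("plated", "fused", "extracted", "pcr")
  expect_true(all(diff(cov$mean_coverage[stages]) <= 1e-9))
  expect_true(all(cov$coverage_fraction >= 0 & cov$coverage_fraction <= 1))
})

test_that("screens written to disk round-trip through the readers", {
  sim <- simulate_screen(sim_params(n_bait_orfs = 3, n_prey_orfs = 3,
                                    mating_cells = 1e4, plated_cells = 1e4,
                                    extraction_molecules = 5e3,
                                    pcr_template_molecules = 5e3,
                                    read_depth = 2e3, replicates = 1,
                                    seed = 61))
  dir <- tempfile()
  write_sim(sim, dir)
  d2 <- load_design(file.path(dir, "design.tsv"))
  expect_identical(d2$baits, sim$design$baits)
  fn <- file.path(dir, "counts_plusHis_BC1BC1_r1.tsv")
  expect_true(file.exists(fn))
  back <- read_counts(fn, design = d2)
  expect_true(counts_equal(back, sim$counts[["+His|BC1BC1|r1"]]))
})
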