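test_that("frequency normalization matches hand arithmetic", {
  m <- matrix(2, 2, 2, dimnames = list(c("b1", "b2"), c("p1", "p2")))
  expect_equal(unname(normalize_counts(m)), matrix(0.125, 2, 2) * 2)
  expect_equal(sum(normalize_counts(m)), 1)

  m2 <- matrix(c(3, 0, 1, 4), 2, 2)
  expect_equal(unname(normalize_counts(m2, pseudocount = 1)),
               matrix(c(4, 1, 2, 5), 2, 2) / 12)

  set.seed(2)
  for (i in 1:5) {
    r <- matrix(rpois(12, 3), 3, 4)
    expect_equal(sum(normalize_counts(r, pseudocount = 0.5)), 1)
  }
  expect_error(normalize_counts(matrix(0, 2, 2)), "all-zero")
})

test_that("inferred non-selective matrix is the marginal outer product", {
  f <- matrix(c(0.5, 0.2, 0.1, 0.2), 2, 2)
  expect_equal(unname(infer_nonselective(f)),
               matrix(c(0.42, 0.28, 0.18, 0.12), 2, 2))

  u <- matrix(0.25, 2, 2)
  expect_equal(infer_nonselective(u), u)

  # rank-1 matrices are fixed points; marginals conserved on random input
  set.seed(33)
  for (i in 1:100) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    f <- matrix(runif(nr * nc), nr, nc)
    f <- f / sum(f)
    fi <- infer_nonselective(f)
    expect_equal(sum(fi), 1, tolerance = 1e-12)
    expect_equal(rowSums(fi), rowSums(f), tolerance = 1e-9)
    expect_equal(colSums(fi), colSums(f), tolerance = 1e-9)
    r1 <- outer(runif(nr), runif(nc))
    r1 <- r1 / sum(r1)
    expect_equal(infer_nonselective(r1), r1, tolerance = 1e-12)
  }
})

test_that("enrichment s is the floored frequency ratio", {
  f <- matrix(c(0.2, 0.3, 0.1, 0.4), 2, 2)
  expect_equal(unname(enrichment_s(f, f)), matrix(1, 2, 2))
  fs <- matrix(c(0.2, 0, 0, 0.8), 2, 2)
  fi <- matrix(c(0.05, 0.45, 0.45, 0.05), 2, 2)
  expect_equal(enrichment_s(fs, fi)[1, 1], 4)
  # dropout denominator is floored, result finite
  fi0 <- matrix(c(0, 0.5, 0.3, 0.2), 2, 2)
  s <- enrichment_s(fs, fi0, floor = 1e-6)
  expect_true(all(is.finite(s)))
  expect_equal(s[1, 1], 0.2 / 1e-6)
  expect_error(enrichment_s(fs, matrix(1, 3, 2) / 6), "axes")
})

test_that("auto-activation correction rescales rows by their quantile", {
  # pure auto-activator: constant row maps to 1
  s <- rbind(a = rep(7, 5), b = c(1, 1, 1, 1, 8))
  colnames(s) <- paste0("p", 1:5)
  sp <- correct_autoactivation(s, background_quantile = 0.75, floor = 1e-3)
  expect_equal(unname(sp["a", ]), rep(1, 5))
  # q0.75 of {1,1,1,1,8} is 1, so the row is unchanged
  expect_equal(unname(sp["b", ]), c(1, 1, 1, 1, 8))

  # degenerate: zero background row, single hit divided by the floor
  z <- rbind(z = c(0, 0, 0, 0, 2))
  expect_equal(unname(correct_autoactivation(z, 0.75, floor = 1e-3)[1, ]),
               c(0, 0, 0, 0, 2000))

  # column-wise margin mirrors the row-wise behaviour
  expect_equal(correct_autoactivation(t(s), margin = 2), t(sp))
})

test_that("strain coverage filter masks exactly the under-covered strains", {
  f <- matrix(c(0.5, 0.5, 0, 0), 2, 2,
              dimnames = list(c("b1", "b2"), c("p1", "p2")))
  f <- f / sum(f)
  mask <- filter_covered_strains(f, 1e-4)
  expect_false(any(mask$baits))
  expect_identical(unname(mask$preys), c(FALSE, TRUE))
  mask0 <- filter_covered_strains(f, 0)
  expect_false(any(c(mask0$baits, mask0$preys)))
  expect_error(filter_covered_strains(f, 2), "entire library")
})

test_that("replicate combining honors method and missingness", {
  expect_equal(combine_scores(matrix(3, 1, 4), "median")$score, 3)
  expect_equal(combine_scores(matrix(c(2, 4), 1), "mean")$score, 3)
  m <- matrix(c(1, 2, 3, 10), 1)
  expect_equal(combine_scores(m, "median")$score, 2.5)
  expect_equal(combine_scores(m, "min")$score, 1)
  expect_equal(combine_scores(m, "max")$score, 10)
  # missing measurements are excluded, not zeroed; all-missing is unscored
  mm <- rbind(c(NA, 4, 6), c(NA, NA, NA))
  got <- combine_scores(mm, "mean")
  expect_equal(got$score, c(5, NA))
  expect_equal(got$n_measurements, c(2L, 0L))
})

test_that("MCC equals its closed form and the phi-coefficient oracle", {
  expect_equal(mcc(5, 0, 0, 5), 1)
  expect_equal(mcc(0, 0, 5, 5), 0)  # zero-denominator convention
  expect_equal(mcc(3, 1, 2, 10), 28 / sqrt(2640))
  expect_error(mcc(0, 0, 0, 0), "empty")

  # oracle: MCC is the Pearson correlation of the binary truth/call vectors
  set.seed(17)
  for (i in 1:1000) {
    tb <- rpois(4, 4)
    if (sum(tb) == 0) tb[1] <- 1
    got <- mcc(tb[1], tb[2], tb[3], tb[4])
    truth <- rep(c(1, 0, 1, 0), tb)
    call <- rep(c(1, 1, 0, 0), tb)
    want <- suppressWarnings(cor(truth, call))
    expect_equal(got, if (is.na(want)) 0 else want, tolerance = 1e-12)
  }
})

test_that("threshold optimization matches an exhaustive cutoff scan", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    keys <- canonical_pair(sprintf("X%03d", 1:n), sprintf("Y%03d", 1:n))
    # draw from a small value set so ties are frequent
    scores <- setNames(sample(seq(0, 5, by = 0.5), n, TRUE), keys)
    ref <- sample(keys, max(1, rbinom(1, n, 0.3)))
    got <- optimize_threshold(scores, ref)
    want <- exhaustive_threshold_scan(scores, ref)
    expect_equal(got$mcc, want$mcc, tolerance = 1e-12)
    expect_equal(got$rank_cutoff, want$k)
    expect_equal(got$tp, want$tp)
  }
})

test_that("threshold handles separable, tied and degenerate score sets", {
  keys <- canonical_pair(paste0("A", 1:6), paste0("B", 1:6))
  sc <- setNames(c(9, 8, 7, 3, 2, 1), keys)
  perfect <- optimize_threshold(sc, keys[1:3])
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$rank_cutoff, 3L)

  # all scores equal: only the all-or-none cutoffs are candidates
  tied <- optimize_threshold(setNames(rep(2, 6), keys), keys[1:2])
  expect_true(all(tied$profile$rank_cutoff %in% c(0L, 6L)))

  expect_error(optimize_threshold(sc, "nope\x1fpair"), "overlap")

  # reference pairs are matched orientation-free
  rev_ref <- canonical_pair("B1", "A1")
  expect_equal(optimize_threshold(sc, rev_ref)$tp, 1L)
})

test_that("scoring is depth- and permutation-invariant", {
  d <- make_design(4, 4, barcodes_per_orf = 1, seed = 77)
  set.seed(78)
  mk <- function(m, cond) {
    bfg_counts(matrix(m, 4, 4, dimnames = list(d$baits$strain_id,
                                               d$preys$strain_id)),
               cond, "BC1BC1", "r1")
  }
  his <- rpois(16, 200) + 10L
  sel <- rpois(16, 40) + as.integer(diag(4) * 500)
  base <- score_screen(list(mk(his, "+His"), mk(sel, "-His")), d)
  deep <- score_screen(list(mk(his * 10L, "+His"), mk(sel, "-His")), d)
  deeper <- score_screen(list(mk(his, "+His"), mk(sel * 7L, "-His")), d)
  expect_equal(coef(deep), coef(base), tolerance = 1e-9)
  expect_equal(coef(deeper), coef(base), tolerance = 1e-9)

  # permuting strain order permutes outputs identically
  pb <- sample(4); pp <- sample(4)
  dperm <- bfg_design(d$baits[pb, ], d$preys[pp, ],
                      conditions = d$conditions, replicates = d$replicates)
  mkp <- function(m, cond) {
    mm <- matrix(m, 4, 4, dimnames = list(d$baits$strain_id,
                                          d$preys$strain_id))
    bfg_counts(mm[pb, pp], cond, "BC1BC1", "r1")
  }
  perm <- score_screen(list(mkp(his, "+His"), mkp(sel, "-His")), dperm)
  expect_equal(coef(perm)[names(coef(base))], coef(base), tolerance = 1e-12)
})
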