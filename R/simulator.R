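# Forward Monte-Carlo simulation of a whole BFG-Y2H screen. Serves three
# purposes: ground-truth oracle for the readout and scoring modules,
# experimental-design tool (bottleneck coverage), and generator of realistic
# FASTQ input for the read counter.

#' Simulation parameters
#'
#' Defaults mirror the stated experimental magnitudes of a pooled screen of
#' this kind: ~1e8 diploid cells plated per condition, a plasmid-extraction
#' bottleneck leaving on the order of 100 fused molecules per strain pair,
#' barcode fusion in ~20% of cells, two barcoded strains per ORF, and
#' log-normally skewed strain abundances.
#'
#' @param n_bait_orfs,n_prey_orfs Number of bait / prey ORFs.
#' @param barcodes_per_orf Barcoded strains per ORF (barcode replicates).
#' @param abundance_sigma Log-normal sigma of haploid strain abundance.
#' @param true_interaction_density Fraction of ORF pairs that truly
#'   interact.
#' @param interaction_strength Additive survival weight of a true pair
#'   under selection (relative to `leakage`).
#' @param autoactivator_fraction Fraction of bait ORFs that auto-activate.
#' @param autoactivator_strength Multiplier on `leakage` for auto-activating
#'   baits (background growth, prey-independent).
#' @param leakage Basal survival weight of a non-interacting pair under
#'   selection.
#' @param stringency_factor Multiplier on `leakage` for the stringent (3-AT)
#'   condition (default 0.1).
#' @param mating_cells Diploid cells drawn at mating.
#' @param plated_cells Cells plated per selection condition.
#' @param extraction_molecules Fused plasmid molecules surviving extraction
#'   (the designed most-restrictive bottleneck).
#' @param pcr_template_molecules Molecules templated into the barcode PCR.
#' @param fusion_probability Probability a cell's barcodes are Cre-fused
#'   (only fused molecules are amplifiable).
#' @param read_depth Reads per condition x fusion type x replicate.
#' @param barcode_error_rate Per-base substitution rate used by
#'   [emit_reads()].
#' @param replicates Number of independent diploid replicates.
#' @param conditions Condition labels: non-selective, selective, stringent.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param bait_abundance,prey_abundance Optional fixed strain abundances
#'   (length `n_orfs * barcodes_per_orf`), overriding the log-normal draw.
#' @param true_pairs Optional fixed logical matrix (`n_bait_orfs` x
#'   `n_prey_orfs`) of true interactions, overriding the random draw.
#' @param autoactivator_baits Optional fixed indices of auto-activating
#'   bait ORFs, overriding the random draw.
#' @return An object of class `bfg_sim_params`.
#' @export
sim_params <- function(n_bait_orfs = 100L, n_prey_orfs = 100L,
                       barcodes_per_orf = 2L, abundance_sigma = 0.5,
                       true_interaction_density = 0.05,
                       interaction_strength = 1,
                       autoactivator_fraction = 0.05,
                       autoactivator_strength = 50, leakage = 1e-3,
                       stringency_factor = 0.1,
                       mating_cells = 1e8, plated_cells = 1e8,
                       extraction_molecules = 4e6,
                       pcr_template_molecules = 4e6,
                       fusion_probability = 0.2, read_depth = 2e6,
                       barcode_error_rate = 0.001, replicates = 4L,
                       conditions = c("+His", "-His", "3AT"), seed = 1L,
                       bait_abundance = NULL, prey_abundance = NULL,
                       true_pairs = NULL, autoactivator_baits = NULL) {
  p <- as.list(environment())
  counts <- c("n_bait_orfs", "n_prey_orfs", "barcodes_per_orf",
              "mating_cells", "plated_cells", "extraction_molecules",
              "pcr_template_molecules", "read_depth", "replicates")
  for (k in counts) if (p[[k]] <= 0) stop(k, " must be > 0")
  fracs <- c("true_interaction_density", "autoactivator_fraction",
             "fusion_probability", "barcode_error_rate")
  for (k in fracs) if (p[[k]] < 0 || p[[k]] > 1) stop(k, " must be in [0,1]")
  if (abundance_sigma < 0) stop("abundance_sigma must be >= 0")
  if (length(conditions) != 3L) {
    stop("conditions must be (non-selective, selective, stringent)")
  }
  structure(p, class = "bfg_sim_params")
}

.random_barcodes <- function(n) {
  repeat {
    bc <- vapply(seq_len(n), function(i) {
      paste(sample(.BASES, .BARCODE_LENGTH, replace = TRUE), collapse = "")
    }, "")
    if (!anyDuplicated(bc)) return(bc)
  }
}

.sim_design <- function(p) {
  mk <- function(prefix, n_orfs, k) {
    orf <- rep(sprintf("%sORF%03d", prefix, seq_len(n_orfs)), each = k)
    idx <- rep(seq_len(k), times = n_orfs)
    data.frame(strain_id = sprintf("%s.%d", orf, idx), orf_id = orf,
               bc1_id = sprintf("%s.%d.bc1", orf, idx),
               bc1_seq = .random_barcodes(n_orfs * k),
               bc2_id = sprintf("%s.%d.bc2", orf, idx),
               bc2_seq = .random_barcodes(n_orfs * k),
               stringsAsFactors = FALSE)
  }
  bfg_design(mk("B", p$n_bait_orfs, p$barcodes_per_orf),
             mk("P", p$n_prey_orfs, p$barcodes_per_orf),
             conditions = p$conditions,
             replicates = sprintf("r%d", seq_len(p$replicates)))
}

#' Simulate a complete BFG-Y2H screen
#'
#' Runs the generative model of the screen: haploid strain abundances are
#' drawn log-normally; the mated diploid pool is multinomial over the outer
#' product of bait and prey abundances; selection reweights each cell by
#' `leakage * aa_multiplier + interaction_strength * [true pair]` and
#' resamples to the plated population (the non-selective condition skips the
#' reweighting; the stringent condition scales `leakage` down); each plated
#' cell fuses its barcodes with `fusion_probability`; the fused molecules
#' pass two sequential multinomial bottlenecks (plasmid extraction, PCR
#' templating); finally reads are drawn multinomially to `read_depth`,
#' independently for the BC1-BC1 and BC2-BC2 amplicons and per replicate.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `bfg_sim`: `counts` (list of [bfg_counts()]),
#'   `design` (the generated [bfg_design()]), and `ledger` (ground truth:
#'   `true_pairs` canonical keys, `autoactivators`, strain `abundance`, and
#'   per-stage molecule-count matrices under `stages[[replicate]][[condition]]`).
#' @export
simulate_screen <- function(params) {
  stopifnot(inherits(params, "bfg_sim_params"))
  p <- params
  set.seed(p$seed)
  design <- .sim_design(p)
  nb <- nrow(design$baits); np <- nrow(design$preys)

  ab <- p$bait_abundance %||% stats::rlnorm(nb, 0, p$abundance_sigma)
  ap <- p$prey_abundance %||% stats::rlnorm(np, 0, p$abundance_sigma)
  if (length(ab) != nb || length(ap) != np) stop("abundance length mismatch")

  truth <- p$true_pairs %||%
    matrix(stats::runif(p$n_bait_orfs * p$n_prey_orfs) <
             p$true_interaction_density,
           p$n_bait_orfs, p$n_prey_orfs)
  aa_idx <- p$autoactivator_baits %||%
    which(stats::runif(p$n_bait_orfs) < p$autoactivator_fraction)
  aa_mult <- rep(1, p$n_bait_orfs)
  aa_mult[aa_idx] <- p$autoactivator_strength

  # expand ORF-level truth/background to strain-level weight components
  bi <- rep(seq_len(p$n_bait_orfs), each = p$barcodes_per_orf)
  pj <- rep(seq_len(p$n_prey_orfs), each = p$barcodes_per_orf)
  truth_s <- truth[bi, pj, drop = FALSE]
  w_sel <- p$leakage * aa_mult[bi] + p$interaction_strength * truth_s
  w_str <- p$leakage * p$stringency_factor * aa_mult[bi] +
    p$interaction_strength * truth_s
  sel_weights <- stats::setNames(
    list(NULL, w_sel, w_str), p$conditions)

  base <- outer(ab, ap)
  dn <- list(design$baits$strain_id, design$preys$strain_id)
  counts <- list()
  stages <- list()
  for (r in seq_len(p$replicates)) {
    rp <- sprintf("r%d", r)
    diploid <- .rmultinom1(p$mating_cells, as.vector(base))
    stages[[rp]] <- list()
    for (cond in p$conditions) {
      w <- sel_weights[[cond]]
      weighted <- if (is.null(w)) diploid else diploid * as.vector(w)
      plated <- .rmultinom1(p$plated_cells, weighted)
      fused <- stats::rbinom(length(plated), plated, p$fusion_probability)
      extracted <- .rmultinom1(min(p$extraction_molecules, sum(fused)), fused)
      pcr <- .rmultinom1(min(p$pcr_template_molecules, sum(extracted)),
                         extracted)
      stages[[rp]][[cond]] <- list(
        diploid = matrix(diploid, nb, np, dimnames = dn),
        plated = matrix(plated, nb, np, dimnames = dn),
        fused = matrix(fused, nb, np, dimnames = dn),
        extracted = matrix(extracted, nb, np, dimnames = dn),
        pcr = matrix(pcr, nb, np, dimnames = dn))
      for (ft in design$fusion_types) {
        reads <- .rmultinom1(p$read_depth, pcr)
        counts[[paste(cond, ft, rp, sep = "|")]] <- bfg_counts(
          matrix(reads, nb, np, dimnames = dn), cond, ft, rp)
      }
    }
  }

  orf_b <- sprintf("BORF%03d", seq_len(p$n_bait_orfs))
  orf_p <- sprintf("PORF%03d", seq_len(p$n_prey_orfs))
  tw <- which(truth, arr.ind = TRUE)
  structure(
    list(counts = counts, design = design,
         ledger = list(
           true_pairs = canonical_pair(orf_b[tw[, 1L]], orf_p[tw[, 2L]]),
           true_matrix = truth,
           autoactivators = stats::setNames(
             rep(p$autoactivator_strength, length(aa_idx)), orf_b[aa_idx]),
           abundance = list(bait = stats::setNames(ab, dn[[1L]]),
                            prey = stats::setNames(ap, dn[[2L]])),
           stages = stages),
         params = p),
    class = "bfg_sim")
}

#' @export
print.bfg_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Simulated BFG-Y2H screen: %dx%d ORFs (%d barcodes/ORF), %d true pairs, %d auto-activators\n",
    p$n_bait_orfs, p$n_prey_orfs, p$barcodes_per_orf,
    length(x$ledger$true_pairs), length(x$ledger$autoactivators)))
  cat(sprintf("  %d count matrices (%s x %s fusion types x %d replicates)\n",
              length(x$counts), paste(p$conditions, collapse = "/"),
              paste(x$design$fusion_types, collapse = "/"), p$replicates))
  invisible(x)
}

#' Default fused-barcode amplicon scheme
#'
#' A fixed synthetic amplicon layout used by the simulator: short fragments
#' of the common priming sites as outer anchors and the lox site left by the
#' Cre crossover as the spacer (loxP for BC1-BC1, lox2272 for BC2-BC2).
#'
#' @param fusion_type `"BC1BC1"` or `"BC2BC2"`.
#' @return A [amplicon_scheme()] object.
#' @export
default_amplicon_scheme <- function(fusion_type = c("BC1BC1", "BC2BC2")) {
  fusion_type <- match.arg(fusion_type)
  if (fusion_type == "BC1BC1") {
    amplicon_scheme("ACTGGCCGTCGTTTT", LOX_MOTIFS[["loxP"]],
                    "GTTGTAAAACGACGG", fusion_type = "BC1BC1")
  } else {
    amplicon_scheme("CAGGAAACAGCTATG", LOX_MOTIFS[["lox2272"]],
                    "CATGGTCATAGCTGT", fusion_type = "BC2BC2")
  }
}

#' Emit sequencing reads for a simulated count matrix
#'
#' Generates one read per counted molecule, laid out according to the
#' amplicon scheme, with independent per-base substitution errors, in
#' shuffled order. The returned truth table records the intended strain
#' pair of every read.
#'
#' @param counts A [bfg_counts()] matrix (e.g. from [simulate_screen()]).
#' @param design The matching [bfg_design()].
#' @param scheme An [amplicon_scheme()] for the matrix's fusion type.
#' @param error_rate Per-base substitution probability.
#' @param seed Optional integer seed.
#' @param fastq Optional path; when given, reads are also written as FASTQ.
#' @return A list with `reads` (character vector) and `truth` (data.frame
#'   `bait_strain`, `prey_strain`, one row per read, in read order).
#' @export
emit_reads <- function(counts, design, scheme = NULL, error_rate = 0,
                       seed = NULL, fastq = NULL) {
  stopifnot(inherits(counts, "bfg_counts"), inherits(design, "bfg_design"))
  if (!is.null(seed)) set.seed(seed)
  ft <- attr(counts, "fusion_type")
  scheme <- scheme %||% default_amplicon_scheme(ft)
  if (scheme$fusion_type != ft) stop("scheme fusion type mismatch")
  slot <- if (ft == "BC1BC1") "bc1_seq" else "bc2_seq"
  bait_seq <- stats::setNames(design$baits[[slot]], design$baits$strain_id)
  prey_seq <- stats::setNames(design$preys[[slot]], design$preys$strain_id)

  nz <- which(unclass(counts) > 0, arr.ind = TRUE)
  n_per <- unclass(counts)[nz]
  bait_strain <- rep(rownames(counts)[nz[, 1L]], n_per)
  prey_strain <- rep(colnames(counts)[nz[, 2L]], n_per)
  reads <- paste0(scheme$upstream_anchor, bait_seq[bait_strain],
                  scheme$spacer_anchor, prey_seq[prey_strain],
                  scheme$downstream_anchor)
  n <- length(reads)
  if (n > 0L && error_rate > 0) {
    len <- nchar(reads[1L])
    m <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                nrow = n, ncol = len, byrow = TRUE)
    hit <- which(stats::runif(n * len) < error_rate)
    if (length(hit)) {
      # substitute with one of the three other bases, uniformly
      shift <- sample.int(3L, length(hit), replace = TRUE)
      cur <- match(m[hit], .BASES)
      m[hit] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
    reads <- do.call(paste0, asplit(m, 2L))
  }
  perm <- if (n > 1L) sample.int(n) else seq_len(n)
  out <- list(reads = reads[perm],
              truth = data.frame(bait_strain = bait_strain[perm],
                                 prey_strain = prey_strain[perm],
                                 stringsAsFactors = FALSE))
  if (!is.null(fastq)) .write_fastq(out$reads, fastq)
  out
}

#' Per-pair coverage at each population bottleneck
#'
#' Experimental-design analytic: simulates the molecule-count stages of the
#' non-selective condition `n_monte_carlo` times and reports the mean
#' per-pair molecule count at each stage, the most restrictive stage, and
#' the fraction of pairs represented by at least 1 / 10 / 100 molecules
#' there. Totals are conserved by every multinomial stage, so with `P`
#' pairs a stage of `N` molecules has mean coverage exactly `N / P`.
#'
#' @param params A [sim_params()] object.
#' @param n_monte_carlo Number of Monte-Carlo draws (>= 1).
#' @return A list of class `bfg_coverage`: `mean_coverage` (named per-stage
#'   means over draws), `min_stage`, `coverage_fraction` (fraction of pairs
#'   with >= 1, 10, 100 molecules at the min stage), `n_pairs`.
#' @export
bottleneck_coverage <- function(params, n_monte_carlo = 3L) {
  stopifnot(inherits(params, "bfg_sim_params"), n_monte_carlo >= 1L)
  p <- params
  set.seed(p$seed)
  nb <- p$n_bait_orfs * p$barcodes_per_orf
  np <- p$n_prey_orfs * p$barcodes_per_orf
  n_pairs <- nb * np
  stages <- c("diploid", "plated", "fused", "extracted", "pcr")
  means <- matrix(NA_real_, n_monte_carlo, length(stages),
                  dimnames = list(NULL, stages))
  min_counts <- vector("list", n_monte_carlo)
  for (k in seq_len(n_monte_carlo)) {
    ab <- p$bait_abundance %||% stats::rlnorm(nb, 0, p$abundance_sigma)
    ap <- p$prey_abundance %||% stats::rlnorm(np, 0, p$abundance_sigma)
    diploid <- .rmultinom1(p$mating_cells, as.vector(outer(ab, ap)))
    plated <- .rmultinom1(p$plated_cells, diploid)
    fused <- stats::rbinom(n_pairs, plated, p$fusion_probability)
    extracted <- .rmultinom1(min(p$extraction_molecules, sum(fused)), fused)
    pcr <- .rmultinom1(min(p$pcr_template_molecules, sum(extracted)),
                       extracted)
    draw <- list(diploid = diploid, plated = plated, fused = fused,
                 extracted = extracted, pcr = pcr)
    means[k, ] <- vapply(draw, function(x) sum(x) / n_pairs, 0)
    min_counts[[k]] <- draw[[which.min(means[k, ])]]
  }
  mean_cov <- colMeans(means)
  min_stage <- stages[which.min(mean_cov)]
  thresh <- c(1, 10, 100)
  frac <- vapply(thresh, function(cc) {
    mean(vapply(min_counts, function(x) mean(x >= cc), 0))
  }, 0)
  structure(
    list(mean_coverage = mean_cov, min_stage = min_stage,
         coverage_fraction = stats::setNames(frac, paste0(">=", thresh)),
         n_pairs = n_pairs, n_monte_carlo = n_monte_carlo,
         per_draw = means),
    class = "bfg_coverage")
}

#' @export
print.bfg_coverage <- function(x, ...) {
  cat("Bottleneck coverage (", x$n_monte_carlo, " Monte-Carlo draws, ",
      x$n_pairs, " strain pairs)\n", sep = "")
  cat("  mean molecules per pair:\n")
  print(round(x$mean_coverage, 2))
  cat(sprintf("  most restrictive stage: %s\n", x$min_stage))
  cat("  fraction of pairs covered there:\n")
  print(round(x$coverage_fraction, 4))
  invisible(x)
}

#' Write a simulated screen to disk
#'
#' Writes the design TSV and one counts TSV per condition x fusion type x
#' replicate into a directory.
#'
#' @param sim A [simulate_screen()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "bfg_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_design(sim$design, file.path(dir, "design.tsv"))
  for (nm in names(sim$counts)) {
    # keep +His / -His distinguishable in file names
    slug <- gsub("[^A-Za-z0-9]+", "_",
                 gsub("\\+", "plus", gsub("-", "minus", nm)))
    fn <- paste0("counts_", slug, ".tsv")
    write_counts(sim$counts[[nm]], file.path(dir, fn))
  }
  m <- split_pair(sim$ledger$true_pairs)
  utils::write.table(
    data.frame(orf_a = m[, 1L], orf_b = m[, 2L], source = "simulated_truth"),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
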