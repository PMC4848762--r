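---
title: "Scoring pooled barcode-fusion Y2H screens: models and methods"
author: "bfgscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pooled barcode-fusion Y2H screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfgscreen)
```

## The measurement

A barcode-fusion yeast two-hybrid (BFG-Y2H) screen tests an entire bait x
prey protein matrix in one pooled culture. Every haploid strain carries a
plasmid with two strain-specific 25-bp barcodes (BC1, BC2) interdigitated
with the orthogonal Cre recombination sites loxP and lox2272. After en
masse mating, diploids representing all bait-prey combinations are grown
under reporter selection (-His, optionally with 3-AT for stringency, plus
a +His non-selective control). Cre induction then swaps barcodes *within*
each cell, leaving two chimeric loci — BC1-BC1 and BC2-BC2 — that each
identify one bait-prey combination in a single amplicon read. Interactions
are read out as enrichment of a pair's fused-barcode counts under
selection relative to the non-selective pool.

The package implements the complete computational side of such a screen:
read-to-count conversion, normalization and scoring, MCC-calibrated
calling, fusion-efficiency estimation, a forward simulator of the whole
experiment, and a degree-preserving network null for downstream
enrichment statistics.

## From reads to counts

Amplicon reads have a fixed layout: upstream priming-site anchor, bait
barcode (25 bp), a lox-derived spacer, prey barcode (25 bp), downstream
anchor. The original analysis located barcodes with a short-read BLAST at
a stringent E-value; this package instead uses anchored extraction plus
bounded Hamming matching, which is deterministic, dependency-free and
strictly defined:

* each anchor must match at its fixed offset with at most
  `max_mismatch_anchor` substitutions (default 3);
* each extracted 25-mer must have a *unique* dictionary barcode within
  `max_mismatch_barcode` substitutions (default 2). Ties at the minimum
  qualifying distance are discarded as ambiguous rather than fractionally
  assigned — conservative unique-best-hit behaviour.

With random 25-mers, two dictionary barcodes are almost never within
Hamming distance 4 of each other, so tolerance 2 cannot misassign; at a
1% per-base error rate the binomial error model loses well under 1% of
reads (the test suite checks >= 99% recovery). Indels inside barcodes are
not rescued (Hamming, not edit distance); this is a documented limitation
— indel reads simply fall into the unmatched tally, which is conserved:
every input read lands in exactly one of matched / unmatched-anchor /
unmatched-barcode / ambiguous.

Base qualities are ignored. The mismatch tolerance already absorbs
sequencer error, and fractional quality weighting would complicate the
exact read-conservation invariant for no measurable gain at these error
rates.

## The scoring model

Let `n[b,p]` be the fused-barcode count for bait strain `b` and prey
strain `p` in one library (condition x fusion type x replicate). The
pipeline in `score_screen()` is:

1. **Frequencies.** `f = (n + pseudocount) / sum(n + pseudocount)`. The
   pseudocount defaults to 0; with it at 0, all downstream quantities are
   invariant to sequencing depth (a tested property).
2. **Non-selective expectation.** The +His pool is deep enough to
   estimate marginal strain abundances but not every pair; the expected
   non-selective frequency of a pair is modelled as the outer product of
   its bait row-marginal and prey column-marginal:
   `f_inf[b,p] = r_b * c_p`. This "inferred" matrix conserves the
   marginals exactly and is a fixed point on rank-1 input.
3. **Enrichment.** `s[b,p] = f_sel[b,p] / max(f_inf[b,p], floor)` with
   `floor = 1e-9`, below the smallest frequency resolvable at around 1e7
   reads, so the floor only guards true dropouts.
4. **Auto-activation correction.** Some baits activate the reporter
   without any interacting prey and inflate their whole row of `s`. Each
   bait's background `B_b` is the `q`-quantile of its row (default
   `q = 0.75`: the bulk of preys do not interact, so an upper-middle
   quantile tracks background, not signal), and
   `s'[b,p] = s[b,p] / max(B_b, floor)` with `floor = 1e-3` on the `s`
   scale. A bait with a constant positive row — the pure auto-activator
   pattern — maps to `s' = 1`; a row that is constant *below* the floor
   is dominated by the floor instead, which keeps dead rows at zero
   rather than promoting them to 1. The same correction is then applied
   column-wise (configurable off) since prey-side expression biases act
   on columns the way bait auto-activation acts on rows.

   The exact background-correction formula of the original screens was
   not published in the main text; this fixed quantile-ratio form is a
   reconstruction that reproduces the described behaviours (marginal
   rescaling, row-background rescaling) with one tunable each, not a
   transcription.
5. **Per-pair combination.** `s'` is first averaged over the barcode
   replicates of each ORF pair, then all measurements (selective
   conditions x fusion types x replicates) are combined — mean by
   default; median/min/max available and comparable via
   `select_scoring_model()`. Missing (masked) measurements are excluded,
   and a pair with no surviving measurement is reported unscored (`NA`),
   never zero. A full two-library-variant screen with two fused-barcode
   loci, four replicates and two selective conditions yields 32 such
   measurements per pair.
6. **Orientation.** Reference sets are orientation-free while the screen
   tests X-as-bait-vs-Y and Y-as-bait-vs-X separately; Y2H orientations
   are genuinely asymmetric (fusion position affects folding and
   activation). The canonical-pair score is therefore the *stronger*
   orientation's score, so an interaction detectable in either
   configuration is recoverable, and calibration counts it once.
7. **Calibration.** Pairs are ranked by descending score and every rank
   cutoff is scanned (cutoffs fall only between distinct score values so
   tied pairs travel together; the empty call set is a candidate too).
   The cutoff maximizing the Matthews correlation coefficient against a
   reference interaction set is reported with the full rank-vs-MCC
   profile. MCC's zero-denominator convention is the standard "return
   0". Homodimeric reference pairs are counted once by default; whether
   they should count for both orientations is genuinely ambiguous, so
   `homodimer_weight = 2` exposes the alternative.

Strains with a +His marginal below `min_marginal` can be masked
(`filter_covered_strains()`); their pairs are unscored. The default is 0
(no masking) because well-constructed arrayed libraries rarely drop
strains; heterogeneous en-masse-cloned pools should set a positive
threshold — the appropriate value depends on pool complexity and depth,
and no universal constant is defensible.

## Fusion-efficiency estimation

Cre fusion happens in only a fraction of cells. Shotgun reads spanning a
lox site reveal whether a junction is parental (both 7-bp flanks from the
same plasmid) or chimeric (one bait- and one prey-derived flank). The
fused fraction is `chimeric / (chimeric + parental)` pooled over loxP and
lox2272, with a Wilson 95% interval (via `prop.test`, continuity
correction off; the closed form is used at the boundaries p = 0, 1).
Per-site estimates are emitted alongside without claiming equivalence to
the pooled one. Both strands are searched and flanks are normalized to
the plasmid forward strand, so the tally is strand-invariant (tested).
Heptamer classification is exact-match by default — 7 bp leaves no room
for tolerant matching — with a 1-mismatch option. Interpreting the
junction-level fraction as "% of cells yielding fused barcodes" assumes
equal bait/prey plasmid copy number and all-or-nothing double crossover
per cell; the estimate object carries this assumption in its metadata.

## The simulator

`simulate_screen()` is the package's ground-truth oracle and an
experimental-design tool. Its generative model:

* haploid strain abundances are log-normal (`abundance_sigma`, default
  0.5 — saturated cultures pooled at equal volume still vary severalfold,
  and the inferred abundance distributions of real pools are
  right-skewed at about this scale);
* the mated diploid pool is multinomial over the outer product of bait
  and prey abundances (`mating_cells`, default 1e8);
* selection reweights each cell by
  `leakage * aa + strength * [true pair]`, where `aa` is 1 or
  `autoactivator_strength` (default 50) for auto-activating baits, then
  resamples to `plated_cells` (default 1e8, the plated-cell scale of a
  real screen). The non-selective condition skips the reweighting; the
  stringent condition multiplies `leakage` by `stringency_factor`
  (default 0.1). Growth is modelled as a single reweighting rather than
  explicit generations because only relative abundances reach the
  readout;
* each plated cell fuses its barcodes with `fusion_probability` (default
  0.2, within the empirically reported 16-27% range); only fused
  molecules are amplifiable;
* two sequential multinomial bottlenecks (plasmid extraction, default
  4e6 molecules — about 100 molecules per strain pair at the default
  matrix size, matching the design target of real screens — then PCR
  templating) precede multinomial read sampling to `read_depth` (default
  2e6), drawn independently for the BC1-BC1 and BC2-BC2 amplicons;
* defaults: 100 x 100 ORFs, 2 barcodes per ORF, 5% true-interaction
  density, `leakage = 1e-3`, `interaction_strength = 1`, 5%
  auto-activating baits, 4 replicates.

One `set.seed()` call at entry makes every run bit-reproducible. The
ledger records the truth (pair set, auto-activators, abundances) and the
per-stage molecule matrices, so every downstream module can be tested
against exact expectations. `bottleneck_coverage()` reports mean per-pair
molecules per stage; because every multinomial stage conserves its total,
a stage of N molecules over P pairs has mean coverage exactly N/P, and
the "most restrictive" stage is discovered from the parameters rather
than asserted.

What the simulator deliberately omits: mating-efficiency biases, colony
geometry on plates, PCR jackpotting, barcode-specific amplification
bias, and indel sequencing errors. Passing the recovery tests therefore
shows the pipeline is correct under multinomial sampling with log-normal
abundance skew and strong selection; it does not certify performance
against those unmodelled real-data artifacts.

## Network null

`rewire_network()` randomizes a called network by double-edge swaps —
two edges (a,b), (c,d) become (a,d), (c,b) with randomized endpoint
assignment, rejecting self-edges and duplicates — preserving the degree
sequence exactly; 10 accepted swaps per edge by default, and 1,000 null
networks per enrichment by default (neither constant is canonical; both
are configurable and the defaults are comfortably past mixing for
networks of a few hundred edges). Homodimers are excluded from rewiring
and from every statistic. Empirical p-values use the
`(1 + #null >= obs) / (1 + n_null)` correction, so the smallest
attainable p is `1/(n_null + 1)` — report `n_null`, not just p. A
network with no valid swap (e.g. a triangle) is returned unchanged with
a warning rather than looping forever; the attempt budget is 200x the
swap target. Enrichment applies to whatever network is supplied; screens
can be pooled or rewired separately upstream, since nothing in the
statistic assumes one choice.

## Numerical and design notes

* Degenerate inputs raise errors rather than silently propagating: an
  all-zero matrix with pseudocount 0, an empty confusion table, a
  reference with no overlap with the tested space, masking an entire
  library, zero classifiable junctions.
* Ties: tied scores share a rank cutoff; tied MCC maxima resolve to the
  smallest cutoff (fewest calls); tied consensus barcodes in a well
  resolve to the first-observed pair deterministically;
  `select_scoring_model()` breaks MCC ties toward the simpler
  configuration (fewer conditions, mean combine) by evaluating candidates
  in that order.
* RCP-PCR well decoding uses the same bounded-Hamming tag matching as
  barcode matching (default 1 mismatch per 6-bp index tag) and flags
  wells as clean / mixed / empty by consensus purity (default threshold
  0.8).
* Problem sizes in the shipped tests are chosen to exercise each
  property at the smallest scale where the property is informative:
  full-default simulations (100x100 ORFs, 2e6 reads) for end-to-end
  recovery across 5 seeds, 20x20 matrices for exact read-count
  round-trips at 1e5 reads, 200 seeded replicates for interval coverage,
  1e4 draws for swap equidistribution.
* The exchangeability test of the simulator (selection off: selective
  and control pools indistinguishable) is run with non-restrictive
  bottlenecks, because with harsh bottlenecks the two conditions' read
  vectors are draws from *different* realized molecule pools and a
  two-sample chi-square would correctly detect that extra dispersion.

## Known limitations

* Numeric agreement with any particular published screen's deposited
  score tables is not promised: the exact background-correction formula
  and the coverage-filter threshold used there were not published, and
  both are configuration parameters here.
* Hamming matching cannot rescue reads with indels inside barcodes.
* The cell-level fusion-efficiency interpretation rests on the
  copy-number assumption stated above.
* Whether per-ORF-pair averaging should also pool fusion types (not just
  barcode replicates) is not externally fixed; the default pools both,
  and `f_average` matrices are exposed per condition for inspection.
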