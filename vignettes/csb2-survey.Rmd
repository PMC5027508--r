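---
title: "Surveying CSB 2 G-tract length heterogeneity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying CSB 2 G-tract length heterogeneity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csb2scan)
```

## The locus and its model

Conserved sequence block 2 (CSB 2) of the human mitochondrial control
region contains a hypervariable guanine tract. On the G-rich strand (the
strand read by light-strand-promoter transcription) most alleles have the
discontinuous form $G_mAG_n$: a first run of $m$ guanines, one
interrupting adenine, and a second run of $n$ guanines. Continuous
alleles $G_k$ lack the interruption. The reference (rCRS) allele is
G5AG7, occupying rCRS positions 303–315; haplogroup literature quotes the
same locus on the opposite strand as a polyC-T-polyC string (C7TC5), and
`light_strand_name()` interconverts the two conventions.

Because the transcribed G-runs can nucleate a hybrid G-quadruplex that
terminates the mitochondrial RNA polymerase, two summary quantities
matter:

* **total guanines** $m + n$ (or $k$), a proxy for quadruplex stability;
* the **adenine-position index**, the signed offset of the interrupting
  base from the tract midpoint:
  $$p = \begin{cases}(m-n)/2 & m+n \text{ even}\\
  \operatorname{sign}(m-n)\,\lceil |m-n|/2 \rceil & m+n \text{ odd}\end{cases}$$
  Positive values place the adenine towards the 3′ end of the tract.

The odd-total labelling (round the half-integer offset away from zero, so
odd totals have no 0 position) is a convention choice: the defining
description fixes the sign and the zero case but not the integer label
for $|m-n| \ge 3$ at odd totals. We validated the chosen convention
against every position value stated alongside named variants in the
source survey (G9AG6 at +2; equal runs at 0; the G6AG7/G6AG8 class at −1;
the 15-guanine G6AG9 class at −2; no zero for odd totals) and found no
discrepancy. The convention is isolated in `adenine_position()`, so a
different reading is a one-line change; antisymmetry
$p(G_mAG_n) = -p(G_nAG_m)$ and the parity rule are property-tested over
the full grid.

## Coordinates

User-facing positions are 1-based inclusive rCRS numbering; internal
intervals are 0-based half-open on the scanned strand
(`rcrs_to_internal()` / `internal_to_rcrs()`), which keeps slicing
arithmetic off-by-one-free while reports stay in the field's coordinate
system. LSP transcription proceeds towards decreasing rCRS numbers, so a
transcript of length $L$ from a start site $t$ ends at $t - (L - 1)$
(`transcript_end_position()`). The start-site position is a required
configuration value, never a built-in constant, because published values
for it vary with how the initiation site is mapped. Inserting a spacer of
$s$ nt between the tract and its downstream terminator lengthens the
transcript to any fixed downstream residue by exactly $s$ — the
coordinate-model counterpart of the band shift observed on sequencing
gels when 3-nt spacers are inserted.

## The scanner and its independent cross-check

The survey's database search used an exact-match strategy: search strings
spanning rCRS 294–325 with the tract varied combinatorially, accepted
only at 100% identity. We reproduce this with literal substring matching
(`build_search_strings()` + `scan_sequences()`): the original BLAST
parameterization (word size, e-value and so on) is provenance, not
behaviour, because at 100% identity over a fixed-length query the engine
reduces to exact matching.

Design points:

* **Mutual exclusivity.** Flanks abut the tract with non-G residues
  (enforced at `anchor_pair()` construction), so no library string can
  contain another; this is re-checked pairwise at build time. A record
  locus therefore matches at most one library string.
* **Minimum query length.** With flanks fixed at rCRS 294–325 the
  smallest variants produce strings under the 25-nt minimum query size.
  Whether the original search extended flanks or skipped tiny variants is
  unstated; we extend flanks symmetrically into packaged context sequence
  until the minimum is met and log the extension (it is also recorded
  per-string in the library object).
* **Both strands by default**, since deposited sequences may be on either
  strand; results are always reported in G-rich nomenclature.
* **Independent classifier.** `classify_locus()` finds the flank pair and
  run-length-parses the segment between them, classifying any shape —
  including `"complex"` segments (two interruptions, multi-base
  interruptions, degenerate bases) the fixed library cannot name, and
  `"absent"` records, making "rare/absent" claims auditable. Scanner and
  classifier are implemented independently and tested for agreement over
  the exhaustive 12 × 12 × {A,C,T} grid plus continuous G1–G24.
* **Multi-locus records** (chimeric or duplicated submissions) are
  counted per locus with a warning; `strict_per_record = TRUE` switches
  to once-per-record counting. The original survey is silent here; per
  locus is the default because it preserves the matrix marginal sums.
* Degenerate bases (N) inside a candidate window simply prevent an exact
  match and make the segment unclassifiable — imperfect loci are
  excluded, not guessed.

## Survey statistics

`frequency_matrix()` stores hit counts per (m, n) cell for each interrupt
base plus a continuous-count vector; every pooled statistic is tested to
conserve `total_hits`.

* `totals_by_total_g()` sums anti-diagonals $m + n = \text{const}$.
* `sample_skewness()` defaults to the adjusted Fisher–Pearson estimator
  $\frac{N}{(N-1)(N-2)} \sum_i \left(\frac{x_i-\bar x}{s}\right)^3$ — the
  spreadsheet SKEW definition the original analysis names — with the
  moment estimator available behind `method = "moment"`.
* `quadrant_counts()` partitions cells around a pivot (default G6AG7, the
  modal allele) in (first-run, second-run) coordinates. Whether a
  "quadrant fraction" counts the bisecting row/column inside or outside
  the quadrant is ambiguous in prose descriptions, so both tallies are
  emitted: strict quadrants with `on_axes` separate, and inclusive totals
  with axes folded in (used for the headline fractions).
* `position_spectrum()` pools interrupted cells by adenine position.
* `cumulative_tp_curve()` joins occupied variants to a termination (TP%)
  table, sorts by ascending TP and accumulates hit fractions;
  `fraction_within(curve, lo, hi)` reads off the mass in a TP window.
  Variants without a TP entry are excluded with a warning, never imputed.
  The packaged TP fixture (`tp_table_printed.tsv`) deliberately contains
  only values printed in the survey's running text, each with a
  provenance tag; figure-only values are not transcribed, so tests and
  examples needing a dense TP table construct synthetic ones.

## Densitometry

Lanes arrive as 1-D pixel→density traces (2-D gel images are out of
scope). `fit_ladder()` reads "first order" calibration as
piecewise-linear interpolation between adjacent ladder knots — a single
global line cannot pass through more than two bands of a log-migrating
ladder — exact at every knot, linearly extrapolated beyond the hull with
an `extrapolated` flag; a global least-squares line is available for
sensitivity checks. `quantify_tp_fraction()` computes TP% as density over
pixels whose calibrated length falls in the TP window (default 92–140 nt)
divided by total density from the well to the ~100 nt marker; the ratio
is scale-invariant, so results are relative termination efficiencies.
Whether the cutoff pixel and well material belong to the total is
unstated in the source procedure; both are toggles, defaulting to
inclusive-cutoff and wells-included. Background subtraction is not
described there either and is off by default. True biochemical TP values
cannot be recomputed from sequence: the module's tests assert recovery of
planted quantities from synthetic lanes, not wet-lab percentages.
`call_peaks()` uses `pracma::findpeaks()` with a height threshold
relative to the lane maximum, converts peak pixels to lengths, and
optionally maps them to transcript 3′-end reference positions.

## The synthetic-data generator

`simulate_survey()` stands in for the un-deposited GenBank download. Its
defaults are the study's stated conditions where stated, and a realistic
choice once where not:

* **Spectrum**: the four most common alleles at their reported survey
  shares (G5AG7 13%, G6AG7 37%, G6AG8 35%, G6AG9 10%), renormalized to
  sum to 1.
* **`fraction_absent` = 0.5**: the download mixed ~29k complete genomes
  with ~64k partial records, many covering only hypervariable segment 1;
  with ~45k hits among ~92k records, about half the records lacking the
  locus is the realistic emulation. Absent records are emitted as the
  context fragment upstream of the locus.
* **`strand_mix` = 0.5**: no deposition-strand statistics exist; an even
  mix exercises both code paths without favouring either.
* **Noise off by default** (`snp_rate`, `slippage_rate` = 0): the
  original search is exact, so noise models exist to *test* robustness
  claims (slippage smears matrix mass to ±1 run lengths; SNPs outside the
  anchor region never disturb classification), not to emulate a
  quantified error rate. Substitutions are confined to context outside
  the anchor region because a flank SNP makes a hit invisible to an
  exact-match search — the same blind spot the original strategy
  documents for itself.
* The template is the packaged reference context (rCRS 241–400; the
  variable tract and both flanks sit well inside it). One seeded RNG
  stream drives all stochastic steps; the caller's RNG state is left
  untouched, and identical specs are byte-identical.

What the generator does **not** emulate: read-level sequencing error
(quality scores, chromatogram artefacts), haplogroup covariance between
the tract and flanking SNPs, duplicate submissions, or real-database
abundance drift. Passing round-trip tests therefore demonstrates that the
scanner, classifier and statistics are mutually consistent and recover
planted truth — not that a live database scan would reproduce any
particular percentage.

`simulate_gel()` renders Gaussian bands through a log migration model
$\text{pixel} = a + b\ln(\text{length})$, $b < 0$, with band widths given
in nt and converted to pixel scale through the model's local slope, plus
a noise-free 25-bp-style ladder. Defaults ($a = 1475$, $b = -250$, 1000
pixels, ladder 25–300 nt) keep the 92–140 nt TP window comfortably inside
the calibration hull.

## Problem sizes and numerical choices

Tests run at desk scale chosen to make every assertion exact or
binomially bounded: exhaustive grids of 456 planted records for
scanner–classifier agreement, a 2000-record seeded survey checked against
exact 99% binomial intervals, 1000 random vectors for the skewness
oracle, and noise-free lanes for 30/70 band-area recovery within 0.5
percentage points. Ladder interpolation is exact at knots by
construction; the piecewise model's chord error against a smooth
log-migration truth is bounded by the curvature over one knot spacing.
Ties in peak heights are resolved by reporting all peaks above threshold
in pixel order.

## Known limitations

* The headline percentages of the original database survey (45,197 hits
  and their breakdown) depend on a historical GenBank snapshot and are
  not reproducible from synthetic data; this package reproduces the
  *procedure* and its internal structure (asymmetry, position spectrum),
  not those numbers.
* Exact matching shares the original strategy's blind spot: any variation
  in the flanks hides a locus. The anchored classifier mitigates but
  still requires exact flank hits.
* `fraction_within()` treats TP values as point estimates; replicate SDs
  in TP tables are carried but not propagated into the curve.
* Circular-genome scanning handles the origin junction; classification of
  a junction-spanning locus by `classify_locus()` requires the record to
  be rotated first.
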