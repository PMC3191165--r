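---
title: "Calling band/interband maps from open-chromatin evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling band/interband maps from open-chromatin evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoband)
```

## The model

Interphase chromosomes — spectacularly visible in *Drosophila* polytene
nuclei — alternate dense chromatin bands with decompacted interbands.
Interbands are where the open-chromatin machinery lives: interband-associated
proteins (Chriz/CHRO, BEAF-32, WDS, BRE1, RNA polymerase II, NURF, TRX, GAF),
DNase I hypersensitive sites, dips in linker-histone H1 occupancy, histone
variant H3.3, and ORC binding all co-localize there, while the largest bands
are late-replicating intercalary heterochromatin (IH) bound by SUUR, D1 and
lamin. This package turns that observation into a calling procedure:

1. group evidence tracks into **classes** (`interband_protein`, `dhs`,
   `h1_dip`, `orc`, `active_state`, `histone_variant`), pooling a marker's
   cell types (union by default) and a class's markers (union);
2. count, per base, how many distinct classes cover it;
3. take maximal runs with at least `min_support` classes as interband
   candidates, merge candidates across small gaps, apply size limits;
4. fill the complement in as bands.

Counting *classes* rather than tracks means five redundant protein tracks
cannot outvote the absence of an orthogonal line of evidence such as DHS or
an H1 dip. The complement step encodes the definition of a band as the
distance between two neighboring interband borders.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `min_support` | 2 | evidence classes | one class can be spurious; two independent open-chromatin signatures rarely co-occur by chance |
| `combine_cells` | union | — | published panels display cell types side by side and call borders cell-type-agnostically |
| `merge_gap` | 500 | bp | one smoothing step of the upstream 1-kb/500-bp windowed profiles |
| `min_size` | 300 | bp | below the border resolution of smoothed tracks |
| `max_size` | 10000 | bp | mapped interbands span roughly 600–3000 bp; 10 kb is a loose ceiling |
| `tss_slop` (annotation) | 250 | bp | interbands are sub-kilobase; a TSS within a quarter kilobase is "at" the interband |
| `t_late` (band typing) | 0.4 | fraction | one canonical IH band is late-replicating over only its distal 40% |
| window / step (smoothing) | 1000 / 500 | bp | the standard sliding-window treatment of tiling-array enrichment profiles |

All are surfaced in `caller_params()` and the respective function arguments.
The upstream thresholds that produced any given published interval set are
generally unstated; the defaults above are declared choices, not inferred
ones, and sensitivity to them can be explored directly (e.g. the
anti-monotonicity of called bases in `min_support` is a tested invariant).

## Calls, peaks and edges

A call's interval is exactly the consensus run — the maximal stretch with at
least `min_support` evidence classes — so `call_interbands()` agrees base
for base with a brute-force per-base voting oracle (a tested property up to
50-kb regions). Two derived views exist:

* the **peak**, the midpoint of the maximal evidence-count run inside the
  call (leftmost on ties), the natural anchor for point annotations;
* the **refined edges** (`refine_borders()`, or `refine = TRUE`), the
  outermost bases of the union of supporting features overlapping the call,
  clipped at the midpoint to a neighboring call. This is the "edges of the
  feature distributions" view used when drawing maps; it is deliberately not
  the default because the union extent is biased outward by the most
  divergent single feature, which degrades border accuracy on small
  interbands.

## Rounding in the compaction table

DNA contour length is `c = b × 0.34 / 1000` µm for `b` base pairs. Published
compaction tables (i) round `c` to two decimals *before* dividing by the
axial length `a` — a 600-bp interband with `a = 0.043` µm gives
`0.20 / 0.043 = 4.65`, not the full-precision 4.74 — and (ii) round exact
decimal ties in the ratio *down* (a ratio of exactly 31.875 prints as
31.87). `compaction_table()` reproduces both behaviors in its default
`rounded_first` mode and carries exact columns (`c_um_exact`,
`ratio_exact`) alongside. Axial-length standard deviations are carried
through but not propagated into ratio uncertainty.

## Printed coordinate tables and the boundary base

Printed band/interband tables give 1-based pairs `s..e` whose printed length
column equals `e − s`. `read_band_table()` converts each pair to the
internal half-open interval `[s − 1, e − 1)` so that `interval_length()`
reproduces the printed lengths exactly. Under that arithmetic, consecutive
rows with `next_start = end + 1` leave one base per boundary belonging to
neither structure — the printed tables are internally inconsistent by one
base per border, and no conversion can make lengths *and* tiling both exact.
We keep lengths exact: element-wise maps of printed tables load with
`banding_map_from_elements(strict = FALSE)` (the unassigned bases are
reported in `attr(, "boundary_gap_bp")`), whereas maps built by
`build_banding_map()` — interbands plus their complement — always tile
exactly and satisfy `interband_bp + band_bp = region_bp`.

Similarly, a region's *reported* summary totals in the literature sometimes
disagree with its printed coordinates (e.g. 20,100 bp of interband DNA and a
428,307-bp span reported against coordinates summing to 18,400 bp in a
427,600-bp span). This package always computes from coordinates;
`interband_fraction()` is exposed separately so reported totals can be
checked as stated-input worked examples.

## The synthetic generator

`generate_region()` emulates the structure such maps are called from: nine
interbands (600–3000 bp) separating eight bands, the outermost two being
150–200-kb IH bands and the middle six 2–17-kb faint bands (the region
starts and ends with an interband, as the mapped region does; `flank =
"band"` flips this). Each interband receives each evidence class with
probability `snr / (1 + snr)`; features are copies of the interband with
Gaussian border jitter (`border_jitter_sd`, default 50 bp — the scale of
probe spacing on the tiling arrays that define enrichment borders); spurious
features are planted outside interbands at expected count
`n_interbands / (1 + snr)` per class, so the fraction of a class's features
with midpoint in a true interband is `snr / (1 + snr)` in expectation — the
enrichment-odds meaning of `snr`. IH bands carry late-replication, SUUR and
lamin cover (`ih_late_fraction` controls partial late replication, e.g.
`c(1, 0.4)` for one fully late and one distally-late band) and BLACK state
labels; faint bands are YELLOW with no open-chromatin features; interbands
are RED. Gene models place most interbands at divergent promoter pairs, one
in a pure intergenic gap, one inside a long first exon, and one mid-gene
(the exception), genes being sized never to cross the midline of a flanking
band. Transposon insertions are Poisson at 5/kb in interbands vs 0.5/kb in
bands. Axial lengths are back-computed from planted compaction ratios
(IH 150–210×, faint 10–75×, interbands 3–15×).

One integer seed drives a single generator stream (element sizes, then
marker presence and jitter per class, spurious features, insertions, axial
lengths, genes), so `generate_region()` is bit-reproducible.

What the generator does **not** emulate: probe-level array signal and its
normalization (features are already interval calls), correlated noise
between evidence classes, cell-type heterogeneity of borders (cell types get
independent jitter only), underreplication gradients within IH bands, and
sequence-level features. Passing recovery tests therefore demonstrates the
interval-consensus logic, not robustness to raw-signal artifacts.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open throughout; empty intervals (length 0)
  are legal in memory but never written to BED.
* Window means ignore missing values, weighted by the defined bases covered;
  an all-missing window propagates `NA` rather than fabricating depletion,
  and an all-missing track is an error.
* Insertion positions on a bin boundary belong to the bin starting there;
  densities keep the nominal denominator in a clipped trailing bin so that
  counts are conserved exactly.
* Peak ties resolve leftmost; a probe equidistant from two calls reports the
  left call with a tie flag.
* The open-chromatin veto in band typing uses midpoint containment, so
  features of a flanking interband that merely graze a band border do not
  count as open chromatin *in* the band.
* `orc_spacing()` reports a span with zero sites as status `"absent"`, not
  as an infinite number.

## Problem sizes

The shipped tests exercise the caller against per-base oracles on regions up
to 50 kb, and end-to-end recovery on twenty ~430-kb synthetic regions; the
acceptance script regenerates twenty synthetic regions per run. These sizes
keep every check well under a few minutes on a single core while matching
the scale of the mapped region the fixtures describe.

## Known limitations

* Single-region, single-chromosome scope; no genome-wide indexing, no
  bigWig/BAM input (interval calls and windowed TSV tracks only).
* No statistical significance model for enrichment: the caller consumes
  already-thresholded interval evidence, and `compare_maps()` reports
  Jaccard overlap rather than a significance test.
* Band typing is rule-based (coverage thresholds), not probabilistic; with
  partial late replication exactly at `t_late` the classification follows
  the `>=` convention.
* The printed-table boundary-base ambiguity above is inherited, not
  resolved: coordinate-derived totals differ from reported totals by design.
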