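---
title: "Methods: comparing homologous loci with CAGE promoters and alignment anchors"
author: "homolocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing homologous loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`homolocus`. It is the package's reference for *why* the code does what it
does; the README shows *how* to run it.

## Coordinate model

All coordinates in memory are `GRanges`: 1-based, closed intervals, the
Bioconductor convention. Conversions happen only at I/O boundaries: GTF
(1-based inclusive) passes through unchanged; BED, CTSS and UCSC chain input
(0-based half-open, with chain query coordinates expressed on the query
strand) are converted on import and back on export. Keeping a single internal
convention on top of the GenomicRanges stack means every overlap, disjoin and
reduce operation used by the package is the extensively tested IRanges
implementation rather than hand-rolled arithmetic; the trade-off is that
boundary examples stated in 0-based half-open terms must be translated by one
base at the I/O surface, which the import/export tests pin down explicitly.

"Overlap" always means at least one shared base under these closed-interval
semantics; intervals that merely abut do not overlap. Regions clipped at
sequence bounds (when a chromInfo-style length registry is supplied) are
clipped silently — a promoter window near the origin is simply shorter, not
an error.

## CAGE tag clusters

Tags are collapsed CAGE reads: a span, a strand-aware 5′ end and a count.
Clustering is single linkage per (sequence, strand): two tags belong to one
tag cluster exactly when a chain of pairwise ≥ 1 bp overlaps connects them.
This is implemented as `GenomicRanges::reduce(min.gapwidth = 0L)`, which
merges overlapping but not abutting ranges — the unit tests verify the
resulting partition against a brute-force union-find over all O(n²) tag
pairs.

Per cluster:

* **representative position** — the 5′-end position with the largest summed
  count; ties resolve to the 5′-most position relative to the strand
  (smallest coordinate on `+`, largest on `-`), making the result
  deterministic under any input order.
* **tpm** — count × 10⁶ / library size. The library size defaults to the sum
  of retained counts (so tpm sums to 10⁶ over a library), with an override
  for the true mapped-tag total when upstream filtering removed tags.
* **shape** — the sharp/broad dichotomy is computed as the count-weighted
  interquantile width of the member 5′ ends: position at the 0.90 quantile
  minus position at the 0.10 quantile, both via the left-continuous inverse
  CDF; width ≤ 4 bp is *sharp*. The quantile pair and the cutoff are
  parameters (`shapeQuantiles`, `sharpWidthMax`) because the shape-class
  literature varies in the exact constants; the defaults are the standard
  interquantile formulation used for CAGE promoter classes.

Cluster-to-gene assignment uses the **representative position**, not the
cluster span: a cluster maps to a transcript when it lies on the same strand
and its representative position is inside the closed window
[TSS − 500, TSS + 500]. The span-overlap alternative would let one long
cluster attach to several genes; the representative position is the sharper
and reproducible choice. The window is closed on both ends — a cluster at
exactly TSS + 500 is in, TSS + 501 is out. Per transcript the highest-tpm
candidate wins; the gene representative is the highest-tpm candidate over all
its transcripts, ties broken by higher total count, then 5′-most position.

## Chains and anchors

A UCSC chain is parsed into its header and gap-free blocks; the block
arithmetic (Σ(size + dt) and Σ(size + dq) against the header spans) is
verified for every chain and a malformed chain aborts the file load —
silently skipping a corrupt alignment would silently change every downstream
multiplicity call. Blocks are normalized so both sides are plus-strand
coordinates, with the original relative orientation kept as a `same`/
`opposite` flag; minus-strand query blocks [s, e) convert as
[q_size − e, q_size − s). The parser is the package's own because the anchor
machinery needs per-block chain identity and scores; `rtracklayer::liftOver`
over the same files serves as an independent cross-check in the test suite.

Interval mapping is a per-block offset map (mirror-offset for `opposite`),
covering exactly the aligned portion of the input; the tests compare it
base-by-base with a brute-force lift built directly from the raw chain
numbers, and verify the t→q→t round trip.

**Anchors.** Every block overlapping the region of interest, trimmed to it,
is a candidate anchor. The reference footprint is split (`disjoin`) into
atomic segments with a constant set of covering chains: one covering chain
makes a 1-to-1 anchor, two make 1-to-2 anchors from each chain, and where
more than `maxAnchorLoci` (default 2) chains cover a base only the
highest-scoring `maxAnchorLoci` survive there, with ties broken by larger
aligned span in the region and then lexicographic chain id. Applying the
competition per constant-coverage segment (rather than once per region)
keeps distinct 1-to-2 relationships alive along a long region while making
the per-base contract exact: no reference base ever carries more than
`maxAnchorLoci` chain ids, and the per-base outcome equals a brute-force
count of covering chains after top-k filtering. One chain is treated as one
candidate homologous locus — chains are the unit UCSC assigns to a syntenic
alignment. Contiguous same-chain segments with the same class are re-merged
so the output is not fragmented. Colors (gray for 1-to-1, blue for 1-to-2)
are display tags, configurable in `locusParams()`.

**Self-chains.** For within-genome paralogs the same extraction runs after
discarding trivial chains in which a span aligns to itself (same sequence,
same span, plus orientation); tandem chains on one sequence are kept.

**Bridged composition.** When two loci B and C in one assembly have no
direct alignment but both align to an outgroup assembly A (A on the target
side of both chain sets), the region in B is mapped back to A, the A
footprints of both chain sets are intersected, and every intersection maps
forward into B and into C. Composed orientation is the product of the two
block orientations, the composed score the minimum of the two chain scores,
and multiplicity is classified over the composed chain pairs exactly as for
direct anchors. Composed anchors narrower than `minAnchorWidth` (default
10 bp) are dropped: 1 bp slivers arise routinely from double trimming and
carry no visual or biological information; the filter is a parameter because
no principled threshold exists. By construction this method cannot see
similarity between B and C that is absent from A — segments lost in the
outgroup lineage are invisible — which is documented rather than
compensated.

## The three views

* **Promoter view** — each side shows the union of the per-transcript
  promoter windows (TSS ± `promoterFlank`, default 500 bp, i.e. 1000 bp
  windows, symmetric in genomic coordinates on both strands). A reference
  tag cluster and a target tag cluster are *shared* when the reference
  representative position lies in an anchor, its mapped position is within
  `sharedTssTolerance` (default 100 bp) of the target representative
  position, and the strands are consistent with the anchor orientation.
  Candidates are paired greedily by smallest mapped distance, ties by higher
  combined tpm, each cluster in at most one pair — a deterministic rule
  chosen because the display-oriented original establishes sharing visually
  and states no pairing rule. Unpaired clusters are promoter *turnover* on
  their side; shared + turnover partitions each track.
* **Gene-structure view** — each side shows the transcript bounding box
  ± `transcriptFlank` (default 500 bp). Per-exon conservation is the
  fraction of exon bases covered by at least one anchor interval, computed
  for both sides; it is 0 with no anchors, 1 for exons inside an anchor, and
  monotone non-decreasing as anchors are added.
* **Neighborhood view** — each side shows a window of twice
  `neighborhoodHalfWidth` (default 1 Mb, i.e. 2 Mb) centered on the midpoint
  of the gene bounding box (the "center" of a gene is not otherwise
  defined). Links here are gene-homology links from the homology table
  (always including the query pair), each flagged for strand agreement, plus
  a view-level conserved-order flag: target partners monotone (increasing or
  decreasing — an inversion preserves order) along the reference gene order.
  Gene links rather than sequence anchors are used because at the 2 Mb scale
  the informative signal is gene content and order; sequence anchors can be
  overlaid by computing them separately.

Views serialize to JSON (schema_version 1.0; all coordinates 1-based closed
as in memory) with a lossless `readViewJSON()` inverse, or to a two-panel
SVG in which anchor ribbons are colored by multiplicity and tag-cluster bar
heights are proportional to tpm. Raw tpm is plotted (the original display may
have used tissue-weighted expression; tissue resolution is out of scope
here). The SVG is presentation-only; the JSON is the machine-readable
surface.

## The fixture generator

`simulateHomologousLoci()` emulates the three study scenarios — orthologs in
two assemblies, within-genome paralogs via self-chain, and two duplicated
loci bridged through an outgroup — from one ancestral layout: `nGenes`
(default 6) genes, each with `nTxPerGene` (default 2) alternative promoters
spaced 1200 bp apart, three exons (150/200/180 bp) and fixed introns
(700/600 bp), random strands, 4–6 kb intergenic spacing. Descendant loci are
the ancestor under a constant offset plus random indels (one 30–150 bp
insertion or deletion per eligible gap, probability `indelRate`, default
0.15), which become the chain gaps. Indels are confined to the free zones
outside a ±560 bp pad around every TSS and outside exon bodies, so planted
promoter positions map exactly through the emitted chains and exon
conservation is exactly 1; with `exonIndels = TRUE`, internal exons also
receive deletions (30–60% of the exon, or the whole exon with probability
0.2), exercising fractional conservation with known truth. One CAGE tag
cluster is planted per transcript TSS on the reference locus and copied to
the homologous position with probability 1 − `tssTurnoverProb` (default
0.3, a realistic turnover rate between moderately diverged loci); half of
the turnover events instead gain a novel target cluster shifted 150–250 bp,
beyond the 100 bp sharing tolerance but within the locus. The default sizes
keep a full end-to-end run (simulate, cluster, anchor, view) well under a
second so the 50-seed stochastic recovery check stays inside a few minutes
on one CPU.

What the generator does **not** emulate: sequence content (it is
coordinate-only), inversions between homologous loci (opposite-orientation
arithmetic is exercised by the chain and anchor unit tests instead),
multi-mapping tag noise, tissue-resolved expression, and unequal gene
complements between the loci. Passing end-to-end tests therefore demonstrate
the correctness of the coordinate pipeline on clean homology, not robustness
to assembly error or annotation noise in real data.

## Numerical and degenerate-case choices

* Quantile positions for the shape class use the left-continuous inverse
  CDF (smallest position with cumulative fraction ≥ q), so the width is
  always realized by actual tag positions.
* Greedy shared-TSS pairing sorts by (distance, −combined tpm, indices); all
  tie-breaks are total orders, so results are independent of input order.
* A transcript with a single 1 bp exon has a well-defined TSS on either
  strand; a gene whose transcripts share one TSS has a promoter span of
  exactly 2 × `promoterFlank`.
* Empty inputs (no tags, no chains overlapping a region, empty homology
  table) produce empty but valid results, never errors; malformed inputs
  (negative counts, unknown strand or relation tokens, inconsistent chain
  arithmetic, same-species self-pairs) fail fast with the offending record
  named.
* `bridgeAnchors(X, X, region)` reproduces the identity on the aligned
  portion of the region — a useful sanity check that composition introduces
  no off-by-one drift.

## Problem sizes used by the checks

The test suite validates clustering against the union-find oracle on 20
libraries of 1000 random tags; chain mapping against a per-base lift on
10 kb genomes with 1000 random intervals including minus-strand chains;
anchor multiplicity on random instances of up to 5 chains over 2 kb;
bridge composition per-base on 10 kb toy genomes; and end-to-end recovery on
fixtures at turnover probabilities 0 and 1 (exact truth match) and 0.3
(50 seeds, pooled recovered turnover within three binomial standard errors
of 0.3). `scripts/acceptance.R` re-runs the same pipeline from scratch at a
caller-supplied seed and reports the resulting quantities as JSON.

## Known limitations

* Chain/net filtering is not applied: every chain in the input file is
  eligible as a locus. Users wanting netted best chains should pre-filter.
* Gene models from different sources (e.g. two annotation sets) are treated
  as independent inputs, not merged.
* The bridge method inherits the outgroup-visibility limitation described
  above.
* The 2 Mb neighborhood window replaces externally defined synteny blocks in
  all comparisons.
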