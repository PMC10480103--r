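---
title: "Substitution mapping with single-segment substitution lines: models and methods"
author: "sslmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substitution mapping with SSSLs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sslmap)
```

## The experimental design this package models

A single segment substitution line (SSSL) carries exactly one homozygous
donor chromosome segment — delimited by SSR markers — in an otherwise
uniform recipient background. A library of such lines tiles the donor
genome across the recipient, so each line and the recipient form a
near-isogenic pair. Two questions drive the analysis:

1. **What does the library look like?** Total and mean substituted length,
   the genome fraction covered by the union of segments, and how coverage
   accumulates across several donor populations.
2. **Where is the gene?** When some lines show a donor-like binary trait
   (large tiller angle, spreading panicle, awn, seed shattering, red
   pericarp, ...), the causal locus must lie in every carrier's segment and
   outside every non-carrier's segment. Intersecting and subtracting those
   physical intervals — substitution mapping — yields a candidate region,
   which is then compared positionally and by sequence against cloned
   genes to decide between a known allele and a novel locus.

## Coordinates and interval arithmetic

Segments are written with the 1-based physical positions of their two
delimiting markers, `(start, end)`, and treated as the half-open base-pair
set `(start, end]`, so `length = end - start`. This is the convention under
which published marker coordinates reproduce published interval sizes
(e.g. 20,286,300–21,478,312 bp is 1.19 Mb). Two practical consequences:

* segments sharing only a boundary marker do **not** overlap (the marker
  is a point, not a base pair shared by both), and subtracting a segment
  that merely touches removes nothing;
* Mb and percent values are rendered by half-up rounding to two decimals
  (`toMb()`), because that is how physical-map sizes are printed; base
  R's banker's rounding would disagree on exact halves.

Internally every operation converts to closed integer ranges
`[start + 1, end]` and delegates union/intersection/difference to IRanges,
converting back afterwards. The unit and acceptance suites check all three
operations against an independent per-base-pair occupancy scan on random
cases, so the coordinate shim, not IRanges, is what is being trusted.

## Constitution statistics

For one population: `total length` is the sum of per-line segment lengths,
`mean length` divides by the line count, `coverage length` is the length
of the union of all segments, and `coverage percent` divides by the genome
length. For several populations the `coverage rate` sums the per-population
coverage lengths before dividing, so it can exceed 100% — three libraries
independently covering half the genome give a 150% rate. The genome
denominator always comes from the genome table supplied by the user (a
published IRGSP-1.0 chromosome-length table ships with the package);
no genome size is hard-coded.

## Substitution mapping

The mapping model is single-locus and fully penetrant: a line shows the
donor-like state iff its segment covers the causal position. SSSLs are
homozygous, so dominance and penetrance are not separable from carrier
status and are not modelled. Mapping proceeds in two steps:

* **Grouping.** Carriers are grouped by chromosome and then into connected
  components of the segment-overlap graph. Each component is mapped
  independently — two disjoint carrier clusters are evidence for two loci,
  not a contradiction.
* **Mapping.** Within a component, the candidate interval is the
  intersection of all carrier segments minus the union of all non-carrier
  segments on that chromosome. Non-carriers whose segments never touch the
  carriers' common region contribute nothing (and are not listed as
  excluders). Flanking markers are the nearest marker at-or-outside each
  boundary.

An empty result means the observations contradict the single-locus model
and is an error by default. The optional `maxConflicts = k` relaxation
searches exactly over dropping up to `k` constraining observations and
reports the largest surviving interval; the search is combinatorial and
meant for `k` of 1 or 2. When exclusions split the region, all
sub-intervals are reported and the locus is flagged ambiguous rather than
silently merged.

Two useful monotonicity facts follow from the set algebra and are tested
as properties: adding an informative line can only shrink (never widen)
the interval, and the mapped region always contains the causal position
when phenotypes are noise-free.

## Allelism calls

A mapped locus is compared to each catalogued cloned gene of the same
trait. Positional relation is `contained`, `overlap`, `proximal`
(disjoint, gap at most 1 Mb by default) or `distal`; a gene without
published coordinates is `untestable`. The 1 Mb default mirrors the
workflow in which a gene ~0.6 Mb outside the interval is still considered
"very close" and sequenced before the locus is declared novel; it is a
configurable screening radius, not a biological constant.

The verdict combines position with sequence evidence (the result of
comparing the gene's sequence in the carrier line versus the recipient):
identical sequence rules the gene out (`novel`) whatever the position;
`distal` is `novel`; `contained`/`overlap` plus observed variants is
`allele_candidate`; everything else is `inconclusive`. Partial overlap is
treated like containment because mapped intervals bound, rather than
pinpoint, the gene. One deliberate consequence: a gene with no coordinates
can never be promoted to `allele_candidate` on sequence evidence alone —
the call stays `inconclusive` and the evidence is reported, leaving the
judgement to the analyst.

## CDS comparison and consequence annotation

Recipient and donor CDS are aligned end-to-end (Needleman–Wunsch, affine
gaps; match +2, mismatch −3, first gapped base −6, each further gapped
base −1; N scores 0). The published analyses used an interactive alignment
tool with unstated parameters, so the scheme here was fixed once for
determinism; the suite checks the score against an independent Gotoh
dynamic program. Mismatch columns become SNPs; each maximal gap run
becomes one indel. Indels are left-normalized (shifted through repeats to
the leftmost equivalent placement), which makes variant descriptions
independent of the aligner's tie-breaking.

Consequences are annotated against the reference reading frame:
`codon_index = ceiling(pos / 3)`; SNPs by translating the reference versus
mutated codon (synonymous / missense / stop_gained / stop_lost); indels by
the length-mod-3 rule — a multiple of 3 is an in-frame event changing the
protein by `length / 3` residues, anything else is a frameshift. A SNP
inside a codon also affected by an indel is still reported in the
reference frame; compound effects surface only in the summary's
`protein_length_delta` (net nucleotide change over 3, defined when that
net is a multiple of 3). Translation uses the standard genetic code,
stops at the first stop codon (rendered `*`), renders N-containing codons
as `X`, and never applies initiator-codon special cases (a non-ATG first
codon translates literally, with a warning at annotation time).

This reproduces the published allele arithmetic exactly: an 18-bp
codon-boundary deletion removes 6 residues, a 72-bp insertion adds 24,
and a 14-bp deletion is a frameshift.

## The synthetic-data generator

The simulator exists so the whole pipeline runs and is testable with no
external data. It generates, deterministically from a seed:

* a genome (default: the 12 packaged rice chromosome lengths) with
  markers at jittered ~1.5 Mb spacing;
* libraries with one segment per line — chromosome sampled proportional
  to length, anchor uniform, raw length exponential with mean 5 Mb
  truncated to [0.2 Mb, chromosome length], endpoints snapped to the
  nearest markers (the default line counts, 123/39/133 across three
  donors, and the length scale match a real three-population rice SSSL
  design with per-population means of roughly 4–6 Mb);
* causal genes planted strictly inside one inter-marker gap of a random
  line's segment. Because segments are marker-delimited, a segment then
  covers either the whole gene or none of it, so noise-free phenotypes
  are exactly the carrier model and mapping must recover the gene — the
  500-simulation recovery property tests the pipeline, not luck;
* binary phenotypes from gene overlap, optionally flipped with
  probability `epsilon` (default 0);
* CDS pairs with planted SNPs and indels whose normalized ground truth is
  returned, enabling exact round-trip checks of the variant caller.

What the generator does **not** emulate: the backcross breeding process
itself (no recombination model is published for it — segments are drawn
directly), heterozygous or multi-segment lines, genotyping error, marker
dropout, and any empirical segment-length distribution (the exponential
default is a stand-in). Passing tests on synthetic data therefore
demonstrate the correctness of the interval algebra, the mapping logic
and the variant arithmetic — not robustness to the messiness of real
genotyping data.

## Numerical and scale choices

Degenerate segments (`start >= end`) are rejected at construction;
markers must lie within their chromosomes; out-of-bounds segments are
reported with the offending line id. Seeds enter through a single wrapper
that restores the caller's RNG state. The property suites run at sizes
chosen to finish in minutes on a laptop while keeping the statistics
meaningful: 1000 random interval cases on 100 kb toy chromosomes against
the occupancy oracle, 1000 seeded variant round trips (required recovery
at least 99%; the rare misses are alignment-equivalent edit sets, e.g. a
SNP adjacent to an indel that an optimal alignment merges), and 500
simulated libraries of 30 lines on four 25 Mb chromosomes for planted-gene
recovery (required: 100%).

## Known limitations

* Positions are CDS coordinates throughout; no exon/genomic mapping is
  attempted, so published positions quoted in exon coordinates must be
  converted by the user.
* The allelism verdict is a screening rule, not a statistical test; it
  encodes the qualitative published workflow.
* `coverage_rate` compares each population's union, not line-level
  redundancy within a population (that redundancy is visible in
  `total_length` versus `coverage_length`).
* Variant counts are of normalized events; a tool counting alignment
  columns can report different InDel totals for the same pair.
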