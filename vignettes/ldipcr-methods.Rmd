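---
title: "Detecting somatic L1 3' transductions from LDI-PCR long reads: models and methods"
author: "ldipcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic L1 3' transductions from LDI-PCR long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldipcr)
```

## The assay and what the package computes

Active LINE-1 (L1) retrotransposons occasionally co-mobilize the unique
genomic sequence downstream of their weak canonical polyadenylation signal
(a *3' transduction*). That transduced "unique tag" identifies the source
element, which makes a targeted assay possible: digest genomic DNA with a
restriction enzyme, self-ligate the fragments into circles, and amplify with
an inverse primer pair facing outward from the unique tag (long-distance
inverse PCR, LDI-PCR). The un-transposed source locus yields a *native*
product; every somatic insertion that carries the tag yields an
insertion-specific product containing both target flanks, the transduced
donor sequence and the polyA tail. Long (Nanopore-type) reads of these
amplicons are chimeric: part of each read aligns to the source locus, part to
the insertion's target locus.

`ldipcr` implements the complete downstream computation:

1. **Locus model** (`source_locus()`, `digest()`, `circularize()`,
   `predict_amplicon()`): in-silico digestion, circularization and amplicon
   prediction.
2. **Caller** (`call_insertions()`): hallmark-read detection, breakpoint
   extraction at alignment switch points, single-linkage clustering,
   modal-coordinate calling, and a filter cascade.
3. **Consensus** (`polish_call()`): greedy identity clustering of a call's
   supporting reads, sub-sampling, and a partial-order-alignment (POA)
   consensus.
4. **Characterization** (`characterize_insertion()`): realignment of the
   consensus to the target and source windows and derivation of every
   retrotransposition hallmark: target-site duplication/deletion,
   twin-priming inversion point, junction microhomology, polyA tail,
   terminating polyadenylation signal, orphan status and insertion length.
5. **Summary statistics** (`summarize_insertions()`,
   `wilcoxon_rank_sum()`), including the packaged catalogue of 39 somatic
   insertions from two colorectal tumour samples.
6. **Simulator** (`make_genome()`, `simulate_ldi_experiment()`): seeded
   synthetic experiments with exact truth tables, so that every stage above is
   testable without external data.

## Caller model and thresholds

A *hallmark read* has, among alignment segments with mapping quality at least
`min_mapq = 20`: at least one segment overlapping the source-element interval,
at least one segment outside it, and all outside segments on a single contig
within `max_target_span = 100` kb. At every switch between a source segment
and a target segment (in read coordinates) a breakpoint is recorded at the
target segment's query-adjacent reference end; the target side is used
because target coordinates are what the final insertion table reports.
Breakpoints from one sample and reaction are clustered per contig by a sorted
single-linkage sweep with a maximum gap of `cluster_max_gap = 3` kb, and each
cluster is called at its modal coordinate (ties resolved to the smallest
coordinate — the tie rule is a package convention, chosen for determinism).

The filter cascade, all boundaries inclusive:

* support: at least `min_support = 5` distinct reads;
* cut distance: the call must lie at least `min_cut_distance = 35` bp from
  the closest cut site of its reaction's enzyme (random ligation products sit
  at cut sites);
* contig whitelist: mitochondrial and unplaced contigs are excluded;
* crosstalk: a call observed in several samples is attributed to the sample
  holding at least `crosstalk_majority = 95%` of its reads. When no sample
  reaches the majority the call is dropped from *all* samples; the inclusion
  rule only licenses calls with a clear majority, and dropping the ambiguous
  remainder is the conservative completion of that rule.
* reactions: the same insertion seen in several enzyme/primer reactions is
  reported once, from the reaction with the most reads (ties to the
  lexicographically first label).

A read contributes once to a call's support regardless of how many
breakpoints it produced (both junctions of one amplicon land in one cluster).

## Consensus polishing

Supporting reads are orientation-normalized and clustered greedily,
longest-first, joining the first cluster whose *founding read* they match at
`min_cluster_identity = 0.60`; identity is matches divided by global-alignment
columns (the convention of the clustering tool family this mirrors). Up to
`sample_size = 20` reads are drawn uniformly from the largest cluster;
smaller clusters are reported as secondary and not polished.

The POA graph is built by aligning each read globally to the growing DAG
(scores `match +2, mismatch -1, gap -2`; linear gaps). The scoring triple is a
package choice — the upstream method does not state one — and is exposed in
`consensus_params()`. Reads are inserted longest-first; insertion order
affects graph topology, so it is fixed for determinism. The consensus is the
heaviest start-to-end path (edge weights are read traversal counts, plus
virtual start/end weights; predecessor ties break to higher node support,
then lexicographically smaller base). A heaviest-path traversal is used
rather than any other consensus call on the graph; on the amplicon depths
this package targets the two coincide for all practical purposes.

## Characterization

The consensus is segmented by recursive best local alignments against two
windows: the target window (`target_halfwidth = 10` kb around the call; both
strands) and the source-locus window. Numerical choices that matter here:

* Segmentation scoring is `+2/-8`, gap open 5, extension 2. The severe
  mismatch cost means an alignment cannot drift diagonally through unrelated
  sequence; crossing a foreign insert forces a long gap, and every accepted
  alignment is decomposed into anchor-supported blocks (anchors are runs of
  at least 10 consecutive matches) split wherever more than 60 bases of
  query or reference are bridged between anchors. Bridged query stretches are
  re-queued for segmentation. The 60 bp split threshold deliberately exceeds
  the maximum inter-primer gap (51 bp), so the one *intended* bridge — the
  unsequenced gap between the inverse primers inside the donor — stays in one
  block.
* polyA/polyT tails are recognized in the unaligned remainder as homopolymer
  runs of at least 10 bases at 90% purity (unstated upstream; exposed in
  `characterize_params()`).
* The amplicon is circularly permuted (the ligation junction sits inside the
  read), so the segmentation is rotated to canonical order — 5' target flank,
  donor, polyA, 3' target flank — rather than re-aligned.
* Junction refinement: a local alignment may extend a few bases past a true
  junction whenever a mismatch is later repaid by chance matches. Each
  segment end facing a junction is therefore reset to its maximal
  perfect-match extension, using a query-to-reference offset chosen by
  probing the 25 bases just inside the end (candidates derived from both
  segment ends, each +/- 6, to tolerate indels elsewhere in the segment).
  Overlapping refined ends are genuine microhomology: bases attributable to
  both sides, which is exactly how `measure_microhomology()` reports them.

Derived quantities and their conventions:

* Target-site modification from the flank coordinates `t5` (5'-flank
  reference end) and `t3` (3'-flank reference start): duplication of size
  `t5 - t3 + 1` when `t5 >= t3`; blunt when `t5 == t3 - 1`; otherwise a
  deletion of `t3 - t5 - 1`. The published per-row coordinate pairs this
  package's tests mirror are occasionally off by one from their printed
  sizes; the convention here is self-consistent rather than fitted per row.
* Twin-priming is donor segments of both orientations; the insertion strand
  is the orientation of the polyA-adjacent donor segment, and the inversion
  point is the reference end of the inverted segment (the donor split
  coordinate). More than two orientation switches are flagged complex.
* The terminating polyadenylation signal is the one whose stop window
  `[end + 10, end + 30]` (both edges inclusive) contains the transduction's
  3' terminus; a terminus inside no window is assigned to the nearest window
  edge with the distance reported.
* Orphan transductions are those whose donor start lies at or beyond the
  unique-tag start (no L1 body sequence).
* Insertion length counts the donor *reference* span — which bridges the
  unsequenced inter-primer gap, keeping error-free recovery exact — plus the
  polyA run and any unaligned bases between the flanks, and it *includes* the
  polyA tail (the published table does not say; this is the package's
  documented choice). An insertion is complete when both flanks are present
  and at most 25 internal bases stay unexplained; otherwise the length is a
  lower bound.

## Summary statistics

`wilcoxon_rank_sum()` always uses the normal approximation with tie-corrected
variance and a 0.5 continuity correction — read counts are heavily tied and
span orders of magnitude, and this matches the upstream analysis — never the
exact small-sample distribution. Insertions with lower-bound lengths are
excluded from length statistics and from the target-site-modification and
twin-priming tallies over "complete" insertions. The packaged catalogue
(`load_insertion_catalogue()`) is a re-entry of published results for two
colorectal tumours; the mean insertion length is reported but not asserted
anywhere, since the printed mean is not obviously consistent with the printed
per-row values.

## What the simulator emulates — and what it does not

`make_genome()` builds a small multi-contig genome whose first contig carries
an L1 stub, a unique 3' tag with nine planted polyadenylation-signal hexamers
(signal 1 canonical, signals 2–9 at 80 bp spacing), two inverse primer pairs
with inter-primer gaps of 30 and 50 bp (under the assay's 51 bp cap), and
planted PstI/NsiI/SacI sites giving every enzyme a native fragment containing
the whole tag. Insertions are planted at fixed target slots, each flanked by
guaranteed sites of one enzyme at -450/+600 bp, so an amplifiable sub-8.2 kb
target fragment exists for every insertion whatever the seed — mirroring the
assay design requirement that at least one enzyme always yields an
amplifiable fragment. A mitochondrial and an unplaced contig are included
for contig-filter testing.

Default insertion specifications emulate the hallmark spectrum of somatic L1
3' transductions: mostly target-site duplications of 1–28 bp with deletions
up to 50 bp and occasional blunt joints, twin-priming in about 45% of
events, about 70% orphan transductions among the rest, polyA tails of 20–60
bp, termination 10–30 bp downstream of signals 2–9, and clonal fractions of
0.5–1 mapping monotonically to read support. Two generator conventions are
worth spelling out:

* *Junction cleanliness.* When an insert's first base happens to equal the
  next reference base, the true junction is not uniquely defined at the
  sequence level (any aligner may attribute the base to either side). The
  default generator redraws such specifications until every junction is free
  of one-base attribution ambiguity, so that "exact recovery" is a
  well-posed property. Real data of course contains such ambiguities; on
  real data the corresponding coordinates are correct up to the junction
  homology, as in any split-read caller.
* *Error channel.* Reads cover the whole amplicon (amplicon sequencing, not
  shotgun) on a uniformly chosen strand, with independent per-base errors
  split 1:1:1 between substitutions, single-base insertions and deletions.
  This is a deliberately simple, analytically checkable stand-in: it does not
  reproduce Nanopore's homopolymer-length errors, quality correlation along
  the read, or barcode sequences (sample crosstalk is injected at the
  read-label level instead). Consequently, passing tests demonstrate the
  pipeline's logic and its behaviour under i.i.d. noise, not performance on
  real flow-cell data.

Alignments are synthesized directly from the simulator's truth (primary plus
0x800-flagged supplementary records, exact query intervals from the per-read
error maps, MAPQ 60 by default), substituting for an external long-read
aligner so the test suite needs none.

## Problem sizes and determinism

The shipped tests and the acceptance script run synthetic experiments with 20
planted transductions across 4 contigs (40–60 kb each), 8 error-free reads
per insertion for exact-recovery checks and 30 reads at 10% error for the
noisy checks, with amplicons of roughly 1–2.5 kb. These sizes were chosen so
the full suite exercises every code path at desk scale; all stages are linear
or quadratic in amplicon length, and nothing in the implementation depends on
these particular sizes. Every source of randomness — genome content,
insertion specifications, the error channel, read sub-sampling — is
seeded, and identical inputs in any record order produce identical call sets.

## Known limitations

* Only transductions carrying the unique tag are visible by construction;
  insertions without 3' transduction (the majority of L1 copies) are
  invisible to the assay and to this package.
* The caller reports one representative coordinate per insertion; complex
  nested rearrangements (more than two donor orientation switches) are
  flagged complex rather than resolved.
* PCR efficiency, chemistry limits and methylation-sensitive digestion are
  out of scope; the 8.2 kb amplifiability cap is an annotation in the
  simulator, not a property of the amplicon predictor.
* The Wilcoxon test intentionally has no exact-distribution branch.
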