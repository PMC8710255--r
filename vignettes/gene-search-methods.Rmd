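---
title: "Multi-reference gene search and k-mer dot plots: methods and design"
author: "regsp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-reference gene search and k-mer dot plots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regsp)
```

## The problem

Newly assembled organellar contigs rarely come annotated. A quick,
reliable way to find their genes is homology: align the translated contig
against the protein CDSs of one or more phylogenetically close reference
genomes and read gene content off the high-scoring segment pairs (HSPs).
Raw translated-search output, however, is noisy — short spurious HSPs,
stacks of overlapping hits over conserved domains, and contigs with a
single incidental match. This package post-processes HSPs with two simple
filters and pairs the protein-level evidence with a nucleotide-level
dot plot, so gene content and overall sequence similarity can be judged
together against several references at once.

## The two-parameter gene search

For each (contig, reference) pair, HSPs whose query nucleotide intervals
overlap (by at least one base, transitively) form a *group* — the
connected components of the interval-overlap graph. Grouping uses contig
coordinates only: reading frame and subject gene identity are ignored,
because a stack of hits over the same stretch of contig is one region of
evidence regardless of which protein each hit matched.

* **N** caps each group at N − 1 hits. Over-full groups are ranked by
  descending bit score, ties broken by ascending E-value, then descending
  alignment length, then input order, and the tail is discarded. The two
  score criteria agree in the common case (E-values are monotone in
  score); the bit score leads because it is the quantity BLAST itself
  ranks by. N = 1 is legal and empties every group — the CLI warns,
  since it voids all output.
* **M** validates each (contig, reference) pair: the surviving hits are
  counted individually (the *sub-gene count*), and the pair is valid iff
  the count is ≥ M. Validity is deliberately per reference, not per
  contig: a contig may be confidently annotatable from one reference and
  not from another.

Groups are formed on **all** hits and capped afterwards, so a group's
query span includes discarded members; this is the natural reading of
"a group can have at most N − 1 hits" and keeps group identity
independent of N. The `.sorted` report records every pair before the M
filter; `.regsp` keeps only valid pairs. Within each block genes are
listed by descending bit score.

The grouping sweep is a single sorted pass (new group when an interval
starts past the running maximum end), checked in the test suite against
an exhaustive pairwise-merge implementation on hundreds of random
instances.

## The dot-plot engine

Nucleotide similarity between each contig and each reference is computed
by exact k-mer matching on both strands:

1. **find** — every position pair where the k-length contig window equals
   the reference window (forward) or its reverse complement (reverse).
   The reference is indexed once; windows containing ambiguity codes
   never match, which avoids quadratic blow-up on N-runs in draft
   contigs. No mismatches are tolerated within a window: coarser
   similarity emerges from segment density, not inexact seeding.
2. **merge** — maximal runs on one diagonal (forward: `r − q` constant;
   reverse: `r + q` constant) become one segment of `run − 1 + k` bases.
   For reverse matches the bookkeeping uses the plus-strand coordinate of
   the reference window whose reverse complement equals the query window.
3. **resolve** — candidate segments whose query intervals overlap form
   clusters; each cluster keeps its longest member (ties: smallest
   reference start, then forward before reverse). Since exact segments of
   equal length are all 100% identical, length is the only meaningful
   similarity criterion and position the tie-break. The kept set is
   independent of scan order, so clusters are computed by the same sweep
   as hit grouping; an exhaustive oracle confirms equality on random
   candidate sets. Resolution is per reference — each panel selects its
   own segments.
4. **order** — contigs are arranged along the query axis by the first
   reference in which they match, then by the start of their longest
   segment there, then input order; contigs with no match anywhere go
   last. This approximates the reference's own coordinate system for
   fragmented assemblies.

k is constrained to 10–30 with default 13. Small k (10) lights up short,
scattered similarity even for distant references but costs time and
visual clutter; large k (30) keeps only long, highly similar segments, so
panels of distant relatives fade out. The k-monotonicity (coverage
non-increasing in k) is asserted in the tests. Low-complexity self-matches
are not masked; repeated regions therefore show as off-diagonal clutter —
a visual caveat, not an error.

Rendering draws merged segments as line glyphs (single-k-mer segments
become k-length ticks), forward in purple and reverse in cyan as in
MUMmer plots, one panel per reference on a near-square grid. PDF bytes
are not a test target (font and timestamp noise); instead
`layout_primitives()` exposes the exact drawn-segment inventory, which is
a pure function of layout and style and is what the tests assert on.

## The built-in translated search

`minisearch()` provides HSPs with no external dependency: six-frame
translation under the standard genetic code, exact peptide word seeds
(default word size 5), and ungapped extension under an embedded BLOSUM62
table with x-drop termination (default 20) and a raw-score floor
(default 50). Extension is bounded by the subject, so full-protein hits
have exact coordinates; the coordinate mapping back to the contig
(`q = 3·(a − 1) + frame offset`, mirrored for minus frames) is covered by
round-trip tests that re-translate the reported slice. Its raw scores are
**not** NCBI bit scores and its E-value column is only a monotone rank
transform (`10^(−score/10)`); reports label the provenance. Real runs can
use genuine `blastx` (tabular output with explicit columns) or any
precomputed BLAST tabular file; gapped HSPs only come from those sources.

## The synthetic-data generator

`make_genome_and_contigs()` emulates the package's target regime: a small
genome carrying, by default, 8 non-overlapping ORFs of 300–900 bp
(ATG start, single terminal stop, no internal stops) separated by
100–300 bp spacers — gene lengths and density in the range typical of
plastid protein-coding genes — cut into 3 contigs after per-base
substitution mutation, each contig reverse-complemented with probability
0.25 (assemblers emit either strand). The truth table lists genes fully
contained in a contig. All randomness flows through the single seed in
`synth_config()`.

What it does **not** emulate: inverted repeats, introns, RNA genes,
indels, sequencing error profiles, or genuine phylogenetic divergence
(substitutions are uniform and independent). Passing recovery tests
therefore show the search-and-filter machinery is correct under clean
point mutation, not that sensitivity matches real cross-species searches.
The regression bound — ≥ 90% of truth genes recovered at 5% substitution
with word size 4, averaged over 20 seeded replicates — is a property of
this generator, not a field benchmark.

## Numerical and design choices

* BLAST's 1-based inclusive coordinates are preserved in the HSP table;
  overlap arithmetic treats them as closed intervals (dot-plot
  coordinates are 0-based half-open). Tabular lines with `qstart > qend`
  (minus-strand convention) are normalised on read; orientation lives in
  the frame sign.
* The `***` separator between reference CDS sets is any line of three or
  more asterisks and nothing else; set count must equal the reference
  count, and CDS ids must be unique across the run because they key the
  HSP-to-reference assignment.
* Duplicate record ids within a FASTA are rejected — ids key all joins.
* The report layout (block header, then per gene: id, matched query
  nucleotide slice, position/score line, aligned peptides) is fixed by
  this package and frozen by tests; the matched nucleotide slice is
  always the plus-strand interval, with orientation in the frame field.
* Degenerate inputs: sequences shorter than k, empty match sets and empty
  report collections produce empty-but-well-formed results with warnings,
  never errors; k outside 10–30 and non-natural N/M are usage errors.
* Recommended scales (≤ 30 query entries, < 10 references) are warnings,
  not limits.

## Problem sizes in the test suite

The suite validates the grouping against a brute-force oracle on 500
random instances of ≤ 20 HSPs, the k-mer chain against a naive
per-diagonal comparison on 50 random pairs of 0.3–1 kb, and recovery on
20 simulator replicates of the default configuration — sizes chosen so
the whole suite completes in a couple of minutes while covering every
code path at the scales where exhaustive oracles are feasible.

## Known limitations

* Exact k-mer matching only; highly diverged references need small k and
  may still show little in the plot even when protein-level hits exist.
* The built-in search is ungapped and unscaled; use real BLASTx for
  sensitive or statistically calibrated searches.
* Gene models are not reconstructed from surviving HSPs (no exon
  chaining); the output is gene evidence per contig, not annotations.
* Protein-domain (PROmer-style) plots are out of scope; only the
  nucleotide dot plot is produced.
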