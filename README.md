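# regsp

Homology-based gene search in assembled contigs against **multiple
reference genomes**, with k-mer dot-plot visualisation of nucleotide
similarity. The package targets organellar (plastid and mitochondrial)
genome assembly and annotation: given newly assembled contigs or scaffolds
and one or more phylogenetically close references with known coding
sequences, it reports which reference genes each contig carries and how
the contigs align to each reference.

## The method

The gene search consumes BLASTx-style high-scoring segment pairs (HSPs) —
local alignments of the translated contig against the reference protein
CDSs — and applies two user parameters:

* **N**, the maximum number of matched BLAST hits per group. A *group* is
  a maximal set of HSPs on one contig whose query intervals are connected
  by pairwise overlap (a non-overlapping section of the contig with
  matches). Each group may keep at most **N − 1** hits: if it holds more,
  hits are ranked by bit score (ties broken by E-value, then alignment
  length, then input order) and only the top N − 1 survive.
* **M**, the minimum sub-gene count per contig. The hits surviving the
  group cap are counted individually per (contig, reference) pair; the
  pair is *valid* only when the count is at least M.

Results are written as plain-text reports: `.sorted` holds every reported
pair (the state before the M filter), `.regsp` only the valid pairs.
Because validity is assessed per reference, a contig can be valid against
one reference and invalid against another.

In parallel, the dot-plot engine (cPlot) finds exact shared k-mers
(k between 10 and 30, default 13) between each contig and each reference
on both strands, merges consecutive matches on a common diagonal into
segments, keeps the longest segment among overlapping candidates, orders
contigs along the reference, and renders one panel per reference into a
PDF — forward matches purple, reverse matches cyan, following the
MUMmer-plot convention. Raising k makes the plot "fade out" to only highly
similar regions; lowering it reveals short, scattered similarity.

HSPs can come from a precomputed BLAST tabular file, from an external
`blastx` on the PATH, or from the package's built-in translated search
(six-frame translation, exact peptide seeding, ungapped BLOSUM62 x-drop
extension) — the latter keeps the whole pipeline dependency-free.

## Worked example

The package ships a frozen worked example: two contigs against three
references, with one group of four mutually overlapping hits. At
`N = 4, M = 4`:

```r
library(regsp)
fx <- fig2_fixture()
params <- search_params(N = 4, M = 4)
reports <- run_gene_search(fx$hsps, params, fx$contig_ids, fx$ref_ids)
report_summary(reports)
#>   contig_id ref_id subgene_count valid
#> 1  Contig_1  Ref_1             5  TRUE
#> 2  Contig_2  Ref_1             7  TRUE
#> 3  Contig_2  Ref_2             3 FALSE
#> 4  Contig_1  Ref_3             4  TRUE
#> 5  Contig_2  Ref_3             1 FALSE
```

Contig 1 vs Reference 1 keeps all five hits (two of them overlap, but a
group of two is within the N − 1 = 3 allowance). Contig 2 vs Reference 1
has eight hits of which four overlap mutually; the lowest-scoring member
of that group is discarded, leaving seven — still valid. Contig 2 carries
only three hits against Reference 2 and one against Reference 3, both
below M = 4, so those pairs are dropped from the `.regsp` report (they
remain visible in `.sorted`). Contig 1 vs Reference 2 had no hits at all
and is not reported.

The same run from the command line, via the bundled `exec/regsp` wrapper:

```sh
regsp fig2-demo --out demo_out
regsp run --query contigs.fa --ref-nt refs.fa --ref-aa refs.faa \
          --N 4 --M 4 --k 13 --use-minisearch --out results_dir
```

In the protein CDS file, consecutive references are separated by a line of
three or more asterisks (`***`).

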