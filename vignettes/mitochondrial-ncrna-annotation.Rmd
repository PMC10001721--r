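---
title: "Identifying and annotating mitochondria-derived small and long non-coding RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and annotating mitochondria-derived small and long non-coding RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Vertebrate mitochondrial genomes are compact (15--20 kb, typically 37 genes)
and their transcripts are abundant -- 5 to 30% of total cellular RNA
depending on cell type. Short-read sequencing libraries therefore contain a
large population of mitochondria-derived reads, among them small RNAs
(mt-sRNAs), including tRNA-derived fragments (tRFs) and tRNA halves (tRHs),
and longer non-coding transcripts (mt-lncRNAs). These molecules have
features that generic sRNA tools handle poorly: non-templated 3' CCA
additions on tRNA-derived fragments, dense length and sequence variants, two
coding strands with overlapping reading frames, and no curated database for
most of them. `mitosrna` identifies, quantifies and annotates these RNAs
directly from adapter-trimmed FASTQ files against a user-supplied
mitochondrial genome FASTA and gene-level GTF.

## The procedure

1. **Read collapsing** (`build_count_matrix`). All reads across all
   libraries are collapsed by exact full-string identity into a
   unique-sequence count matrix (rows: sequences; columns: libraries).
   Small-RNA mode keeps reads of at most 50 nt, long-ncRNA mode reads of at
   least 50 nt; a 50-nt read is eligible for both. Sequences whose total
   count across libraries falls below a cutoff (default 200) are removed,
   because counting accuracy for very shallow sequences is erratic. Files
   are processed independently (one worker per file when parallelism is
   requested) and merged; the output is identical for any worker count.
2. **Alignment** (`align_sequence`, `align_matrix`). Each unique sequence is
   placed on the genome with best-hit, ungapped, at-most-one-mismatch
   semantics, on both strands. The heavy (H) strand is the forward strand of
   the FASTA; a match to its reverse complement is a light (L) strand read.
   The genome is small enough that exhaustive matching is exact and fast; no
   external aligner is needed.
3. **CCA rescue** (`cca_rescue`). Mature tRNAs carry an enzymatically added
   3' CCA absent from the genome. Unmapped sequences ending in the literal
   motif are re-aligned after trimming it, at zero mismatches, and accepted
   only when the trimmed 3' end falls within the boundary tolerance of a
   tRNA gene's 3' end (sense) or 5' end (antisense).
4. **Annotation** (`classify_location`, `classify_trf_subtype`,
   `annotate_alignments`). Each mapped sequence receives a gene, a location
   class, an orientation, a tRF subtype where the gene is a tRNA, a
   substitution string, and two nomenclature identifiers.
5. **Long-ncRNA grouping** (`group_by_five_prime`, `apply_length_filter`).
   lncRNA libraries contain families of 3'-end length variants; counts of
   sequences sharing strand, orientation and 5' start are summed into one
   group in addition to the per-unique-sequence table.

## Annotation rules

**Location classes.** Class A: the read's start site (its 5' end in read
orientation) falls within a gene; class D: the start site is in one gene and
the 3' end in a different gene -- the start-site gene is assigned; class B:
the read starts in non-coding DNA and overlaps a gene; class C: entirely
non-coding (gene "nc"). The four cases partition all placements. Two
details had to be decided here because the four pictured cases do not cover
them: a read that starts inside a gene and runs into non-coding DNA without
reaching a second gene is treated as class A (gene-anchored by its start),
and when a start site lies inside two overlapping genes the gene on the
read's own strand is preferred, then annotation order. The one exception to
start-site assignment is tRF-1: a read starting 1--3 nt after a tRNA gene's
3' end on the same strand is that tRNA's 3' trailer fragment and is assigned
to the tRNA even when its start lies in the next gene or in non-coding DNA;
such reads are reported with class A, the trailer being treated as an
extension of the tRNA.

**tRF subtypes.** Within a tRNA gene, a read is 5'-anchored when either of
its ends lies within the boundary tolerance (default ±3 nt) of the gene's 5'
boundary, and 3'-anchored when either end lies within tolerance of the 3'
boundary or the read carried a non-templated CCA. Anchoring by *either* end
is deliberate: fragments are observed both ending at a boundary and starting
at one and running across it, and both signal processing at that boundary.
Anchored fragments of at least `trh_min_length` nt (default 30) are halves
(tRH-5/tRH-3); shorter ones are tRF-5/tRF-3; 5'-anchoring wins when both
apply. Unanchored reads are internal fragments: i-tRF-5 when the read
midpoint lies in the gene's 5' half (ties to the 5' side), i-tRF-3
otherwise. The 30-nt half threshold is not standardized anywhere; tRNA
halves are typically 30--34 nt, and 30 reproduces typical tRH calls at
31--34 nt. Both the threshold and the tolerance are `annotation_config()`
parameters.

**Coordinates.** All coordinates are 1-based inclusive (GTF convention). The
reported start position is the genomic coordinate of the read's 5' base in
its own orientation: the leftmost base for H-strand reads, the rightmost for
L-strand reads. This makes a sense fragment and its antisense counterpart at
the same boundary report adjacent start positions, which is the only
convention under which such pairs are coherent. The genome is treated as
linear; reads spanning the origin of the circular molecule go unmapped
(documented limitation).

**Nomenclature.** The specific ID uniquely identifies an isoform:
`species|mt-sRNA|gene|subtype|strand|[as]start|length` for small RNAs
(subtype present only for tRNA-derived sequences) and
`species|mt-lncRNA|gene|strand|[as]start|length` for long ncRNAs; antisense
orientation is encoded by the `as` prefix on the start position, and species
codes are lowercased KEGG-style organism abbreviations. The general ID drops
the length, collapsing length/modification variants into one family.
Substitutions are reported in their own column as
`<position from read 5' end><read base>` (e.g. `24C`), `NIL` when none; the
parser also accepts a legacy trailing digit (`24C0`). tRNA gene names are
normalized to their amino-acid code (`mt-Te` or `tRNA-Glu` become `Glu`) so
identifiers are annotation-source independent; rRNA and protein-coding names
pass through from the GTF verbatim.

## The simulator and what passing means

`simulate_reads` generates ground-truth FASTQ files: each unique sequence is
drawn from a random gene or non-coding interval on either strand (light
strand sequences are emitted as reverse complements), with lengths 15--50 nt
(sRNA mode) or 50--300 nt (lncRNA mode) and per-file counts drawn uniformly
from 200--10,000. Strands are allocated so that a target fraction of reads
-- default 0.875, constrained to the 80--95% range typical of heavy-strand
transcription -- originates from the heavy strand: heavy-strand counts are
rescaled per file to hit the target in expectation and the realized fraction
is checked against the bounds. A configurable subset of sequences (default
2%, at least one in lncRNA mode) is generated antisense to heavy-strand
genes with one planted internal substitution; these read as light-strand
transcripts. `check_concordance` then compares the truth table to the
pipeline output element-wise under four criteria: sequence sets, mapping and
strand distribution, total and per-file counts, and annotation together with
the biotype read distribution.

Several draws are rejected and redrawn so that the truth is *exactly*
recoverable: sequences with more than one equally good genome placement
(tie-breaking could legitimately differ), starts inside overlapping-gene
regions or tRF-1 trailer windows (assignment would be rule-dependent rather
than source-dependent), non-coding draws are confined to their interval, and
planted substitutions never create a trailing CCA. The simulator therefore
emulates read populations with known origin, not sequencing physics: there
are no quality-driven errors, no adapter remnants, no coverage biases, and
no reads from outside the mitochondrial genome. A passing round trip shows
the counting, mapping, CCA handling, annotation and grouping machinery is
self-consistent and sensitive (a single perturbed cell fails); it does not
show robustness to artifacts that upstream trimming and quality control are
expected to remove.

## Numerical and design choices

* Cutoff comparison is `total >= 200` (strictly lower totals are discarded).
* Tie-break among equally good placements: fewest mismatches, heavy strand
  before light, smallest start; `multimap` flags that alternatives existed.
* Reads containing N never map; sequences shorter than 15 nt are not
  aligned (upstream trimming removes them by contract).
* Only the full literal CCA motif is rescued; partial C/CA additions are
  not considered.
* The lncRNA length filter (`--filter`, e.g. 200 to exclude 50--200 nt
  intermediate RNAs) applies *after* grouping, on the representative
  (longest-member) length, so short 3' variants still contribute counts to
  a retained family. Filtering first would silently discard them.
* RPM normalization uses per-library total read counts before any
  filtering.
* Row order everywhere is descending total count with lexicographic
  tie-break, so outputs are byte-reproducible.

## Problem sizes used in the shipped checks

The test suite validates the round trip at 200 unique small-RNA sequences
across 4 files and 50 long-ncRNA sequences across 2 files on the packaged
2-kb toy reference (six genes, all biotypes, both strands, one overlapping
pair), and the aligner against an independent exhaustive-scan oracle on
1,000 planted queries with 0--2 mismatches. These sizes exercise every code
path while keeping the default check quick; all generators are seeded, and
the same machinery scales to real libraries by changing only the inputs.

## Limitations

* Linear-genome assumption: origin-spanning reads are lost.
* No NUMT awareness: reads are placed on the mitochondrial genome only, so
  nuclear copies of mitochondrial DNA cannot be distinguished; mapping
  against the nuclear genome is out of scope.
* Annotation quality is bounded by the GTF: anticodon positions are not
  annotated there, so tRH boundaries are length-based, not anticodon-aware.
* Differential expression is downstream: the annotated CSV is designed as
  direct input for count-based DE tools, but no statistics are computed
  here.
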