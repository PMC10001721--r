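# mitosrna

Identification, quantification and annotation of RNAs derived from the
mitochondrial genome in short-read sequencing data: small RNAs (mt-sRNAs,
≤ 50 nt), including tRNA-derived fragments with non-templated 3′ CCA
additions, and mitochondria-derived long non-coding RNAs (mt-lncRNAs,
≥ 50 nt).

Mitochondrial transcripts make up 5–30% of cellular RNA, yet generic small-RNA
tools mishandle their hallmarks: CCA-tailed tRNA fragments that fail direct
alignment, dense length/sequence variants, two coding strands, and overlapping
reading frames. `mitosrna` works directly from adapter-trimmed FASTQ files
plus a mitochondrial genome FASTA and gene GTF, and is aimed at
transcriptomics researchers re-mining bulk or single-cell sRNA-seq and
RNA-seq datasets for mitochondrial signal.

## Method

- **Read collapsing.** Reads from all libraries are collapsed by exact
  sequence identity into a unique-sequence count matrix (one column per
  library); sequences with total count < 200 (configurable) are discarded.
  Counting parallelizes per file and is deterministic for any worker count.
- **Alignment.** Each sequence is placed on the genome with best-hit,
  ungapped, ≤ 1-mismatch semantics on both strands (heavy H = FASTA forward,
  light L = reverse complement); the ~16-kb genome makes exhaustive matching
  exact. Unmapped sequences ending in the non-templated `CCA` of mature
  tRNAs are trimmed and re-mapped at zero mismatches, accepted only at tRNA
  gene ends (±3 nt).
- **Annotation.** Every mapped sequence gets a gene (assigned by its 5′
  start site; reads spanning two genes go to the start-site gene, with the
  tRF-1 trailer exception), a location class (A–D), an orientation, a tRF
  subtype (tRF-5/tRF-3/tRF-1/i-tRF-5/i-tRF-3/tRH-5/tRH-3; halves at
  ≥ 30 nt), a substitution string (`24C`-style), and two identifiers:

  ```
  specific: species|mt-sRNA|gene|subtype|strand|[as]start|length
  general:  species|mt-sRNA|gene|subtype|strand|[as]start
  lncRNA:   species|mt-lncRNA|gene|strand|[as]start|length
  ```

- **lncRNA grouping.** 3′-end length variants sharing a 5′ start are summed
  into families; `--filter 200` restricts output to strict lncRNAs.
- **Ground-truth simulator.** `simulate_reads()` writes FASTQ files with
  known per-sequence origin (80–95% heavy-strand reads, antisense sequences
  with planted substitutions, uniform 200–10,000 per-file counts) plus a
  truth CSV in the tool's output schema; `check_concordance()` compares
  truth and pipeline output element-wise.

## Worked example

Simulate a small dataset on the packaged toy reference and run the pipeline
on it:

```r
library(mitosrna)

ref    <- make_toy_reference()
genome <- load_genome(ref$fasta)
genes  <- load_annotation(ref$gtf, genome)

cfg <- sim_config(genes, n_sequences = 30, n_files = 2, mode = "sRNA", seed = 7)
sim <- simulate_reads(cfg)

res <- run_pipeline(sim$fastq, ref$fasta, ref$gtf,
                    mode = "sRNA", species = "dre", out_dir = tempdir())
#> reference: genome 'MT' 2000 nt, 6 genes
#> counting: 2 files, 329530 total reads, 30 unique sequences with total count >= 200
#> mapping: 30/30 sequences mapped (100.0% of reads); heavy strand 87.5% of mapped reads, light 12.5%
#> annotation: 30 sequences annotated (7 tRNA, 2 rRNA, 4 protein-coding, 17 non-coding)

check_concordance(sim$truth, res$annotated)
#> Concordance: PASS
#>                   criterion n_compared n_mismatch pass
#> 1          unique_sequences         30          0 TRUE
#> 2         mapped_and_strand         31          0 TRUE
#> 3 total_and_per_file_counts         61          0 TRUE
#> 4   annotation_and_biotypes        181          0 TRUE
```

The log lines report the library sizes, how many unique sequences cleared
the count cutoff, the mapping rate, and the heavy/light strand split of
mapped reads (here 87.5% heavy, matching the simulation target). The
concordance report shows that every simulated sequence was recovered with
its exact counts, strand, coordinates and annotation. `res$annotated` holds
the DE-ready table (sequence, specific/general ID, gene, biotype, class,
subtype, strand, orientation, start, length, substitutions, per-library
counts), written as CSV in `out_dir`.

Command-line wrappers over the same functions are in `inst/scripts/`
(`mitosrna.R` for the pipeline, `mitosim.R` for the simulator).

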