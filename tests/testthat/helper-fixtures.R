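# Shared fixtures, built in code at test time.

# Toy reference (2-kb genome, 6 genes), generated once per test run.
toy_env <- new.env(parent = emptyenv())
toy_ref <- function() {
  if (is.null(toy_env$ref)) {
    ref <- make_toy_reference(file.path(tempdir(), "toyref-tests"))
    genome <- load_genome(ref$fasta)
    genes <- load_annotation(ref$gtf, genome)
    toy_env$ref <- c(ref, list(genome = genome, genes = genes))
  }
  toy_env$ref
}

# Write a plain 4-line-record FASTQ by hand (independent of the package's
# FASTQ reader), repeating each sequence `counts` times.
write_plain_fastq <- function(seqs, counts, path, qual = NULL) {
  lines <- character(0)
  k <- 0L
  for (i in seq_along(seqs)) {
    for (j in seq_len(counts[i])) {
      k <- k + 1L
      q <- if (is.null(qual)) strrep("F", nchar(seqs[i])) else qual
      lines <- c(lines, paste0("@r", k), seqs[i], "+", q)
    }
  }
  writeLines(lines, path)
  path
}

# Hand-built gene set over a dummy genome, for annotation unit tests.
make_gene_set <- function(df, genome_len = 2000L, genome_seq = NULL) {
  if (is.null(genome_seq)) genome_seq <- strrep("A", genome_len)
  genome <- structure(list(name = "fake", sequence = genome_seq,
                           length = nchar(genome_seq)),
                      class = "mito_genome")
  structure(list(genes = df, genome = genome), class = "mito_genes")
}

# Minimal mapped-alignment record.
make_al <- function(start, len, strand, cca = FALSE, nmm = 0L,
                    mm_pos = NA_integer_, mm_base = NA_character_) {
  list(sequence = strrep("A", len), mapped = TRUE,
       genome_start = as.integer(start), strand = strand,
       length = as.integer(len), n_mismatch = as.integer(nmm),
       mm_pos = mm_pos, mm_base = mm_base, cca_added = cca,
       multimap = FALSE)
}

# A 200-nt hand genome with a 70-nt tRNA at [41, 110] whose downstream
# flank [111, 113] is forced to TTT, so that a read carrying a genuinely
# non-templated CCA cannot map directly.
cca_fixture <- function(trna_strand = "H") {
  seq <- with_seed_helper(424L, paste(sample(c("A", "C", "G", "T"), 200L,
                                             replace = TRUE), collapse = ""))
  substr(seq, 111L, 113L) <- "TTT"
  genome <- structure(list(name = "cca", sequence = seq, length = 200L),
                      class = "mito_genome")
  genes <- data.frame(
    gene_name = c("Glu", "ND1"),
    biotype = c("tRNA", "protein_coding"),
    strand = c(trna_strand, "H"),
    start = c(41L, 130L), end = c(110L, 190L),
    stringsAsFactors = FALSE)
  structure(list(genes = genes, genome = genome), class = "mito_genes")
}

with_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
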