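# Count character mismatches between two equal-length strings.
count_mismatches <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(av != bv)
}

unmapped_alignment <- function(seq) {
  list(sequence = seq, mapped = FALSE, genome_start = NA_integer_,
       strand = NA_character_, length = nchar(seq),
       n_mismatch = NA_integer_, mm_pos = NA_integer_,
       mm_base = NA_character_, cca_added = FALSE, multimap = FALSE)
}

# All placements of `seq` on both strands with at most max_mismatches
# mismatches. Returns data.frame(start, strand, nmm).
candidate_placements <- function(seq, genome, max_mismatches) {
  subject <- Biostrings::DNAString(genome$sequence)
  res <- list()
  for (strand in c("H", "L")) {
    query <- if (strand == "H") seq else reverse_complement(seq)
    hits <- Biostrings::matchPattern(Biostrings::DNAString(query), subject,
                                     max.mismatch = max_mismatches)
    st <- Biostrings::start(hits)
    if (length(st)) {
      nmm <- vapply(st, function(s) {
        count_mismatches(query, genome_substr(genome, s, s + nchar(query) - 1L))
      }, integer(1L))
      res[[strand]] <- data.frame(start = st, strand = strand, nmm = nmm,
                                  stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(0), strand = character(0),
                      nmm = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Place one sequence on the mitochondrial genome
#'
#' Best-hit, ungapped placement with at most `max_mismatches` mismatches
#' (default 1), considering both strands: a forward-strand match is reported
#' as heavy (H), a match to the reverse complement as light (L). Among equally
#' good placements the tie-break is deterministic: fewest mismatches, then H
#' before L, then smallest start coordinate; `multimap` flags that more than
#' one equally good placement existed. Sequences containing N never match.
#'
#' @param seq DNA sequence (character scalar), at least 15 nt by caller
#'   contract.
#' @param genome A `mito_genome`.
#' @param max_mismatches Maximum mismatches allowed (default 1).
#' @return A list: `sequence`, `mapped`, `genome_start` (1-based coordinate
#'   of the leftmost aligned base on the forward strand), `strand`, `length`
#'   (aligned length), `n_mismatch`, `mm_pos` (1-based from the read 5' end),
#'   `mm_base` (read base at the mismatch), `cca_added`, `multimap`.
#' @export
align_sequence <- function(seq, genome, max_mismatches = 1L) {
  stopifnot(inherits(genome, "mito_genome"))
  if (nchar(seq) > genome$length) {
    stop("sequence longer than the genome (", nchar(seq), " nt)")
  }
  if (grepl("N", seq, fixed = TRUE)) return(unmapped_alignment(seq))
  cand <- candidate_placements(seq, genome, max_mismatches)
  cand <- cand[cand$nmm <= max_mismatches, , drop = FALSE]
  if (nrow(cand) == 0L) return(unmapped_alignment(seq))
  best_nmm <- min(cand$nmm)
  best <- cand[cand$nmm == best_nmm, , drop = FALSE]
  best <- best[order(match(best$strand, c("H", "L")), best$start), ,
               drop = FALSE]
  top <- best[1L, ]
  al <- list(sequence = seq, mapped = TRUE,
             genome_start = as.integer(top$start),
             strand = top$strand, length = nchar(seq),
             n_mismatch = as.integer(top$nmm), mm_pos = NA_integer_,
             mm_base = NA_character_, cca_added = FALSE,
             multimap = nrow(best) > 1L)
  if (top$nmm > 0L) {
    seg <- genome_substr(genome, top$start, top$start + nchar(seq) - 1L)
    oriented <- if (top$strand == "H") seg else reverse_complement(seg)
    rv <- strsplit(seq, "", fixed = TRUE)[[1L]]
    sv <- strsplit(oriented, "", fixed = TRUE)[[1L]]
    pos <- which(rv != sv)[1L]
    al$mm_pos <- as.integer(pos)
    al$mm_base <- rv[pos]
  }
  al
}

# Genomic coordinate of the read's 3' end in read orientation.
read_three_prime <- function(al) {
  if (al$strand == "H") al$genome_start + al$length - 1L else al$genome_start
}

# Genomic coordinate of the read's 5' end in read orientation (also the
# reported start position in identifiers).
read_five_prime <- function(al) {
  if (al$strand == "H") al$genome_start else al$genome_start + al$length - 1L
}

#' Rescue an unmapped sequence carrying a non-templated 3' CCA
#'
#' Mature tRNAs carry an enzymatically added CCA at their 3' end that is
#' absent from the genome, so tRNA 3'-end-derived fragments fail direct
#' alignment. Sequences left unmapped by [align_sequence()] that end in the
#' literal motif "CCA" are re-aligned after trimming the motif, under a
#' zero-mismatch criterion. The rescue is accepted only when the trimmed
#' alignment's 3' end (in read orientation) lies within `tolerance` nt of a
#' tRNA gene's 3' end when sense, or of its 5' end when antisense; otherwise
#' the sequence stays unmapped.
#'
#' @param seq Original (untrimmed) sequence ending in "CCA".
#' @param genome A `mito_genome`.
#' @param genes A `mito_genes`.
#' @param tolerance Boundary tolerance in nt (default 3, the annotation
#'   tolerance).
#' @return An alignment list as in [align_sequence()], with `cca_added = TRUE`
#'   and `length` equal to the trimmed length on success; an unmapped record
#'   otherwise.
#' @export
cca_rescue <- function(seq, genome, genes, tolerance = 3L) {
  stopifnot(inherits(genes, "mito_genes"))
  if (!endsWith(seq, "CCA")) {
    stop("cca_rescue called on a sequence not ending in CCA")
  }
  trimmed <- substr(seq, 1L, nchar(seq) - 3L)
  if (nchar(trimmed) < 1L) return(unmapped_alignment(seq))
  al <- align_sequence(trimmed, genome, max_mismatches = 0L)
  if (!al$mapped) return(unmapped_alignment(seq))
  trna <- genes$genes[genes$genes$biotype == "tRNA", , drop = FALSE]
  p3 <- read_three_prime(al)
  ok <- FALSE
  for (i in seq_len(nrow(trna))) {
    g <- trna[i, ]
    gene3 <- if (g$strand == "H") g$end else g$start
    gene5 <- if (g$strand == "H") g$start else g$end
    target <- if (al$strand == g$strand) gene3 else gene5
    if (abs(p3 - target) <= tolerance) { ok <- TRUE; break }
  }
  if (!ok) return(unmapped_alignment(seq))
  al$sequence <- seq
  al$cca_added <- TRUE
  al
}

#' Align every sequence of a count matrix
#'
#' Runs [align_sequence()] on each unique sequence, applies the CCA rescue to
#' unmapped sequences ending in "CCA", and computes mapping statistics.
#' Sequences shorter than 15 nt are reported unmapped without alignment
#' (upstream trimming is expected to have removed them).
#'
#' @param matrix An `mt_counts`.
#' @param genome A `mito_genome`.
#' @param genes A `mito_genes` (needed for the CCA rescue).
#' @param tolerance Boundary tolerance for the CCA rescue (default 3 nt).
#' @return A list with `alignments` (data.frame, one row per matrix sequence,
#'   columns as in [align_sequence()]) and `stats` (data.frame with sequence-
#'   and read-level mapping statistics, including the heavy/light split of
#'   mapped reads).
#' @export
align_matrix <- function(matrix, genome, genes, tolerance = 3L) {
  stopifnot(inherits(matrix, "mt_counts"))
  seqs <- rownames(matrix$counts)
  rows <- lapply(seqs, function(s) {
    if (nchar(s) < 15L) return(unmapped_alignment(s))
    al <- align_sequence(s, genome)
    if (!al$mapped && endsWith(s, "CCA")) {
      al <- cca_rescue(s, genome, genes, tolerance = tolerance)
    }
    al
  })
  aln <- do.call(rbind, lapply(rows, function(x) {
    as.data.frame(x, stringsAsFactors = FALSE)
  }))
  seq_reads <- rowSums(matrix$counts)
  total_reads <- sum(matrix$file_totals)
  if (any(is.na(total_reads))) total_reads <- sum(seq_reads)
  mapped <- aln$mapped
  mapped_reads <- sum(seq_reads[mapped])
  heavy <- mapped & aln$strand == "H"
  stats <- data.frame(
    n_sequences = length(seqs),
    n_mapped = sum(mapped),
    pct_sequences_mapped = 100 * sum(mapped) / max(1L, length(seqs)),
    pct_reads_mapped = 100 * mapped_reads / max(1, total_reads),
    pct_heavy_sequences = 100 * sum(heavy) / max(1L, sum(mapped)),
    pct_heavy_reads = 100 * sum(seq_reads[heavy]) / max(1, mapped_reads),
    stringsAsFactors = FALSE
  )
  stats$pct_light_sequences <- 100 - stats$pct_heavy_sequences
  stats$pct_light_reads <- 100 - stats$pct_heavy_reads
  list(alignments = aln, stats = stats)
}
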