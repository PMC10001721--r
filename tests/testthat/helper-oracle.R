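# Independent exhaustive-scan alignment oracle, in plain R (no Biostrings).
# Scores every offset on both strands and applies the same tie-break the
# package documents: fewest mismatches, H before L, smallest start.

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

oracle_scan <- function(seq, genome_seq, max_mm = 1L) {
  gv <- strsplit(genome_seq, "", fixed = TRUE)[[1L]]
  n <- length(gv)
  L <- nchar(seq)
  hits <- list()
  for (strand in c("H", "L")) {
    q <- if (strand == "H") seq else oracle_revcomp(seq)
    qv <- strsplit(q, "", fixed = TRUE)[[1L]]
    n_off <- n - L + 1L
    if (n_off < 1L) next
    mm <- integer(n_off)
    off <- seq_len(n_off)
    for (j in seq_len(L)) {
      mm <- mm + (gv[off + j - 1L] != qv[j])
    }
    keep <- which(mm <= max_mm)
    if (length(keep)) {
      hits[[strand]] <- data.frame(start = keep, strand = strand,
                                   nmm = mm[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(list(mapped = FALSE))
  }
  cand <- do.call(rbind, hits)
  best <- cand[cand$nmm == min(cand$nmm), , drop = FALSE]
  best <- best[order(match(best$strand, c("H", "L")), best$start), ,
               drop = FALSE]
  list(mapped = TRUE, genome_start = best$start[1L],
       strand = best$strand[1L], n_mismatch = best$nmm[1L],
       multimap = nrow(best) > 1L)
}

# Plant a query: extract a substring of the genome on a random strand and
# mutate k random positions.
plant_query <- function(genome_seq, k_mismatches, min_len = 15L,
                        max_len = 40L) {
  n <- nchar(genome_seq)
  len <- sample(min_len:max_len, 1L)
  start <- sample(seq_len(n - len + 1L), 1L)
  seq <- substr(genome_seq, start, start + len - 1L)
  if (sample(c(TRUE, FALSE), 1L)) seq <- oracle_revcomp(seq)
  if (k_mismatches > 0L) {
    pos <- sample(seq_len(len), k_mismatches)
    sv <- strsplit(seq, "", fixed = TRUE)[[1L]]
    for (p in pos) {
      sv[p] <- sample(setdiff(c("A", "C", "G", "T"), sv[p]), 1L)
    }
    seq <- paste(sv, collapse = "")
  }
  seq
}
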