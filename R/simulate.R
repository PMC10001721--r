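# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate the packaged toy mitochondrial reference
#'
#' Writes a small synthetic reference used for testing and examples: a 2-kb
#' random genome with six genes covering all three biotypes, both strands,
#' one overlapping protein-coding pair (ATP8/ATP6, as in real mitochondrial
#' genomes) and ample non-coding DNA. The tRNA gene names exercise both GTF
#' naming styles ("mt-Te", "tRNA-Arg").
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the random genome sequence (default 101; the layout
#'   is fixed).
#' @return List with `fasta` and `gtf` paths.
#' @export
make_toy_reference <- function(dir = tempfile("toyref"), seed = 101L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seq <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), 2000L,
                                      replace = TRUE), collapse = ""))
  fasta <- file.path(dir, "toy_mito.fa")
  writeLines(c(">MT synthetic toy mitochondrial genome", seq), fasta)
  gtf <- file.path(dir, "toy_mito.gtf")
  attr_fmt <- 'gene_id "%s"; gene_name "%s"; gene_biotype "%s";'
  rows <- list(
    c("12S",  "Mt_rRNA",        "+", 61L,   360L),
    c("mt-Te", "Mt_tRNA",       "+", 401L,  470L),
    c("ND1",  "protein_coding", "+", 521L,  1060L),
    c("ATP8", "protein_coding", "+", 1101L, 1300L),
    c("ATP6", "protein_coding", "+", 1261L, 1500L),
    c("tRNA-Arg", "Mt_tRNA",    "-", 1551L, 1620L)
  )
  lines <- vapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    paste("MT", "toy", "gene", r[4L], r[5L], ".", r[3L], ".",
          sprintf(attr_fmt, paste0("g", i), r[1L], r[2L]), sep = "\t")
  }, character(1L))
  writeLines(lines, gtf)
  list(fasta = fasta, gtf = gtf)
}

#' Simulation configuration
#'
#' @param genes A `mito_genes` (reference the reads are simulated from).
#' @param n_sequences Number of unique sequences to simulate (shared across
#'   files; per-file counts differ).
#' @param n_files Number of FASTQ files (libraries) to write.
#' @param mode `"sRNA"` (15-50 nt reads) or `"lncRNA"` (50-300 nt).
#' @param heavy_fraction Target fraction of reads originating from the heavy
#'   strand; must lie in \[0.80, 0.95\] (default 0.875, the midpoint).
#' @param antisense_sub_fraction Fraction of sequences generated antisense to
#'   heavy-strand genes with one planted substitution; such sequences read as
#'   light-strand transcripts. At least one is always generated in lncRNA
#'   mode (default 0.02).
#' @param count_range Inclusive range for per-file random counts (default
#'   c(200, 10000), so every sequence clears the default count cutoff).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genes, n_sequences, n_files,
                       mode = c("sRNA", "lncRNA"),
                       heavy_fraction = 0.875,
                       antisense_sub_fraction = 0.02,
                       count_range = c(200L, 10000L), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(genes, "mito_genes"), n_sequences >= 1L, n_files >= 1L,
            heavy_fraction >= 0.80, heavy_fraction <= 0.95,
            length(count_range) == 2L, count_range[1L] >= 1L,
            count_range[2L] >= count_range[1L])
  structure(list(genes = genes, n_sequences = as.integer(n_sequences),
                 n_files = as.integer(n_files), mode = mode,
                 heavy_fraction = heavy_fraction,
                 antisense_sub_fraction = antisense_sub_fraction,
                 count_range = as.integer(count_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Non-coding intervals: complement of the union of gene intervals.
noncoding_intervals <- function(genes) {
  g <- genes$genes
  ir <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
  gaps <- IRanges::gaps(ir, start = 1L, end = genes$genome$length)
  data.frame(start = IRanges::start(gaps), end = IRanges::end(gaps))
}

# Is `pos` a tRF-1 trailer start (1..off nt past a same-strand tRNA 3' end)?
in_trf1_trailer <- function(pos, strand, genes, off = 3L) {
  g <- genes$genes
  idx <- which(g$biotype == "tRNA" & g$strand == strand)
  for (i in idx) {
    d <- if (g$strand[i] == "H") pos - g$end[i] else g$start[i] - pos
    if (d >= 1L && d <= off) return(TRUE)
  }
  FALSE
}

# Uniform draw from a:b, safe when a == b (sample() would misread a scalar).
sample_range <- function(a, b) {
  if (a > b) stop("empty range")
  if (a == b) return(a)
  sample(seq.int(a, b), 1L)
}

# Number of genes containing a position.
n_genes_at <- function(pos, genes) {
  sum(genes$genes$start <= pos & genes$genes$end >= pos)
}

# Draw one candidate sequence record, or NULL when the draw is rejected.
# Rejection keeps the ground truth exact: draws are discarded when their
# placement would be ambiguous to the aligner, when the start falls in a
# tRF-1 trailer or an overlapping-gene region (gene assignment tie), or when
# an antisense mutation creates a trailing CCA.
draw_candidate <- function(cfg, antisense, strand = NULL) {
  genes <- cfg$genes
  genome <- genes$genome
  g <- genes$genes
  nc <- noncoding_intervals(genes)
  lim <- if (cfg$mode == "sRNA") c(15L, 50L) else c(50L, 300L)
  if (antisense) {
    src <- g[g$strand == "H", , drop = FALSE]
    i <- sample.int(nrow(src), 1L)
    len <- sample_range(lim[1L], lim[2L])
    p <- sample_range(src$start[i], src$end[i])   # read 5' (L read)
    lo <- p - len + 1L
    if (lo < 1L) return(NULL)
    if (n_genes_at(p, genes) != 1L) return(NULL)
    if (in_trf1_trailer(p, "L", genes)) return(NULL)
    base_seq <- reverse_complement(genome_substr(genome, lo, p))
    mpos <- sample_range(2L, len - 1L)
    old <- substr(base_seq, mpos, mpos)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    seq <- paste0(substr(base_seq, 1L, mpos - 1L), new,
                  substr(base_seq, mpos + 1L, len))
    if (endsWith(seq, "CCA")) return(NULL)
    return(list(sequence = seq, gene = src$gene_name[i],
                biotype = src$biotype[i], strand = "L",
                orientation = "antisense", start = p, length = len,
                substitutions = paste0(mpos, new), lo = lo,
                mm_pos = mpos, mm_base = new))
  }
  if (is.null(strand)) {
    strand <- if (runif(1L) < cfg$heavy_fraction) "H" else "L"
  }
  gene_src <- g[g$strand == strand, , drop = FALSE]
  n_src <- nrow(gene_src) + nrow(nc)
  k <- sample.int(n_src, 1L)
  len <- sample_range(lim[1L], lim[2L])
  if (k <= nrow(gene_src)) {
    src <- gene_src[k, ]
    p <- sample_range(src$start, src$end)
    gene_name <- src$gene_name; biotype <- src$biotype
    if (n_genes_at(p, genes) != 1L) return(NULL)
  } else {
    ivl <- nc[k - nrow(gene_src), ]
    ilen <- ivl$end - ivl$start + 1L
    if (ilen < lim[1L]) return(NULL)
    len <- sample_range(lim[1L], min(lim[2L], ilen))
    # confine to the interval so the read is wholly non-coding
    p <- if (strand == "H") sample_range(ivl$start, ivl$end - len + 1L)
         else sample_range(ivl$start + len - 1L, ivl$end)
    gene_name <- "nc"; biotype <- "non_coding"
  }
  lo <- if (strand == "H") p else p - len + 1L
  hi <- lo + len - 1L
  if (lo < 1L || hi > genome$length) return(NULL)
  if (in_trf1_trailer(p, strand, genes)) return(NULL)
  raw <- genome_substr(genome, lo, hi)
  seq <- if (strand == "H") raw else reverse_complement(raw)
  list(sequence = seq, gene = gene_name, biotype = biotype, strand = strand,
       orientation = "sense", start = p, length = len,
       substitutions = "NIL", lo = lo, mm_pos = NA_integer_,
       mm_base = NA_character_)
}

# Verify that the aligner reproduces the candidate's recorded placement.
candidate_alignable <- function(cand, cfg) {
  al <- align_sequence(cand$sequence, cfg$genes$genome)
  if (!al$mapped || al$multimap) return(FALSE)
  if (al$genome_start != cand$lo || al$strand != cand$strand) return(FALSE)
  if (cand$substitutions == "NIL") {
    al$n_mismatch == 0L
  } else {
    al$n_mismatch == 1L && al$mm_pos == cand$mm_pos &&
      al$mm_base == cand$mm_base
  }
}

# Per-file counts: uniform draws, heavy-strand counts rescaled so the
# realized heavy read fraction matches the target in expectation, then
# clamped to the configured minimum.
draw_counts <- function(strands, cfg) {
  n <- length(strands)
  f <- cfg$heavy_fraction
  lo <- cfg$count_range[1L]; hi <- cfg$count_range[2L]
  counts <- matrix(sample(seq.int(lo, hi), n * cfg$n_files, replace = TRUE),
                   nrow = n, ncol = cfg$n_files)
  h <- strands == "H"
  for (j in seq_len(cfg$n_files)) {
    s_h <- sum(counts[h, j]); s_l <- sum(counts[!h, j])
    if (s_h == 0L || s_l == 0L) next
    alpha <- (f / (1 - f)) * s_l / s_h
    counts[h, j] <- pmax(lo, as.integer(round(counts[h, j] * alpha)))
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate mitochondrial reads with known ground truth
#'
#' Draws unique sequences from random genes or non-coding regions on either
#' strand of the reference, light-strand sequences being emitted as the
#' reverse complement of the forward strand; a configurable subset is
#' generated antisense to heavy-strand genes with one planted internal
#' substitution (these read as light-strand transcripts). Per-file counts
#' are drawn uniformly from `count_range` and allocated so that the realized
#' heavy-strand read fraction lies within \[0.80, 0.95\]. Draws whose genome
#' placement would be ambiguous, or whose annotation would be
#' position-dependent (tRF-1 trailer starts, overlapping-gene starts), are
#' redrawn so that the truth table is exactly reproducible by the pipeline.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Directory for the FASTQ files and truth CSV.
#' @return List with `fastq` (paths, `file_1.fastq` ...), `truth`
#'   (data.frame: sequence, gene, biotype, strand, orientation, start,
#'   length, substitutions, then per-library counts) and `truth_csv` (path).
#'   Fully reproducible from `cfg$seed`.
#' @export
simulate_reads <- function(cfg, out_dir = tempfile("sim")) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(cfg$seed, {
    n_as <- if (cfg$mode == "lncRNA") {
      max(1L, as.integer(round(cfg$n_sequences * cfg$antisense_sub_fraction)))
    } else {
      as.integer(round(cfg$n_sequences * cfg$antisense_sub_fraction))
    }
    n_sense <- cfg$n_sequences - n_as
    # deterministic strand allocation so the heavy read fraction is
    # controllable for every seed; at least one sequence per strand
    n_l <- max(1L, as.integer(round(n_sense * (1 - cfg$heavy_fraction))))
    n_h <- n_sense - n_l
    if (n_h < 1L) {
      stop("simulation infeasible: too few sequences to populate both strands")
    }
    strand_plan <- sample(c(rep("H", n_h), rep("L", n_l)))
    flags <- c(rep(TRUE, n_as), rep(FALSE, n_sense))
    records <- vector("list", cfg$n_sequences)
    seen <- character(0)
    max_tries <- 200L * cfg$n_sequences
    tries <- 0L
    for (i in seq_len(cfg$n_sequences)) {
      repeat {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("simulation infeasible: could not draw ", cfg$n_sequences,
               " unambiguous unique sequences from this reference")
        }
        cand <- draw_candidate(cfg, antisense = flags[i],
                               strand = if (flags[i]) NULL
                                        else strand_plan[i - n_as])
        if (is.null(cand)) next
        if (cand$sequence %in% seen) next
        if (!candidate_alignable(cand, cfg)) next
        break
      }
      seen <- c(seen, cand$sequence)
      records[[i]] <- cand
    }
    truth <- do.call(rbind, lapply(records, function(r) {
      data.frame(sequence = r$sequence, gene = r$gene, biotype = r$biotype,
                 strand = r$strand, orientation = r$orientation,
                 start = r$start, length = r$length,
                 substitutions = r$substitutions, stringsAsFactors = FALSE)
    }))
    for (try in seq_len(50L)) {
      counts <- draw_counts(truth$strand, cfg)
      frac <- sum(counts[truth$strand == "H", ]) / sum(counts)
      if (frac >= 0.80 && frac <= 0.95) break
      if (try == 50L) {
        stop("simulation infeasible: heavy-strand read fraction never ",
             "reached [0.80, 0.95] under this configuration")
      }
    }
    libs <- paste0("file_", seq_len(cfg$n_files))
    colnames(counts) <- libs
    fastq <- file.path(out_dir, paste0(libs, ".fastq"))
    for (j in seq_len(cfg$n_files)) {
      reads <- rep(truth$sequence, counts[, j])
      ids <- paste0("t", rep(seq_len(nrow(truth)), counts[, j]), ".",
                    seq_along(reads))
      dss <- Biostrings::DNAStringSet(reads)
      names(dss) <- ids
      quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(dss)))
      Biostrings::writeXStringSet(dss, fastq[j], format = "fastq",
                                  qualities = quals)
    }
    truth <- cbind(truth, as.data.frame(counts, stringsAsFactors = FALSE))
    ord <- order(-rowSums(counts), truth$sequence)
    truth <- truth[ord, , drop = FALSE]
    rownames(truth) <- NULL
    truth_csv <- file.path(out_dir, "truth.csv")
    utils::write.csv(truth, truth_csv, row.names = FALSE, quote = FALSE)
    list(fastq = fastq, truth = truth, truth_csv = truth_csv)
  })
}

concordance_criterion <- function(name, n, n_mismatch) {
  data.frame(criterion = name, n_compared = n, n_mismatch = n_mismatch,
             pass = n_mismatch == 0L, stringsAsFactors = FALSE)
}

#' Element-wise concordance between simulator truth and pipeline output
#'
#' Rows are aligned by sequence and four criteria are checked: (1) identity
#' of the unique sequence sets; (2) every truth sequence mapped, with the
#' expected strand and strand distribution; (3) total and per-file counts;
#' (4) annotation (gene, biotype, orientation, start, length, substitutions)
#' and the count distribution among the four biotypes (tRNA, rRNA,
#' protein-coding, non-coding). The check passes only when every compared
#' cell matches.
#'
#' @param truth Truth data.frame (or CSV path) from [simulate_reads()].
#' @param tool_output Annotated data.frame (or CSV path) from the pipeline.
#' @return A list of class `mt_concordance`: `pass`, `criteria` (per-
#'   criterion summary) and `mismatches` (flagged cells, if any).
#' @export
check_concordance <- function(truth, tool_output) {
  if (is.character(truth)) truth <- utils::read.csv(truth,
                                                    stringsAsFactors = FALSE)
  if (is.character(tool_output)) {
    tool_output <- utils::read.csv(tool_output, stringsAsFactors = FALSE)
  }
  meta <- c("sequence", "gene", "biotype", "strand", "orientation", "start",
            "length", "substitutions")
  libs <- setdiff(names(truth), meta)
  if (!all(libs %in% names(tool_output))) {
    stop("file sets differ: tool output lacks libraries ",
         paste(setdiff(libs, names(tool_output)), collapse = ", "))
  }
  crit <- list()
  flagged <- list()
  # (1) unique sequence sets
  only_truth <- setdiff(truth$sequence, tool_output$sequence)
  only_tool <- setdiff(tool_output$sequence, truth$sequence)
  n1 <- length(only_truth) + length(only_tool)
  crit$seqs <- concordance_criterion("unique_sequences",
                                     length(union(truth$sequence,
                                                  tool_output$sequence)), n1)
  if (n1 > 0L) {
    flagged$seqs <- data.frame(
      criterion = "unique_sequences",
      sequence = c(only_truth, only_tool),
      field = rep(c("missing_from_tool", "missing_from_truth"),
                  c(length(only_truth), length(only_tool))),
      stringsAsFactors = FALSE)
  }
  common <- intersect(truth$sequence, tool_output$sequence)
  ti <- match(common, truth$sequence)
  oi <- match(common, tool_output$sequence)
  compare_col <- function(name, tv, ov) {
    bad <- which(tv != ov)
    if (length(bad)) {
      flagged[[name]] <<- data.frame(criterion = name,
                                     sequence = common[bad], field = name,
                                     stringsAsFactors = FALSE)
    }
    length(bad)
  }
  # (2) mapped + strand distribution
  n_strand <- compare_col("strand", truth$strand[ti], tool_output$strand[oi])
  dist_ok <- identical(table(factor(truth$strand, c("H", "L"))),
                       table(factor(tool_output$strand, c("H", "L"))))
  crit$mapped <- concordance_criterion("mapped_and_strand",
                                       length(common) + 1L,
                                       n_strand + as.integer(!dist_ok) +
                                         length(only_truth))
  # (3) counts
  n_cnt <- 0L
  for (l in libs) {
    n_cnt <- n_cnt + compare_col(paste0("count_", l),
                                 truth[[l]][ti], tool_output[[l]][oi])
  }
  tot_ok <- sum(as.matrix(truth[ti, libs])) ==
    sum(as.matrix(tool_output[oi, libs]))
  crit$counts <- concordance_criterion("total_and_per_file_counts",
                                       length(common) * length(libs) + 1L,
                                       n_cnt + as.integer(!tot_ok))
  # (4) annotation + biotype distribution
  norm_sub <- function(x) {
    vapply(x, function(s) {
      p <- parse_substitution(s)
      if (is.na(p$pos)) "NIL" else paste0(p$pos, p$base)
    }, character(1L), USE.NAMES = FALSE)
  }
  n_ann <- compare_col("gene", truth$gene[ti], tool_output$gene[oi]) +
    compare_col("biotype", truth$biotype[ti], tool_output$biotype[oi]) +
    compare_col("orientation", truth$orientation[ti],
                tool_output$orientation[oi]) +
    compare_col("start", truth$start[ti], tool_output$start[oi]) +
    compare_col("length", truth$length[ti], tool_output$length[oi]) +
    compare_col("substitutions", norm_sub(truth$substitutions[ti]),
                norm_sub(tool_output$substitutions[oi]))
  bt_levels <- c("tRNA", "rRNA", "protein_coding", "non_coding")
  bt_reads <- function(df, idx) {
    vapply(bt_levels, function(b) {
      sum(as.matrix(df[idx, libs])[df$biotype[idx] == b, , drop = FALSE])
    }, numeric(1L))
  }
  bt_ok <- identical(bt_reads(truth, ti), bt_reads(tool_output, oi))
  crit$annotation <- concordance_criterion("annotation_and_biotypes",
                                           length(common) * 6L + 1L,
                                           n_ann + as.integer(!bt_ok))
  criteria <- do.call(rbind, crit)
  rownames(criteria) <- NULL
  mismatches <- if (length(flagged)) {
    do.call(rbind, c(flagged, list(make.row.names = FALSE)))
  } else {
    data.frame(criterion = character(0), sequence = character(0),
               field = character(0), stringsAsFactors = FALSE)
  }
  structure(list(pass = all(criteria$pass), criteria = criteria,
                 mismatches = mismatches),
            class = "mt_concordance")
}

#' @export
print.mt_concordance <- function(x, ...) {
  cat("Concordance:", if (x$pass) "PASS" else "FAIL", "\n")
  print(x$criteria)
  if (nrow(x$mismatches)) {
    cat(nrow(x$mismatches), "mismatching cells; see $mismatches\n")
  }
  invisible(x)
}
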