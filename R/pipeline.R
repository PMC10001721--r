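#' Run the full identification and annotation pipeline
#'
#' End-to-end workflow: collapse reads into a unique-sequence count matrix,
#' place every sequence on the mitochondrial genome (with CCA rescue of
#' unmapped sequences ending in the non-templated motif), annotate, and --
#' in lncRNA mode -- group 3' length variants by shared 5' end and apply the
#' optional length filter. Only the declared outputs are written (annotated
#' CSV, grouped CSV in lncRNA mode, statistics TSV, log); no intermediate
#' files are created, and partial outputs are removed on error.
#'
#' @param fastq_paths Character vector of adapter-trimmed FASTQ files.
#' @param fasta Mitochondrial genome FASTA (single record).
#' @param gtf GTF annotation restricted to the mitochondrial genes.
#' @param mode `"sRNA"` or `"lncRNA"`.
#' @param species Species code used in the identifiers (default "hsa").
#' @param cutoff Total-count cutoff (default 200).
#' @param filter Optional minimum length for lncRNA output (e.g. 200 to
#'   restrict to strict lncRNAs); `NULL` keeps everything >= 50 nt.
#' @param workers Parallel workers for counting (default 1); the output is
#'   identical for any worker count.
#' @param cfg An [annotation_config()].
#' @param out_dir Output directory (created if needed).
#' @param prefix File name prefix for outputs (default "mito").
#' @return Invisibly, a list: `annotated`, `grouped` (lncRNA mode or NULL),
#'   `stats`, `matrix`, `log`, `files` (paths written).
#' @export
run_pipeline <- function(fastq_paths, fasta, gtf, mode = c("sRNA", "lncRNA"),
                         species = "hsa", cutoff = 200L, filter = NULL,
                         workers = 1L, cfg = annotation_config(),
                         out_dir = ".", prefix = "mito") {
  mode <- match.arg(mode)
  if (!is.null(filter) && mode != "lncRNA") {
    stop("--filter applies to lncRNA mode only")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    message(line)
  }
  genome <- load_genome(fasta)
  genes <- load_annotation(gtf, genome)
  say("reference: genome '%s' %d nt, %d genes", genome$name, genome$length,
      nrow(genes$genes))
  matrix <- build_count_matrix(fastq_paths, mode = mode, cutoff = cutoff,
                               workers = workers)
  say("counting: %d files, %d total reads, %d unique sequences with total count >= %d",
      length(fastq_paths), sum(matrix$file_totals), nrow(matrix$counts),
      matrix$cutoff)
  aligned <- align_matrix(matrix, genome, genes,
                          tolerance = cfg$boundary_tolerance)
  st <- aligned$stats
  say("mapping: %d/%d sequences mapped (%.1f%% of reads); heavy strand %.1f%% of mapped reads, light %.1f%%",
      st$n_mapped, st$n_sequences, st$pct_reads_mapped, st$pct_heavy_reads,
      st$pct_light_reads)
  annotated <- annotate_alignments(aligned, matrix, genes, species = species,
                                   cfg = cfg)
  say("annotation: %d sequences annotated (%d tRNA, %d rRNA, %d protein-coding, %d non-coding)",
      nrow(annotated), sum(annotated$biotype == "tRNA"),
      sum(annotated$biotype == "rRNA"),
      sum(annotated$biotype == "protein_coding"),
      sum(annotated$biotype == "non_coding"))
  grouped <- NULL
  if (mode == "lncRNA") {
    grouped <- group_by_five_prime(annotated, matrix)
    say("grouping: %d 5'-anchor groups from %d unique sequences",
        nrow(grouped), nrow(annotated))
    if (!is.null(filter)) {
      grouped <- apply_length_filter(grouped, filter)
      annotated <- apply_length_filter(annotated, filter)
      say("length filter >= %d nt: %d groups, %d unique sequences retained",
          filter, nrow(grouped), nrow(annotated))
    }
  }
  ann_csv <- file.path(out_dir, sprintf("%s_%s_annotated.csv", prefix, mode))
  write_annotated_csv(annotated, ann_csv)
  written <- c(written, ann_csv)
  files <- list(annotated = ann_csv)
  if (!is.null(grouped)) {
    grp_csv <- file.path(out_dir, sprintf("%s_%s_grouped.csv", prefix, mode))
    utils::write.csv(grouped, grp_csv, row.names = FALSE, quote = FALSE)
    written <- c(written, grp_csv)
    files$grouped <- grp_csv
  }
  stats_tsv <- file.path(out_dir, sprintf("%s_%s_stats.tsv", prefix, mode))
  utils::write.table(st, stats_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  written <- c(written, stats_tsv)
  files$stats <- stats_tsv
  log_file <- file.path(out_dir, sprintf("%s_%s_log.txt", prefix, mode))
  writeLines(log, log_file)
  written <- c(written, log_file)
  files$log <- log_file
  ok <- TRUE
  invisible(list(annotated = annotated, grouped = grouped, stats = st,
                 matrix = matrix, log = log, files = files))
}

#' Compare identified sequences against a reference sequence set
#'
#' Splits the sequences of an annotated table into those present in a
#' reference list (overlap) and novel ones, by exact full-sequence string
#' match only. Both sides are deduplicated first. Optionally, novel
#' sequences are required to reach a minimum reads-per-million value in at
#' least one library.
#'
#' @param test Annotated data.frame (or CSV path) with a `sequence` column.
#' @param reference_sequences Character vector of reference sequences, or a
#'   path to a text/TSV file whose first column holds them.
#' @param min_rpm Optional RPM threshold for novel sequences (e.g. 1);
#'   requires `file_totals`.
#' @param file_totals Named per-library total read counts (pre-filter), as
#'   stored in `mt_counts$file_totals`.
#' @return List: `novel` (annotated rows whose sequence is absent from the
#'   reference), `n_novel`, `n_overlap`.
#' @export
compare_sequence_sets <- function(test, reference_sequences, min_rpm = NULL,
                                  file_totals = NULL) {
  if (is.character(test) && length(test) == 1L && file.exists(test)) {
    test <- read_annotated_csv(test)
  }
  if (length(reference_sequences) == 1L && file.exists(reference_sequences)) {
    reference_sequences <- utils::read.table(
      reference_sequences, stringsAsFactors = FALSE)[, 1L]
  }
  if (nrow(test) == 0L || length(reference_sequences) == 0L) {
    stop("both the test table and the reference list must be non-empty")
  }
  ref <- unique(reference_sequences)
  test <- test[!duplicated(test$sequence), , drop = FALSE]
  is_novel <- !(test$sequence %in% ref)
  novel <- test[is_novel, , drop = FALSE]
  if (!is.null(min_rpm)) {
    if (is.null(file_totals)) stop("min_rpm requires file_totals")
    libs <- names(file_totals)
    rpm <- as.matrix(novel[, libs, drop = FALSE]) *
      rep(1e6 / unlist(file_totals), each = nrow(novel))
    novel <- novel[apply(rpm, 1L, max) >= min_rpm, , drop = FALSE]
  }
  rownames(novel) <- NULL
  list(novel = novel, n_novel = nrow(novel), n_overlap = sum(!is_novel))
}
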