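#' @importFrom stats setNames
NULL

new_mt_counts <- function(counts, mode, cutoff, file_totals) {
  structure(
    list(counts = counts, mode = mode, cutoff = cutoff,
         file_totals = file_totals),
    class = "mt_counts"
  )
}

#' @export
print.mt_counts <- function(x, ...) {
  cat(sprintf("mt_counts [%s]: %d unique sequences x %d files (cutoff %d)\n",
              x$mode, nrow(x$counts), ncol(x$counts), x$cutoff))
  invisible(x)
}

# Read one FASTQ file and return a named integer vector of per-unique-sequence
# counts for length-eligible reads, plus the file's total read number.
count_one_fastq <- function(path, mode) {
  reads <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
  quals <- S4Vectors::mcols(reads)$qualities
  # a quality line shorter than its read is NUL-padded by the parser; the
  # padding surfaces as an embedded-nul error on conversion
  qual_ok <- tryCatch({
    as.character(quals); TRUE
  }, error = function(e) FALSE)
  if (!qual_ok || any(Biostrings::width(reads) != Biostrings::width(quals))) {
    stop("malformed FASTQ record in ", path,
         ": sequence and quality lengths differ")
  }
  w <- Biostrings::width(reads)
  total <- length(reads)
  keep <- if (mode == "sRNA") w <= 50L else w >= 50L
  tab <- table(as.character(reads[keep]))
  list(counts = setNames(as.integer(tab), names(tab)), total = total)
}

#' Collapse FASTQ files into a unique-sequence count matrix
#'
#' Every read is collapsed by exact full-sequence string identity. Reads
#' failing the mode length rule are dropped before counting: small-RNA mode
#' keeps reads of at most 50 nt, long-ncRNA mode keeps reads of at least
#' 50 nt (a 50-nt read is eligible for both modes). After counting, unique
#' sequences whose total count across all files falls below `cutoff` are
#' removed; the default of 200 discards sequences whose counting accuracy is
#' erratic at low depth. Rows are ordered by descending total count, ties
#' broken lexicographically, so output is deterministic.
#'
#' Files are processed independently (optionally in parallel, one worker per
#' file) and merged; the result is identical for any worker count.
#'
#' @param fastq_paths Character vector of FASTQ paths (gzip accepted).
#' @param mode `"sRNA"` or `"lncRNA"`.
#' @param cutoff Minimum total count across files for a sequence to be
#'   retained (total >= cutoff). Default 200.
#' @param workers Number of parallel workers (default 1).
#' @return An object of class `mt_counts`: integer matrix `counts` with
#'   unique sequences as row names and library (file base-)names as column
#'   names, the `mode`, the applied `cutoff`, and `file_totals` (total reads
#'   per input file, before any filtering), used for RPM normalization.
#' @export
build_count_matrix <- function(fastq_paths, mode = c("sRNA", "lncRNA"),
                               cutoff = 200L, workers = 1L) {
  mode <- match.arg(mode)
  if (length(fastq_paths) == 0L) stop("no input FASTQ files given")
  missing <- fastq_paths[!file.exists(fastq_paths)]
  if (length(missing)) stop("FASTQ file(s) not found: ",
                            paste(missing, collapse = ", "))
  per_file <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(fastq_paths, count_one_fastq, mode = mode,
                       mc.cores = workers)
  } else {
    lapply(fastq_paths, count_one_fastq, mode = mode)
  }
  err <- vapply(per_file, function(x) inherits(x, "try-error"), logical(1L))
  if (any(err)) stop("FASTQ counting failed: ", per_file[[which(err)[1L]]])
  libs <- library_names(fastq_paths)
  seqs <- sort(unique(unlist(lapply(per_file, function(x) names(x$counts)))))
  counts <- matrix(0L, nrow = length(seqs), ncol = length(libs),
                   dimnames = list(seqs, libs))
  for (j in seq_along(per_file)) {
    cj <- per_file[[j]]$counts
    counts[names(cj), j] <- cj
  }
  totals <- vapply(per_file, function(x) x$total, integer(1L))
  m <- new_mt_counts(counts, mode, as.integer(cutoff),
                     setNames(totals, libs))
  apply_count_cutoff(m)
}

# Library name = file name without directory or fastq extensions.
library_names <- function(paths) {
  nm <- basename(paths)
  nm <- sub("\\.gz$", "", nm)
  nm <- sub("\\.(fastq|fq)$", "", nm)
  if (anyDuplicated(nm)) stop("duplicate library names after stripping paths: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  nm
}

# Drop sequences below the total-count cutoff and impose the canonical row
# order (descending total, ties lexicographic by sequence).
apply_count_cutoff <- function(m) {
  tot <- rowSums(m$counts)
  keep <- tot >= m$cutoff
  counts <- m$counts[keep, , drop = FALSE]
  if (nrow(counts) == 0L) {
    m$counts <- counts
    return(m)
  }
  tot <- tot[keep]
  ord <- order(-tot, rownames(counts))
  m$counts <- counts[ord, , drop = FALSE]
  m
}

#' Merge partial count matrices over disjoint file subsets
#'
#' Supports split-apply-merge counting: fragments built with `cutoff = 0`
#' over disjoint file sets are merged into the matrix a single pass would
#' produce, and the final cutoff is applied to the merged totals. Merging is
#' commutative and associative up to the fixed column order given by the
#' order of the fragments.
#'
#' @param partials List of `mt_counts` fragments with pairwise disjoint file
#'   (column) sets and a common mode.
#' @param cutoff Total-count cutoff applied after merging (default 200).
#' @return A merged `mt_counts`.
#' @export
merge_partial_counts <- function(partials, cutoff = 200L) {
  stopifnot(length(partials) >= 1L,
            all(vapply(partials, inherits, logical(1L), "mt_counts")))
  modes <- unique(vapply(partials, function(x) x$mode, character(1L)))
  if (length(modes) != 1L) stop("fragments have differing modes")
  files <- unlist(lapply(partials, function(x) colnames(x$counts)))
  if (anyDuplicated(files)) {
    stop("fragments overlap in file names: ",
         paste(unique(files[duplicated(files)]), collapse = ", "))
  }
  seqs <- sort(unique(unlist(lapply(partials, function(x) rownames(x$counts)))))
  counts <- matrix(0L, nrow = length(seqs), ncol = length(files),
                   dimnames = list(seqs, files))
  for (p in partials) {
    counts[rownames(p$counts), colnames(p$counts)] <- p$counts
  }
  totals <- unlist(lapply(partials, function(x) x$file_totals))
  m <- new_mt_counts(counts, modes, as.integer(cutoff),
                     setNames(totals, files))
  apply_count_cutoff(m)
}

#' Write / read a count matrix as CSV
#'
#' First column `sequence`, remaining columns one per library. The round trip
#' is lossless for the counts; `mode` and `cutoff` must be restated on read.
#'
#' @param matrix An `mt_counts`.
#' @param path Output CSV path.
#' @export
write_count_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "mt_counts"))
  df <- data.frame(sequence = rownames(matrix$counts),
                   matrix$counts, row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_count_csv
#' @param mode,cutoff Matrix metadata to attach on read.
#' @export
read_count_csv <- function(path, mode = c("sRNA", "lncRNA"), cutoff = 200L) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  counts <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$sequence
  new_mt_counts(counts, mode, as.integer(cutoff),
                setNames(rep(NA_integer_, ncol(counts)), colnames(counts)))
}
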