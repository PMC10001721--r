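#' Annotation parameters
#'
#' @param boundary_tolerance Tolerance in nt when matching read ends to gene
#'   boundaries (default 3). Mitochondrial genes overlap and fragment ends
#'   are ragged, so exact boundary matching would miss genuine
#'   boundary-anchored fragments.
#' @param trh_min_length Minimum length in nt for a boundary-anchored tRNA
#'   fragment to be called a tRNA half (tRH) rather than a tRF (default 30;
#'   tRNA halves are typically 30-34 nt).
#' @param srna_max_length Maximum small-RNA length in nt (default 50).
#' @param trf1_max_offset Maximum offset in nt past a tRNA gene's 3' end for
#'   a read start to qualify as a tRF-1 (3' trailer fragment; default 3).
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(boundary_tolerance = 3L, trh_min_length = 30L,
                              srna_max_length = 50L, trf1_max_offset = 3L) {
  stopifnot(boundary_tolerance >= 0L, trh_min_length >= 0L,
            srna_max_length >= 0L, trf1_max_offset >= 0L)
  structure(list(boundary_tolerance = as.integer(boundary_tolerance),
                 trh_min_length = as.integer(trh_min_length),
                 srna_max_length = as.integer(srna_max_length),
                 trf1_max_offset = as.integer(trf1_max_offset)),
            class = "annotation_config")
}

# Genomic positions of a gene's 5'/3' ends in gene orientation.
gene_five_prime <- function(g) if (g$strand == "H") g$start else g$end
gene_three_prime <- function(g) if (g$strand == "H") g$end else g$start

# Offset of a read start past a tRNA gene's 3' end, measured downstream in
# gene orientation; positive values lie in the 3' trailer.
trailer_offset <- function(r5, g) {
  if (g$strand == "H") r5 - g$end else g$start - r5
}

# Pick one gene among candidates: prefer genes on the read's strand (sense),
# then annotation order. Returns a row index into `genes`.
pick_gene <- function(idx, genes, read_strand) {
  if (length(idx) == 1L) return(idx)
  sense <- idx[genes$strand[idx] == read_strand]
  if (length(sense)) sense[1L] else idx[1L]
}

#' Classify the genomic location of an alignment
#'
#' Assigns each mapped sequence a location class and a gene:
#' \describe{
#'   \item{A}{the read start site falls within a gene (the read may overhang
#'     that gene's boundary into non-coding DNA);}
#'   \item{B}{the read starts in a non-coding region and overlaps a gene;}
#'   \item{D}{the read starts in one gene and ends within a different gene
#'     (overlapping reading frames make this common) -- the gene containing
#'     the start site is taken for annotation;}
#'   \item{C}{the read lies entirely in non-coding DNA (gene "nc").}
#' }
#' The start site is the 5' end of the read in its own orientation. The one
#' exception to start-site assignment is tRF-1: a read starting within
#' `trf1_max_offset` nt after a tRNA gene's 3' end (on the same strand) is
#' assigned to that tRNA as its 3' trailer fragment, even when its start lies
#' in the next gene or in non-coding DNA; such reads are reported with class
#' A, the trailer being treated as an extension of the tRNA gene.
#'
#' @param al An alignment list from [align_sequence()] (mapped).
#' @param genes A `mito_genes`.
#' @param cfg An [annotation_config()].
#' @return List with `location_class`, `gene_idx` (row in `genes$genes`, or
#'   NA for "nc") and `is_trf1`.
#' @export
classify_location <- function(al, genes, cfg = annotation_config()) {
  if (!isTRUE(al$mapped)) stop("cannot classify an unmapped sequence")
  g <- genes$genes
  lo <- al$genome_start
  hi <- al$genome_start + al$length - 1L
  r5 <- read_five_prime(al)
  # tRF-1 exception: start in the 3' trailer of a same-strand tRNA gene
  trna_idx <- which(g$biotype == "tRNA" & g$strand == al$strand)
  for (i in trna_idx) {
    off <- trailer_offset(r5, g[i, ])
    if (off >= 1L && off <= cfg$trf1_max_offset) {
      return(list(location_class = "A", gene_idx = i, is_trf1 = TRUE))
    }
  }
  at_start <- which(g$start <= r5 & g$end >= r5)
  if (length(at_start)) {
    gi <- pick_gene(at_start, g, al$strand)
    within <- g$start[gi] <= lo && g$end[gi] >= hi
    if (within) {
      return(list(location_class = "A", gene_idx = gi, is_trf1 = FALSE))
    }
    e3 <- read_three_prime(al)
    other <- setdiff(which(g$start <= e3 & g$end >= e3), gi)
    cls <- if (length(other)) "D" else "A"
    return(list(location_class = cls, gene_idx = gi, is_trf1 = FALSE))
  }
  overlapping <- which(g$start <= hi & g$end >= lo)
  if (length(overlapping)) {
    # class B: assign the overlapped gene nearest the read start
    d <- pmin(abs(g$start[overlapping] - r5), abs(g$end[overlapping] - r5))
    near <- overlapping[d == min(d)]
    gi <- pick_gene(near, g, al$strand)
    return(list(location_class = "B", gene_idx = gi, is_trf1 = FALSE))
  }
  list(location_class = "C", gene_idx = NA_integer_, is_trf1 = FALSE)
}

#' Classify the tRNA-fragment subtype of an alignment
#'
#' Fragments of tRNA genes are typed by where their ends sit relative to the
#' gene boundaries, in gene orientation and with the configured boundary
#' tolerance. A read is 5'-anchored when either of its ends lies within
#' `boundary_tolerance` nt of the gene's 5' boundary, and 3'-anchored when
#' either end lies within tolerance of the 3' boundary or the read carried a
#' non-templated CCA (which marks a mature tRNA 3' end). Anchored fragments
#' of at least `trh_min_length` nt are halves (tRH-5 / tRH-3), shorter ones
#' are tRFs (tRF-5 / tRF-3); 5'-anchoring wins when both apply. Reads
#' starting 1..`trf1_max_offset` nt past the gene 3' end are tRF-1 (handled
#' in [classify_location()]). Everything else is internal: i-tRF-5 when the
#' read midpoint lies in the gene's 5' half (ties to 5'), i-tRF-3 otherwise.
#'
#' @param al A mapped alignment list.
#' @param gene One-row data.frame for the assigned tRNA gene.
#' @param cfg An [annotation_config()].
#' @param is_trf1 Was the read assigned through the tRF-1 trailer exception?
#' @return Subtype string: one of tRF-5, tRF-3, tRH-5, tRH-3, i-tRF-5,
#'   i-tRF-3, tRF-1.
#' @export
classify_trf_subtype <- function(al, gene, cfg = annotation_config(),
                                 is_trf1 = FALSE) {
  if (gene$biotype != "tRNA") stop("subtype classification requires a tRNA gene")
  if (is_trf1) return("tRF-1")
  tol <- cfg$boundary_tolerance
  g5 <- gene_five_prime(gene)
  g3 <- gene_three_prime(gene)
  r5 <- read_five_prime(al)
  r3 <- read_three_prime(al)
  five_anchored <- min(abs(r5 - g5), abs(r3 - g5)) <= tol
  three_anchored <- isTRUE(al$cca_added) ||
    min(abs(r3 - g3), abs(r5 - g3)) <= tol
  long <- al$length >= cfg$trh_min_length
  if (five_anchored) return(if (long) "tRH-5" else "tRF-5")
  if (three_anchored) return(if (long) "tRH-3" else "tRF-3")
  mid <- (al$genome_start + (al$genome_start + al$length - 1L)) / 2
  gene_pos <- if (gene$strand == "H") mid - gene$start + 1 else gene$end - mid + 1
  gene_len <- gene$end - gene$start + 1L
  if (gene_pos <= (gene_len + 1) / 2) "i-tRF-5" else "i-tRF-3"
}

#' Encode the substitution of an alignment
#'
#' Mismatches against the reference are reported as the 1-based position from
#' the read's 5' end followed by the read base at that position, e.g. "24C";
#' "NIL" when the read matches the genome exactly.
#'
#' @param al An alignment list (at most one mismatch by contract).
#' @return Substitution string.
#' @export
encode_substitutions <- function(al) {
  if (is.na(al$n_mismatch) || al$n_mismatch == 0L) return("NIL")
  paste0(al$mm_pos, al$mm_base)
}

#' Parse a substitution string
#'
#' Accepts "NIL", "<pos><base>" and the legacy form with a trailing digit
#' ("24C0"), which is ignored.
#'
#' @param x Substitution string.
#' @return List with `pos` (integer, NA for NIL) and `base`.
#' @export
parse_substitution <- function(x) {
  if (identical(x, "NIL")) return(list(pos = NA_integer_, base = NA_character_))
  m <- regmatches(x, regexec("^([0-9]+)([ACGT])[0-9]?$", x))[[1L]]
  if (length(m) != 3L) stop("unparseable substitution string: ", x)
  list(pos = as.integer(m[2L]), base = m[3L])
}

id_start_field <- function(orientation, start) {
  ifelse(orientation == "antisense", paste0("as", start), as.character(start))
}

#' Build specific nomenclature identifiers
#'
#' The specific ID uniquely identifies every isoform. Small RNAs:
#' `species|mt-sRNA|gene|subtype|strand|[as]start|length`, the subtype field
#' being present only for tRNA-derived sequences; long ncRNAs:
#' `species|mt-lncRNA|gene|strand|[as]start|length`. Antisense orientation is
#' encoded by prefixing "as" to the start position. Substitutions are kept in
#' their own output column, not embedded in the ID. Species codes are
#' lowercased.
#'
#' @param ann A data.frame with columns `gene`, `subtype`, `strand`,
#'   `orientation`, `start`, `length` (subtype is ignored for lncRNA mode).
#' @param species Three- or four-letter species code.
#' @param mode `"sRNA"` or `"lncRNA"`.
#' @return Character vector of specific IDs.
#' @export
specific_id <- function(ann, species, mode = c("sRNA", "lncRNA")) {
  mode <- match.arg(mode)
  species <- tolower(species)
  if (NROW(ann) == 0L) return(character(0))
  startf <- id_start_field(ann$orientation, ann$start)
  if (mode == "sRNA") {
    sub_field <- ifelse(is.na(ann$subtype) | ann$subtype == "none",
                        NA_character_, ann$subtype)
    parts <- cbind(species, "mt-sRNA", ann$gene, sub_field, ann$strand,
                   startf, ann$length)
  } else {
    parts <- cbind(species, "mt-lncRNA", ann$gene, ann$strand, startf,
                   ann$length)
  }
  apply(parts, 1L, function(p) paste(p[!is.na(p)], collapse = "|"))
}

#' Build general (family-level) nomenclature identifiers
#'
#' The general ID drops the sequence length (and any substitution), so all
#' length and modification variants sharing species, gene, subtype, strand,
#' orientation and start position collapse into one family.
#'
#' @inheritParams specific_id
#' @return Character vector of general IDs.
#' @export
general_id <- function(ann, species, mode = c("sRNA", "lncRNA")) {
  ids <- specific_id(ann, species, mode)
  sub("\\|[0-9]+$", "", ids)
}

#' Split a specific ID back into its fields
#'
#' @param id A specific ID string.
#' @return Named list of fields; `orientation` is recovered from the "as"
#'   prefix of the start field.
#' @export
parse_specific_id <- function(id) {
  f <- strsplit(id, "|", fixed = TRUE)[[1L]]
  kind <- f[2L]
  startf <- f[length(f) - 1L]
  anti <- startsWith(startf, "as")
  start <- as.integer(sub("^as", "", startf))
  out <- list(species = f[1L], kind = kind, gene = f[3L],
              orientation = if (anti) "antisense" else "sense",
              start = start, length = as.integer(f[length(f)]))
  if (kind == "mt-sRNA") {
    out$subtype <- if (length(f) == 7L) f[4L] else "none"
    out$strand <- f[length(f) - 2L]
  } else {
    out$strand <- f[4L]
  }
  out
}

#' Annotate aligned sequences
#'
#' Combines alignment, location/gene assignment, subtype classification,
#' substitution encoding and the two-level nomenclature into the final
#' annotated table. Unmapped sequences are dropped (they are counted in the
#' alignment statistics).
#'
#' @param aligned Result of [align_matrix()].
#' @param matrix The `mt_counts` the alignments came from.
#' @param genes A `mito_genes`.
#' @param species Species code for the identifiers.
#' @param cfg An [annotation_config()].
#' @return A data.frame with one row per mapped unique sequence: sequence,
#'   specific_id, general_id, gene, biotype, location_class, subtype, strand,
#'   orientation, start, length, substitutions, cca_added, multimap, followed
#'   by one count column per library.
#' @export
annotate_alignments <- function(aligned, matrix, genes, species = "hsa",
                                cfg = annotation_config()) {
  stopifnot(inherits(matrix, "mt_counts"), inherits(genes, "mito_genes"))
  aln <- aligned$alignments
  mapped <- which(aln$mapped)
  g <- genes$genes
  rows <- lapply(mapped, function(i) {
    al <- as.list(aln[i, ])
    loc <- classify_location(al, genes, cfg)
    if (is.na(loc$gene_idx)) {
      gene_name <- "nc"; biotype <- "non_coding"; orientation <- "sense"
      subtype <- "none"
    } else {
      gr <- g[loc$gene_idx, ]
      gene_name <- gr$gene_name
      biotype <- gr$biotype
      orientation <- if (al$strand == gr$strand) "sense" else "antisense"
      subtype <- if (biotype == "tRNA") {
        classify_trf_subtype(al, gr, cfg, is_trf1 = loc$is_trf1)
      } else "none"
    }
    data.frame(sequence = al$sequence, gene = gene_name, biotype = biotype,
               location_class = loc$location_class, subtype = subtype,
               strand = al$strand, orientation = orientation,
               start = read_five_prime(al), length = al$length,
               substitutions = encode_substitutions(al),
               cca_added = al$cca_added, multimap = al$multimap,
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  if (is.null(ann)) {
    ann <- data.frame(sequence = character(0), gene = character(0),
                      biotype = character(0), location_class = character(0),
                      subtype = character(0), strand = character(0),
                      orientation = character(0), start = integer(0),
                      length = integer(0), substitutions = character(0),
                      cca_added = logical(0), multimap = logical(0),
                      stringsAsFactors = FALSE)
  }
  ann$specific_id <- specific_id(ann, species, matrix$mode)
  ann$general_id <- general_id(ann, species, matrix$mode)
  cols <- c("sequence", "specific_id", "general_id", "gene", "biotype",
            "location_class", "subtype", "strand", "orientation", "start",
            "length", "substitutions", "cca_added", "multimap")
  ann <- ann[, cols]
  counts <- matrix$counts[ann$sequence, , drop = FALSE]
  out <- cbind(ann, as.data.frame(counts, stringsAsFactors = FALSE),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read the annotated CSV
#'
#' @param annotated Annotated data.frame from [annotate_alignments()].
#' @param path CSV path.
#' @export
write_annotated_csv <- function(annotated, path) {
  utils::write.csv(annotated, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotated_csv
#' @export
read_annotated_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Append reads-per-million columns to an annotated table
#'
#' RPM normalizes each library's counts by that library's total read number
#' (all reads in the input FASTQ, before any filtering) times 10^6.
#'
#' @param annotated Annotated data.frame.
#' @param file_totals Named vector of per-library total read counts.
#' @return The table with one additional `rpm.<library>` column per library.
#' @export
add_rpm <- function(annotated, file_totals) {
  for (lib in names(file_totals)) {
    annotated[[paste0("rpm.", lib)]] <-
      annotated[[lib]] * 1e6 / file_totals[[lib]]
  }
  annotated
}
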