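#' Load a mitochondrial genome from a single-record FASTA file
#'
#' The mitochondrial genome is a single contig, so the FASTA file must contain
#' exactly one record. The sequence is uppercased and validated against the
#' DNA alphabet (A/C/G/T/N). The genome is treated as linear: reads spanning
#' the replication origin of the circular molecule will not map.
#'
#' @param fasta_path Path to a FASTA file with exactly one record.
#' @return An object of class `mito_genome`: a list with `name`, `sequence`
#'   (uppercase character scalar) and `length` (nt).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">mt", "acgtACGT"), fa)
#' g <- load_genome(fa)
#' g$length
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  recs <- Biostrings::readBStringSet(fasta_path, format = "fasta")
  if (length(recs) != 1L) {
    stop("mitochondrial genome FASTA must contain exactly one record, found ",
         length(recs))
  }
  seq <- toupper(as.character(recs[[1L]]))
  if (grepl("[^ACGTN]", seq)) {
    stop("genome sequence contains characters outside {A,C,G,T,N}")
  }
  structure(
    list(name = sub("\\s.*$", "", names(recs)[1L]),
         sequence = seq,
         length = nchar(seq)),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("mito_genome '%s': %d nt\n", x$name, x$length))
  invisible(x)
}

# Three-letter amino-acid codes used to normalize mitochondrial tRNA gene
# names. Ensembl-style names ("mt-Te", "mt-Tl1") carry a one-letter code;
# other annotations spell the amino acid ("tRNA-Glu", "mt-tRNA-Glu", "trnE").
.aa_one_to_three <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

#' Normalize a mitochondrial tRNA gene name to its amino-acid code
#'
#' Identifiers name tRNA genes by amino acid ("Glu", "Arg"), while GTF files
#' use annotation-specific forms such as "mt-Te", "mt-Tl1", "tRNA-Glu" or
#' "trnE". Non-tRNA names are returned verbatim.
#'
#' @param name Gene name as found in the GTF `gene_name` attribute.
#' @param biotype Biotype of the gene; normalization only applies to "tRNA".
#' @return Normalized gene name.
#' @export
normalize_trna_name <- function(name, biotype = "tRNA") {
  if (!identical(biotype, "tRNA")) return(name)
  # already a three-letter amino-acid code?
  three <- unname(.aa_one_to_three)
  hit <- three[match(tolower(name), tolower(three))]
  if (!is.na(hit)) return(hit)
  # spelled-out code embedded, e.g. tRNA-Glu / mt-tRNA-Glu
  m <- regmatches(name, regexpr(paste(three, collapse = "|"), name,
                                ignore.case = TRUE))
  if (length(m) == 1L) {
    return(three[match(tolower(m), tolower(three))])
  }
  # Ensembl mt-T<x>[12] or trn<X> style one-letter code
  m <- regmatches(name, regexec("^(?:mt-T|trn)([A-Za-z])[0-9]?$", name))[[1L]]
  if (length(m) == 2L) {
    hit <- .aa_one_to_three[toupper(m[2L])]
    if (!is.na(hit)) return(unname(hit))
  }
  name
}

#' Load mitochondrial gene annotation from a GTF file
#'
#' Reads gene features from a GTF file (1-based inclusive coordinates) and
#' builds the internal gene model. GTF strand "+" is the heavy (H) strand,
#' i.e. the forward strand of the genome FASTA; "-" is the light (L) strand.
#' Biotypes are collapsed to tRNA / rRNA / protein_coding (the default when
#' the attribute is absent). tRNA gene names are normalized to their
#' amino-acid code via [normalize_trna_name()].
#'
#' Overlapping genes are legal (mitochondrial genomes contain overlapping
#' reading frames, e.g. ATP8/ATP6) and are all retained, in GTF order.
#'
#' @param gtf_path Path to a GTF file restricted to the mitochondrial contig.
#' @param genome A `mito_genome` from [load_genome()].
#' @return An object of class `mito_genes`: list with `genes` (data.frame with
#'   columns gene_name, biotype, strand, start, end) and `genome`.
#' @export
load_annotation <- function(gtf_path, genome) {
  stopifnot(inherits(genome, "mito_genome"))
  if (!file.exists(gtf_path)) stop("GTF file not found: ", gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc)) {
    keep <- as.character(mc$type) == "gene"
    # annotations without explicit gene features: fall back to all rows
    if (!any(keep)) keep <- rep(TRUE, length(gr))
    gr <- gr[keep]
    mc <- S4Vectors::mcols(gr)
  }
  if (length(gr) == 0L) stop("no gene features found in ", gtf_path)
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  if (any(en > genome$length) || any(st < 1L)) {
    stop("gene coordinates exceed genome bounds (genome length ",
         genome$length, ")")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("gene features must have strand '+' or '-'")
  }
  biotype_raw <- if ("gene_biotype" %in% names(mc)) {
    as.character(mc$gene_biotype)
  } else {
    rep(NA_character_, length(gr))
  }
  biotype <- ifelse(grepl("trna", biotype_raw, ignore.case = TRUE), "tRNA",
             ifelse(grepl("rrna", biotype_raw, ignore.case = TRUE), "rRNA",
                    "protein_coding"))
  biotype[is.na(biotype_raw)] <- "protein_coding"
  name <- if ("gene_name" %in% names(mc)) {
    as.character(mc$gene_name)
  } else if ("gene_id" %in% names(mc)) {
    as.character(mc$gene_id)
  } else {
    stop("GTF lacks gene_name/gene_id attributes")
  }
  name <- mapply(normalize_trna_name, name, biotype, USE.NAMES = FALSE)
  genes <- data.frame(
    gene_name = name,
    biotype = biotype,
    strand = ifelse(strand == "+", "H", "L"),
    start = st,
    end = en,
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, genome = genome), class = "mito_genes")
}

#' @export
print.mito_genes <- function(x, ...) {
  cat(sprintf("mito_genes: %d genes on '%s' (%d nt)\n",
              nrow(x$genes), x$genome$name, x$genome$length))
  print(x$genes)
  invisible(x)
}

#' Reverse complement of a DNA sequence
#'
#' @param seq Character vector of DNA sequences over {A,C,G,T,N}.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Extract a genomic subsequence (1-based inclusive, forward strand)
#' @keywords internal
#' @noRd
genome_substr <- function(genome, start, end) {
  substr(genome$sequence, start, end)
}

#' Subset a whole-genome GTF to the mitochondrial contig
#'
#' Convenience pre-processing step for users starting from a full-genome
#' annotation: keeps only lines whose first field equals `contig` (plus
#' comment lines are dropped) and writes them to `out_path`.
#'
#' @param gtf_path Input GTF path.
#' @param contig Mitochondrial contig name (commonly "MT" or "chrM").
#' @param out_path Output GTF path.
#' @return Invisibly, the number of lines written.
#' @export
subset_gtf_to_contig <- function(gtf_path, contig = "MT", out_path) {
  lines <- readLines(gtf_path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- vapply(strsplit(lines, "\t"), `[`, character(1L), 1L)
  keep <- lines[fields == contig]
  writeLines(keep, out_path)
  invisible(length(keep))
}

#' Expected reference file names for built-in species codes
#'
#' Maps KEGG-style species codes to the file names under which the package
#' expects a user-supplied mitochondrial genome FASTA and GTF. No download is
#' performed; references are always provided by the user.
#'
#' @param species Species code (e.g. "hsa", "mmu", "dre", "rno", "gga",
#'   "xla", "xtr").
#' @return Named character vector with elements `fasta` and `gtf`.
#' @export
species_reference_files <- function(species) {
  known <- c("hsa", "mmu", "dre", "rno", "gga", "xla", "xtr")
  species <- tolower(species)
  if (!species %in% known) {
    stop("unknown species code '", species, "'; supply --FASTA/--GTF paths")
  }
  c(fasta = paste0(species, "_mito.fa"), gtf = paste0(species, "_mito.gtf"))
}
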