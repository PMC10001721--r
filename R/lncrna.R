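#' Group long ncRNA sequences sharing a 5' end
#'
#' Mitochondria-derived long non-coding transcripts occur as 3'-end length
#' variants of a common 5' end. In addition to the per-unique-sequence table,
#' counts of sequences sharing strand, orientation and reported 5' start are
#' summed into one group; the group inherits the gene assignment of its
#' anchor and reports the longest member's length as representative.
#'
#' @param annotated Annotated data.frame from [annotate_alignments()]
#'   (lncRNA mode).
#' @param matrix The `mt_counts` the annotation came from (supplies library
#'   names).
#' @return A data.frame with one row per (strand, orientation, start) anchor:
#'   gene, biotype, strand, orientation, start, representative_length,
#'   n_members, then per-library summed counts. Count conservation holds:
#'   column sums equal those of the unique-sequence table.
#' @export
group_by_five_prime <- function(annotated, matrix) {
  stopifnot(inherits(matrix, "mt_counts"))
  libs <- colnames(matrix$counts)
  if (nrow(annotated) == 0L) {
    out <- data.frame(gene = character(0), biotype = character(0),
                      strand = character(0), orientation = character(0),
                      start = integer(0), representative_length = integer(0),
                      n_members = integer(0), stringsAsFactors = FALSE)
    for (l in libs) out[[l]] <- integer(0)
    return(out)
  }
  key <- paste(annotated$strand, annotated$orientation, annotated$start,
               sep = "\r")
  idx <- split(seq_len(nrow(annotated)), key)
  rows <- lapply(idx, function(i) {
    sub <- annotated[i, , drop = FALSE]
    rep_i <- i[which.max(sub$length)]
    sums <- colSums(sub[, libs, drop = FALSE])
    cbind(
      data.frame(gene = annotated$gene[rep_i],
                 biotype = annotated$biotype[rep_i],
                 strand = sub$strand[1L], orientation = sub$orientation[1L],
                 start = sub$start[1L],
                 representative_length = max(sub$length),
                 n_members = length(i), stringsAsFactors = FALSE),
      as.data.frame(as.list(sums), check.names = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter long ncRNAs by minimum length
#'
#' By default the long-ncRNA mode reports every transcript of at least 50 nt,
#' including 50-200 nt mid-size ("intermediate") RNAs. Passing
#' `min_length = 200` restricts the output to strict lncRNAs (> 200 nt
#' families). The filter applies to the sequence length of the unique table
#' or to the representative (longest-member) length of the grouped table;
#' grouping is performed before filtering so that short 3' variants still
#' contribute their counts to a retained anchor.
#'
#' @param x Annotated unique-sequence table (column `length`) or grouped
#'   table (column `representative_length`).
#' @param min_length Minimum length in nt, at least 50.
#' @return The filtered table.
#' @export
apply_length_filter <- function(x, min_length = 50L) {
  if (min_length < 50L) {
    stop("min_length below 50 conflicts with the long-ncRNA mode boundary")
  }
  len <- if ("representative_length" %in% names(x)) {
    x$representative_length
  } else {
    x$length
  }
  out <- x[len >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}
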