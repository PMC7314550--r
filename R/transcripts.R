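#' Transcript model for NMD prediction
#'
#' A minimal exon-structure container in spliced-transcript space: exon
#' lengths ordered 5' to 3' and the CDS interval in transcript (spliced)
#' coordinates. Genomic placement (`chrom`, `tx_start`, `strand`) is kept
#' only so that models can be written as BED12.
#'
#' @param gene gene symbol.
#' @param transcript transcript id.
#' @param chrom contig name.
#' @param strand `"+"` or `"-"`.
#' @param tx_start 1-based genomic start of the transcript.
#' @param exon_lengths integer vector of exon lengths, 5' to 3'.
#' @param cds_start,cds_end CDS interval in 1-based transcript coordinates.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(gene, transcript, chrom = "1", strand = "+",
                             tx_start = 1L, exon_lengths,
                             cds_start, cds_end) {
  exon_lengths <- as.integer(exon_lengths)
  stopifnot(length(exon_lengths) >= 1, all(exon_lengths > 0),
            strand %in% c("+", "-"),
            cds_start >= 1, cds_end >= cds_start,
            cds_end <= sum(exon_lengths))
  structure(list(gene = gene, transcript = transcript, chrom = chrom,
                 strand = strand, tx_start = as.integer(tx_start),
                 exon_lengths = exon_lengths,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("Transcript %s (%s, %s strand): %d exon(s), %d nt, CDS %d-%d\n",
              x$transcript, x$gene, x$strand, length(x$exon_lengths),
              sum(x$exon_lengths), x$cds_start, x$cds_end))
  invisible(x)
}

#' Write transcript models as BED12
#'
#' Exons are laid out contiguously from `tx_start` with 100-bp introns
#' (the synthetic models carry no genomic intron sizes); coordinates are
#' 0-based half-open per BED convention.
#'
#' @param transcripts list of [transcript_model()]s.
#' @param path output file.
#' @export
write_transcripts_bed <- function(transcripts, path) {
  lines <- vapply(transcripts, function(t) {
    n <- length(t$exon_lengths)
    starts <- cumsum(c(0L, head(t$exon_lengths, -1) + 100L))
    chrom_start <- t$tx_start - 1L
    chrom_end <- chrom_start + starts[n] + t$exon_lengths[n]
    paste(t$chrom, chrom_start, chrom_end, t$transcript, 0, t$strand,
          chrom_start, chrom_end, "0,0,0", n,
          paste0(paste(t$exon_lengths, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
}
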