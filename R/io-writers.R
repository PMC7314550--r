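#' Write variant records as TSV
#'
#' The documented TSV dialect of [variant_io]: one row per record,
#' `carriers` comma-separated, numerics printed at full precision so a
#' write/read round trip is lossless.
#'
#' @param records variant record data.frame.
#' @param path output file.
#' @export
write_variants_tsv <- function(records, path) {
  d <- records
  d$carriers <- vapply(records$carriers, paste, character(1), collapse = ",")
  d$maf <- sprintf("%.17g", records$maf)
  d$missing_rate <- sprintf("%.17g", records$missing_rate)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a phenotype table as TSV
#' @param phenotypes phenotype data.frame (see [simulate_cohort()]).
#' @param path output file.
#' @export
write_phenotypes_tsv <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write variant records as a minimal VCF 4.2 with an ANN field
#'
#' Emits one ANN annotation per record
#' (`allele|effect|MODIFIER|gene|gene|transcript|transcript`), a
#' `NONCANON` flag for non-canonical annotations, `MAF=`/`MISS=` INFO
#' fields carrying the record's external frequency and missing rate, and
#' (optionally) per-sample GT columns derived from the carrier lists
#' (heterozygous; ultra-rare carriers are essentially never homozygous).
#'
#' @param records variant record data.frame.
#' @param path output file.
#' @param sample_ids character vector of cohort ids; when non-NULL a GT
#'   column is written for each.
#' @export
write_variants_vcf <- function(records, path, sample_ids = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele|Annotation|Impact|Gene_Name|Gene_ID|Feature_Type|Feature_ID'\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##INFO=<ID=MISS,Number=1,Type=Float,Description=\"Genotype missing rate\">",
    "##INFO=<ID=NONCANON,Number=0,Type=Flag,Description=\"Annotation is not on the canonical transcript\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(sample_ids)) cols <- c(cols, "FORMAT", sample_ids)
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    ann <- sprintf("ANN=%s|%s|MODIFIER|%s|%s|transcript|%s",
                   r$alt, r$effect, r$gene, r$gene, r$transcript)
    info <- paste0(ann, sprintf(";MAF=%.17g;MISS=%.17g",
                                r$maf, r$missing_rate))
    if (!isTRUE(r$canonical)) info <- paste0(info, ";NONCANON")
    fields <- c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", info)
    if (!is.null(sample_ids)) {
      gt <- ifelse(sample_ids %in% records$carriers[[i]], "0/1", "0/0")
      fields <- c(fields, "GT", gt)
    }
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(c(header, paste(cols, collapse = "\t"), body), path)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `phenotypes.tsv`, `burden.tsv` (long format: id, bin, count),
#' `variants.tsv`, `variants.vcf` and `transcripts.bed`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param vcf_genotypes write per-sample GT columns into the VCF (can be
#'   large for big cohorts).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, vcf_genotypes = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phenotypes_tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  b <- cohort$burden
  long <- data.frame(id = rep(rownames(b), times = ncol(b)),
                     bin = rep(colnames(b), each = nrow(b)),
                     count = as.vector(b))
  write.table(long, file.path(dir, "burden.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$variants)) {
    write_variants_tsv(cohort$variants, file.path(dir, "variants.tsv"))
    write_variants_vcf(cohort$variants, file.path(dir, "variants.vcf"),
                       sample_ids = if (vcf_genotypes)
                         cohort$phenotypes$id else NULL)
    write_transcripts_bed(cohort$transcripts,
                          file.path(dir, "transcripts.bed"))
  }
  invisible(dir)
}
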