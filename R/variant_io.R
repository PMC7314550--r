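#' @name variant_io
#' @title Reading, filtering and classifying annotated variants
#' @description Variant records are plain data.frames with one row per
#' (site, alt allele, canonical transcript): columns `chrom`, `pos`,
#' `ref`, `alt`, `gene`, `transcript`, `canonical` (logical), `effect`
#' (annotation terms, `&`-separated when a variant has several), `maf`,
#' `missing_rate`, optional `cds_pos` (CDS coordinate of a stop gain) and
#' `carriers` (list column of individual ids carrying at least one
#' alternate allele).
NULL

PTV_TERMS <- c("stop_gained", "frameshift_variant",
               "splice_donor_variant", "splice_acceptor_variant")

EFFECT_CATEGORIES <- c(
  stop_gained = "stop_gained",
  frameshift_variant = "frameshift",
  splice_donor_variant = "splice_donor",
  splice_acceptor_variant = "splice_acceptor",
  synonymous_variant = "synonymous",
  "3_prime_UTR_variant" = "utr3",
  "5_prime_UTR_variant" = "utr5",
  TF_binding_site_variant = "tf_binding",
  structural_interaction_variant = "structural_interaction"
)

variant_columns <- c("chrom", "pos", "ref", "alt", "gene", "transcript",
                     "canonical", "effect", "maf", "missing_rate")

#' Compute the (folded) minor allele frequency from genotypes
#'
#' @param genotypes integer vector of alternate-allele dosages in
#'   `{0, 1, 2, NA}` (NA = missing genotype).
#' @return alternate-allele count over twice the number of non-missing
#'   genotypes, folded to the minor allele (always `<= 0.5`).
#' @export
compute_maf <- function(genotypes) {
  ok <- !is.na(genotypes)
  if (!any(ok)) stop("all genotypes missing")
  if (!all(genotypes[ok] %in% 0:2)) stop("genotypes must be 0, 1, 2 or NA")
  af <- sum(genotypes[ok]) / (2 * sum(ok))
  min(af, 1 - af)
}

#' Classify annotation terms into an effect category
#'
#' A variant is a protein-truncating variant (PTV) iff any of the four
#' truncating terms (stop gain, frameshift, splice donor/acceptor
#' disruption) is annotated on a canonical transcript. Synonymous
#' variants are flagged as the neutral control category.
#'
#' @param effect_terms character vector of annotation terms (one variant).
#' @param canonical logical; is the annotated transcript canonical?
#' @return list with `category` (one of `stop_gained`, `frameshift`,
#'   `splice_donor`, `splice_acceptor`, `synonymous`, `utr3`, `utr5`,
#'   `tf_binding`, `structural_interaction`, `other`) and `is_ptv`.
#' @export
classify_effect <- function(effect_terms, canonical = TRUE) {
  if (length(effect_terms) == 0 || all(!nzchar(effect_terms)))
    stop("empty effect term set")
  ## PTV terms take precedence, in decreasing severity order
  hit <- PTV_TERMS[PTV_TERMS %in% effect_terms]
  if (length(hit) > 0) {
    return(list(category = unname(EFFECT_CATEGORIES[hit[1]]),
                is_ptv = isTRUE(canonical)))
  }
  known <- intersect(names(EFFECT_CATEGORIES), effect_terms)
  category <- if (length(known) > 0) unname(EFFECT_CATEGORIES[known[1]])
              else "other"
  list(category = category, is_ptv = FALSE)
}

## Vectorised helpers over a record data.frame.
record_terms <- function(records) strsplit(records$effect, "&", fixed = TRUE)

#' Per-record PTV flag and effect category
#' @param records variant record data.frame (see [variant_io]).
#' @return `is_ptv()`: logical vector; `effect_category()`: character
#'   vector of categories.
#' @export
is_ptv <- function(records) {
  terms <- record_terms(records)
  mapply(function(tt, can) classify_effect(tt, can)$is_ptv,
         terms, records$canonical, USE.NAMES = FALSE)
}

#' @rdname is_ptv
#' @export
effect_category <- function(records) {
  terms <- record_terms(records)
  mapply(function(tt, can) classify_effect(tt, can)$category,
         terms, records$canonical, USE.NAMES = FALSE)
}

#' Assign a MAF to one of the four frequency bins
#'
#' Bins are the half-open intervals `[0, 1e-4)`, `[1e-4, 1e-3)`,
#' `[1e-3, 1e-2)` and `[1e-2, 0.2)`; a boundary value belongs to the
#' upper bin. Bin 1 is the ultra-rare class.
#'
#' @param maf numeric vector, `0 <= maf < 0.2`.
#' @return integer vector of bin indices (1-4).
#' @export
assign_maf_bin <- function(maf) {
  if (any(is.na(maf)) || any(maf < 0) || any(maf >= 0.2))
    stop("MAF must lie in [0, 0.2); filter first")
  findInterval(maf, maf_bin_breaks())
}

#' Apply the site-level filters
#'
#' Drops, in this order of reported reason: non-autosomal sites, sites
#' with genotype missing rate >= 10%, sites with MAF >= 0.2, and
#' monomorphic sites (folded MAF 0). Filtering is idempotent and
#' order-independent.
#'
#' @param records variant record data.frame.
#' @param max_missing maximum tolerated missing rate (exclusive bound).
#' @param max_maf maximum tolerated MAF (exclusive bound).
#' @return list with `variants` (retained records) and `log`, a
#'   data.frame of excluded row indices and reasons; `table(log$reason)`
#'   gives counts per reason.
#' @export
filter_variants <- function(records, max_missing = 0.10, max_maf = 0.2) {
  reason <- rep(NA_character_, nrow(records))
  autosome <- sub("^chr", "", records$chrom) %in% as.character(1:22)
  reason[!autosome] <- "non_autosomal"
  miss <- is.na(reason) & records$missing_rate >= max_missing
  reason[miss] <- "missing_rate"
  freq <- is.na(reason) & records$maf >= max_maf
  reason[freq] <- "frequency"
  mono <- is.na(reason) & records$maf == 0
  reason[mono] <- "monomorphic"
  keep <- is.na(reason)
  list(variants = records[keep, , drop = FALSE],
       log = data.frame(row = which(!keep),
                        reason = reason[!keep],
                        stringsAsFactors = FALSE))
}

#' Read annotated variants from TSV or VCF
#'
#' The TSV dialect has the columns documented in [variant_io] with
#' `carriers` comma-separated; malformed rows (missing fields,
#' non-numeric MAF or position) are dropped with a warning naming the
#' line numbers. VCF input must be VCF 4.2 with an ANN-style INFO
#' annotation field (`effect` terms `&`-separated inside each
#' annotation); genotype columns, when present, supply the carrier sets
#' and internal MAF.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return variant record data.frame.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  switch(format, tsv = read_variants_tsv(path), vcf = read_variants_vcf(path))
}

read_variants_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(variant_columns, names(d))
  if (length(missing_cols) > 0)
    stop("missing annotation columns: ", paste(missing_cols, collapse = ", "))
  pos <- suppressWarnings(as.integer(d$pos))
  maf <- suppressWarnings(as.numeric(d$maf))
  miss <- suppressWarnings(as.numeric(d$missing_rate))
  bad <- is.na(pos) | is.na(maf) | is.na(miss) | !nzchar(d$effect) |
    !nzchar(d$gene)
  if (any(bad)) {
    warning(sprintf("dropping %d malformed row(s) at line(s) %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")))
  }
  cds <- if ("cds_pos" %in% names(d))
    suppressWarnings(as.integer(d$cds_pos)) else rep(NA_integer_, nrow(d))
  d <- d[!bad, , drop = FALSE]
  out <- data.frame(
    chrom = d$chrom, pos = pos[!bad], ref = d$ref, alt = d$alt,
    gene = d$gene, transcript = d$transcript,
    canonical = d$canonical %in% c("TRUE", "1", "true"),
    effect = d$effect, maf = maf[!bad], missing_rate = miss[!bad],
    cds_pos = cds[!bad],
    stringsAsFactors = FALSE
  )
  out$carriers <- I(lapply(
    if ("carriers" %in% names(d)) d$carriers else rep("", nrow(d)),
    function(s) if (nzchar(s)) strsplit(s, ",", fixed = TRUE)[[1]]
                else character(0)))
  rownames(out) <- NULL
  out
}

## Parse one ANN INFO entry (SnpEff-style pipe-separated subfields):
## Allele|Annotation|Impact|Gene_Name|Gene_ID|Feature_Type|Feature_ID|...
parse_ann <- function(ann) {
  fields <- strsplit(ann, "|", fixed = TRUE)[[1]]
  if (length(fields) < 7) return(NULL)
  list(allele = fields[1], effect = fields[2], gene = fields[4],
       transcript = fields[7])
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info <- vcfR::getINFO(vcf)
  n <- nrow(fix)
  has_gt <- ncol(vcf@gt) > 1
  gt_dose <- NULL
  if (has_gt) {
    gtm <- vcfR::extract.gt(vcf, element = "GT")
    gt_dose <- matrix(NA_integer_, nrow = n, ncol = ncol(gtm),
                      dimnames = dimnames(gtm))
    clean <- gsub("|", "/", gtm, fixed = TRUE)
    gt_dose[clean == "0/0"] <- 0L
    gt_dose[clean %in% c("0/1", "1/0")] <- 1L
    gt_dose[clean == "1/1"] <- 2L
  }
  rows <- vector("list", n)
  bad <- integer(0)
  for (i in seq_len(n)) {
    kv <- strsplit(info[i], ";", fixed = TRUE)[[1]]
    ann_raw <- sub("^ANN=", "", grep("^ANN=", kv, value = TRUE))
    ann <- if (length(ann_raw) == 1) parse_ann(strsplit(
      ann_raw, ",", fixed = TRUE)[[1]][1]) else NULL
    if (is.null(ann)) { bad <- c(bad, i); next }
    maf_ext <- sub("^MAF=", "", grep("^MAF=", kv, value = TRUE))
    miss_ext <- sub("^MISS=", "", grep("^MISS=", kv, value = TRUE))
    canon <- !any(kv == "NONCANON")
    if (has_gt) {
      g <- gt_dose[i, ]
      maf <- compute_maf(g)
      missing_rate <- mean(is.na(g))
      carriers <- names(g)[!is.na(g) & g > 0]
    } else {
      maf <- if (length(maf_ext) == 1) as.numeric(maf_ext) else NA_real_
      missing_rate <- if (length(miss_ext) == 1) as.numeric(miss_ext) else 0
      carriers <- character(0)
    }
    if (length(maf_ext) == 1 && !has_gt) maf <- as.numeric(maf_ext)
    rows[[i]] <- list(chrom = fix[i, "CHROM"],
                      pos = as.integer(fix[i, "POS"]),
                      ref = fix[i, "REF"], alt = fix[i, "ALT"],
                      gene = ann$gene, transcript = ann$transcript,
                      canonical = canon, effect = ann$effect,
                      maf = maf, missing_rate = missing_rate,
                      carriers = carriers)
  }
  if (length(bad) > 0)
    warning(sprintf("dropping %d VCF record(s) without a parseable ANN field",
                    length(bad)))
  rows <- rows[lengths(rows) > 0]
  out <- data.frame(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    pos = vapply(rows, `[[`, integer(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    gene = vapply(rows, `[[`, character(1), "gene"),
    transcript = vapply(rows, `[[`, character(1), "transcript"),
    canonical = vapply(rows, `[[`, logical(1), "canonical"),
    effect = vapply(rows, `[[`, character(1), "effect"),
    maf = vapply(rows, `[[`, numeric(1), "maf"),
    missing_rate = vapply(rows, `[[`, numeric(1), "missing_rate"),
    cds_pos = NA_integer_,
    stringsAsFactors = FALSE
  )
  out$carriers <- I(lapply(rows, `[[`, "carriers"))
  out
}
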