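#' Per-individual variant burden by MAF bin
#'
#' Counts, for every individual, the number of qualifying variant sites
#' at which the individual carries at least one alternate allele
#' (`mode = "site"`, the default: het or hom counts once) or the summed
#' allele dosage (`mode = "dosage"`). Qualifying sites are selected by
#' effect category and MAF bin; records should already have passed
#' [filter_variants()].
#'
#' @param records variant record data.frame with `carriers` list column;
#'   for dosage mode an optional `hom_carriers` list column marks
#'   homozygous carriers (absent means all carriers heterozygous).
#' @param individuals character vector of cohort ids (defines rows; an
#'   error is raised if a carrier id is not in the cohort).
#' @param category `"ptv"` (the four truncating classes on canonical
#'   transcripts), `"synonymous"`, `"all"`, or one of the effect category
#'   names returned by [effect_category()].
#' @param bins integer vector of MAF bins to tabulate (default all four).
#' @param mode `"site"` or `"dosage"`.
#' @return integer matrix individuals x bins with `counting_mode` and
#'   `category` attributes. Column sums equal per-variant carrier counts.
#' @export
compute_burden <- function(records, individuals,
                           category = "ptv", bins = 1:4,
                           mode = c("site", "dosage")) {
  mode <- match.arg(mode)
  stopifnot(length(individuals) > 0, !anyDuplicated(individuals))
  qual <- switch(category,
    ptv = is_ptv(records),
    all = rep(TRUE, nrow(records)),
    effect_category(records) == category
  )
  bin <- assign_maf_bin(records$maf)
  m <- matrix(0L, nrow = length(individuals), ncol = length(bins),
              dimnames = list(individuals, maf_bin_labels()[bins]))
  for (i in which(qual & bin %in% bins)) {
    ids <- records$carriers[[i]]
    if (length(ids) == 0) next
    unknown <- setdiff(ids, individuals)
    if (length(unknown) > 0)
      stop("carrier id(s) not in cohort: ",
           paste(head(unknown, 5), collapse = ", "))
    j <- match(bin[i], bins)
    add <- rep(1L, length(ids))
    if (mode == "dosage" && !is.null(records$hom_carriers))
      add <- add + as.integer(ids %in% records$hom_carriers[[i]])
    m[ids, j] <- m[ids, j] + add
  }
  attr(m, "counting_mode") <- mode
  attr(m, "category") <- category
  m
}

#' Stratify individuals into burden groups
#'
#' Groups by ultra-rare PTV count: 1 = 0-3, 2 = 4-5, 3 = 6-7, 4 = 8-9,
#' 5 = 10 or more.
#'
#' @param counts non-negative integer vector of ultra-rare PTV counts.
#' @return integer vector of group labels in 1..5.
#' @export
stratify_by_burden <- function(counts) {
  if (any(counts < 0)) stop("burden counts must be non-negative")
  findInterval(counts, c(0, 4, 6, 8, 10))
}
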