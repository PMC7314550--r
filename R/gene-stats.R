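#' Per-gene PTV counts for the constraint test
#'
#' Tallies ultra-rare stop gains and frameshifts (splice-site variants
#' excluded: their per-gene count scales with intron number, not
#' constraint) and synonymous variants at all frequencies.
#'
#' @param records filtered variant record data.frame.
#' @param genes gene universe; defaults to the genes present in
#'   `records`.
#' @return data.frame with `gene`, `n_ptv`, `n_syn`.
#' @export
gene_counts <- function(records, genes = NULL) {
  cat_ <- effect_category(records)
  ur <- assign_maf_bin(records$maf) == 1L
  is_ptv_count <- ur & records$canonical &
    cat_ %in% c("stop_gained", "frameshift")
  is_syn <- cat_ == "synonymous"
  if (is.null(genes)) genes <- sort(unique(records$gene))
  data.frame(
    gene = genes,
    n_ptv = as.integer(table(factor(records$gene[is_ptv_count],
                                    levels = genes))),
    n_syn = as.integer(table(factor(records$gene[is_syn],
                                    levels = genes))),
    stringsAsFactors = FALSE
  )
}

#' Gene constraint test: ultra-rare PTVs versus synonymous background
#'
#' For each gene, a 2x2 Fisher exact test compares the gene's ultra-rare
#' PTV and synonymous counts against those of the rest of the genome.
#' Genes with Bonferroni-adjusted `p < alpha` are labeled `intolerant`
#' (odds ratio < 1: disproportionately few ultra-rare PTVs) or `prone`
#' (odds ratio > 1); all others are `neutral`.
#'
#' @param counts data.frame from [gene_counts()] (`gene`, `n_ptv`,
#'   `n_syn`).
#' @param alpha significance level after Bonferroni adjustment.
#' @return data.frame with `gene`, `n_ptv`, `n_syn`, `odds_ratio`, `p`,
#'   `p_adj`, `label`.
#' @export
constraint_test <- function(counts, alpha = 0.05) {
  total_ptv <- sum(counts$n_ptv)
  total_syn <- sum(counts$n_syn)
  if (total_syn == 0)
    stop("zero synonymous variants overall: cannot normalize")
  res <- lapply(seq_len(nrow(counts)), function(i) {
    tab <- matrix(c(counts$n_ptv[i], total_ptv - counts$n_ptv[i],
                    counts$n_syn[i], total_syn - counts$n_syn[i]),
                  nrow = 2, byrow = TRUE)
    ft <- fisher.test(tab)
    c(or = unname(ft$estimate), p = ft$p.value)
  })
  or <- vapply(res, `[[`, numeric(1), "or")
  p <- vapply(res, `[[`, numeric(1), "p")
  p_adj <- p.adjust(p, method = "bonferroni")
  label <- rep("neutral", nrow(counts))
  label[p_adj < alpha & or < 1] <- "intolerant"
  label[p_adj < alpha & or > 1] <- "prone"
  cbind(counts,
        data.frame(odds_ratio = or, p = p, p_adj = p_adj, label = label,
                   stringsAsFactors = FALSE))
}

#' Split-cohort gene burden test
#'
#' Orders individuals by a survival phenotype, splits them into two
#' equal halves (stable sort by phenotype then id; the first half takes
#' the extra individual when the cohort size is odd), counts the unique
#' carriers of each gene's ultra-rare PTVs in each half, and tests the
#' imbalance per gene with a two-sided Fisher exact test against the
#' total carrier counts of the two halves. Benjamini-Hochberg q-values
#' are reported.
#'
#' @param gene_carriers named list: for each gene, the character vector
#'   of ids of individuals carrying at least one ultra-rare PTV in the
#'   gene (individuals counted once per gene).
#' @param phenotype numeric vector of lifespan/healthspan values.
#' @param ids individual ids aligned with `phenotype`.
#' @return data.frame with `gene`, `carriers_low`, `carriers_high`
#'   (counts in the short- and long-lived halves), `p` and `q`
#'   (BH-adjusted), one row per gene with at least one carrier.
#' @export
gene_burden_test <- function(gene_carriers, phenotype, ids) {
  stopifnot(length(phenotype) == length(ids), !anyDuplicated(ids))
  ord <- order(phenotype, ids)
  n <- length(ids)
  half <- ceiling(n / 2)
  low <- ids[ord][seq_len(half)]            # shorter-lived half
  counts <- lapply(gene_carriers, function(carr) {
    carr <- unique(carr)
    unknown <- setdiff(carr, ids)
    if (length(unknown) > 0)
      stop("carrier id(s) not in cohort: ",
           paste(head(unknown, 5), collapse = ", "))
    c(low = sum(carr %in% low), high = sum(!(carr %in% low)))
  })
  keep <- vapply(counts, sum, numeric(1)) > 0
  counts <- counts[keep]
  if (length(counts) == 0)
    return(data.frame(gene = character(0), carriers_low = integer(0),
                      carriers_high = integer(0), p = numeric(0),
                      q = numeric(0)))
  tot_low <- sum(vapply(counts, `[[`, numeric(1), "low"))
  tot_high <- sum(vapply(counts, `[[`, numeric(1), "high"))
  p <- vapply(counts, function(ct) {
    tab <- matrix(c(ct["low"], ct["high"],
                    tot_low - ct["low"], tot_high - ct["high"]),
                  nrow = 2, byrow = TRUE)
    fisher.test(tab)$p.value
  }, numeric(1))
  data.frame(gene = names(counts),
             carriers_low = vapply(counts, `[[`, numeric(1), "low"),
             carriers_high = vapply(counts, `[[`, numeric(1), "high"),
             p = unname(p), q = unname(p.adjust(p, method = "BH")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Predict nonsense-mediated decay by the 50-bp rule
#'
#' A premature stop triggers NMD iff it lies more than 50 nt upstream of
#' the last exon-exon junction in spliced-transcript coordinates; stops
#' in the last exon, or within 50 nt of the final junction, escape.
#' Single-exon transcripts have no junction and never trigger NMD.
#'
#' @param stop_pos 1-based position of the premature stop in
#'   spliced-transcript coordinates; must lie within the CDS.
#' @param transcript a [transcript_model()].
#' @return logical: does the stop trigger NMD?
#' @export
nmd_predict <- function(stop_pos, transcript) {
  stopifnot(inherits(transcript, "transcript_model"))
  if (stop_pos < transcript$cds_start || stop_pos > transcript$cds_end)
    stop("stop position outside the CDS")
  n_exons <- length(transcript$exon_lengths)
  if (n_exons == 1) return(FALSE)
  last_junction <- sum(transcript$exon_lengths) -
    transcript$exon_lengths[n_exons]
  (last_junction - stop_pos) > 50
}

#' Expression breadth from a tissue TPM vector
#'
#' Fraction of tissues in which the gene is expressed (TPM > 10).
#'
#' @param tpm non-negative numeric vector, one entry per tissue.
#' @return fraction in `[0, 1]`.
#' @export
expression_breadth <- function(tpm) {
  if (length(tpm) == 0) stop("empty TPM vector")
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  mean(tpm > 10)
}

#' Genes intolerant to ultra-rare PTVs (iPTV set)
#'
#' The genes of the universe in which no ultra-rare PTV is observed.
#'
#' @param records filtered variant record data.frame.
#' @param universe character vector of genes under consideration.
#' @return character vector (sorted).
#' @export
iptv_genes <- function(records, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  hit <- unique(records$gene[is_ptv(records) &
                               assign_maf_bin(records$maf) == 1L])
  sort(setdiff(universe, hit))
}

#' Compare a gene-annotation metric between two gene groups
#'
#' Two-sided comparison of a constraint/expression metric (oe, pLI,
#' GHIS, indispensability, dN/dS, expression breadth, ...) between two
#' groups of genes, with the test used in the corresponding published
#' comparison: Wilcoxon rank-sum, Student t, or Fisher exact (for
#' binary metrics such as predicted LoF / NMD status).
#'
#' @param values numeric (or 0/1 for `test = "fisher"`) metric values.
#' @param group two-level group labels aligned with `values`.
#' @param test `"wilcoxon"`, `"t"` or `"fisher"`.
#' @return list with `statistic`, `p` and the group summary.
#' @export
compare_gene_groups <- function(values, group,
                                test = c("wilcoxon", "t", "fisher")) {
  test <- match.arg(test)
  group <- factor(as.character(group))
  stopifnot(length(values) == length(group), nlevels(group) == 2)
  a <- values[group == levels(group)[1]]
  b <- values[group == levels(group)[2]]
  if (test %in% c("wilcoxon", "t") && (length(a) < 2 || length(b) < 2))
    stop("each group needs at least 2 observations")
  res <- switch(test,
    wilcoxon = {
      w <- suppressWarnings(wilcox.test(a, b))
      list(statistic = unname(w$statistic), p = w$p.value)
    },
    t = {
      tt <- t.test(a, b)
      list(statistic = unname(tt$statistic), p = tt$p.value)
    },
    fisher = {
      stopifnot(all(values %in% 0:1))
      ft <- fisher.test(table(group, factor(values, levels = 0:1)))
      list(statistic = unname(ft$estimate), p = ft$p.value)
    })
  res$summary <- data.frame(
    group = levels(group), n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)))
  res
}
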