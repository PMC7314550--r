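#' Simulation configuration for synthetic exome-cohort data
#'
#' Bundles every parameter of the synthetic cohort generator. Defaults
#' reproduce the statistical structure of a large biobank exome study:
#' about 6 ultra-rare PTVs per genome (SD 2.6), Gompertz log-hazard slope
#' 0.09/yr for both mortality and first-disease incidence, burden
#' log-hazard effects of 0.046 (lifespan) and 0.014 (healthspan) per
#' mutation, enrollment between ages 40 and 70, and an 11-year follow-up.
#'
#' @param n_individuals number of individuals in the cohort.
#' @param burden_mean expected number of ultra-rare PTVs per genome.
#' @param burden_dispersion variance/mean ratio of the ultra-rare burden
#'   distribution; 1 gives a Poisson, the default `2.6^2 / 6` matches an
#'   SD of 2.6 at mean 6.
#' @param gompertz_slope per-year log-hazard slope (Gamma) shared by the
#'   mortality and morbidity processes.
#' @param h0_lifespan baseline mortality hazard per year at age 0.
#' @param h0_morbidity baseline first-disease hazard per year at age 0.
#' @param beta_burden_lifespan,beta_burden_healthspan log-hazard increase
#'   per ultra-rare PTV for death and for first chronic disease.
#' @param beta_sex_lifespan,beta_sex_healthspan log-hazard for male vs
#'   female.
#' @param male_fraction probability that a simulated individual is male.
#' @param assessment_age_range length-2 numeric, uniform enrollment ages.
#' @param followup_years length of the follow-up window in years.
#' @param n_genes,n_variants size of the simulated variant universe.
#' @param iptv_fraction fraction of genes kept free of ultra-rare PTVs.
#' @param bin_burden_means expected per-individual PTV counts in the four
#'   MAF bins; the first (ultra-rare) entry is `burden_mean`.
#' @param maf_bin_probs sampling probabilities of the four MAF bins for
#'   simulated variant sites.
#' @param parent_h0 baseline mortality hazard for simulated parents.
#' @param parent_burden_weight weight of the child's burden in the
#'   parent's linear predictor (Mendelian transmission stand-in).
#' @param parent_age_gap mean parent-child age difference in years.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#'
#' @return an object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_individuals = 1000,
                       burden_mean = 6,
                       burden_dispersion = 2.6^2 / 6,
                       gompertz_slope = 0.09,
                       h0_lifespan = 5e-6,
                       h0_morbidity = 6e-5,
                       beta_burden_lifespan = 0.046,
                       beta_burden_healthspan = 0.014,
                       beta_sex_lifespan = 0.47,
                       beta_sex_healthspan = 0.16,
                       male_fraction = 0.54,
                       assessment_age_range = c(40, 70),
                       followup_years = 11,
                       n_genes = 200,
                       n_variants = 2000,
                       iptv_fraction = 0.10,
                       bin_burden_means = c(burden_mean, 3, 5, 15),
                       maf_bin_probs = c(0.55, 0.20, 0.15, 0.10),
                       parent_h0 = 5e-5,
                       parent_burden_weight = 0.5,
                       parent_age_gap = 28,
                       seed = NULL) {
  stopifnot(n_individuals >= 1, burden_mean >= 0, burden_dispersion >= 1,
            gompertz_slope >= 0, h0_lifespan > 0, h0_morbidity > 0,
            followup_years > 0, length(assessment_age_range) == 2,
            assessment_age_range[1] < assessment_age_range[2],
            n_genes >= 1, n_variants >= n_genes,
            iptv_fraction >= 0, iptv_fraction < 1,
            length(bin_burden_means) == 4, all(bin_burden_means >= 0),
            length(maf_bin_probs) == 4, all(maf_bin_probs > 0),
            parent_burden_weight >= 0, parent_burden_weight <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  individuals: %d, genes: %d, variants: %d\n",
              x$n_individuals, x$n_genes, x$n_variants))
  cat(sprintf("  ultra-rare burden: mean %.3g, dispersion %.3g (SD %.3g)\n",
              x$burden_mean, x$burden_dispersion,
              sqrt(x$burden_mean * x$burden_dispersion)))
  cat(sprintf("  Gompertz slope: %.3g /yr; h0 lifespan %.3g, morbidity %.3g\n",
              x$gompertz_slope, x$h0_lifespan, x$h0_morbidity))
  cat(sprintf("  beta burden: %.3g (lifespan), %.3g (healthspan)\n",
              x$beta_burden_lifespan, x$beta_burden_healthspan))
  invisible(x)
}

## Draw counts with a given mean and variance/mean ratio.
## dispersion == 1 is the Poisson limit; mean 0 is degenerate at 0.
rcount <- function(n, mean, dispersion = 1) {
  if (mean < 0) stop("count mean must be non-negative")
  if (mean == 0) return(integer(n))
  if (dispersion < 1) stop("variance/mean ratio below 1 is not supported")
  if (dispersion == 1) return(rpois(n, mean))
  size <- mean / (dispersion - 1)
  rnbinom(n, size = size, mu = mean)
}

#' Simulate per-individual germline PTV counts by MAF bin
#'
#' The ultra-rare bin uses a negative-binomial with the configured mean
#' and variance/mean ratio (Poisson when the ratio is 1); the remaining
#' bins use Poisson counts at their configured means.
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed`; `NA` leaves the RNG
#'   state untouched (used internally by [simulate_cohort()]).
#' @return integer matrix `n_individuals x 4`, columns named by MAF bin.
#' @export
simulate_burdens <- function(config, seed = config$seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  n <- config$n_individuals
  m <- cbind(
    rcount(n, config$bin_burden_means[1], config$burden_dispersion),
    rcount(n, config$bin_burden_means[2]),
    rcount(n, config$bin_burden_means[3]),
    rcount(n, config$bin_burden_means[4])
  )
  colnames(m) <- maf_bin_labels()
  rownames(m) <- sprintf("I%05d", seq_len(n))
  m
}

## Inverse-transform sample of a Gompertz proportional-hazards event time:
## h(t) = h0 * exp(Gamma * t + linpred). Gamma == 0 falls back to the
## exponential limit h(t) = h0 * exp(linpred).
## `min_age` conditions the draw on survival to that age (T > min_age).
gompertz_event_times <- function(n, h0, gamma, linpred = 0, min_age = 0) {
  if (h0 <= 0) stop("baseline hazard must be positive")
  if (gamma < 0) stop("negative Gompertz slope is not supported")
  rate <- h0 * exp(linpred)
  u <- runif(n)
  if (gamma == 0) return(min_age - log(u) / rate)
  log(exp(gamma * min_age) - gamma * log(u) / rate) / gamma
}

#' Simulate event ages under a Gompertz proportional-hazards model
#'
#' Draws age at death (`phenotype = "lifespan"`) or age at first chronic
#' disease (`phenotype = "healthspan"`) from the hazard
#' `h(t) = h0 exp(Gamma t + beta_burden n + beta_sex s)` by inverse
#' transform. A zero Gompertz slope uses the exponential limit.
#'
#' @param config a [sim_config()].
#' @param burdens integer vector of ultra-rare PTV counts.
#' @param sexes integer vector, 1 = male, 0 = female.
#' @param phenotype `"lifespan"` or `"healthspan"`; selects the baseline
#'   hazard and burden/sex coefficients from `config`.
#' @param seed optional seed (see [simulate_burdens()]).
#' @return numeric vector of event ages in years.
#' @export
simulate_event_ages <- function(config, burdens, sexes,
                                phenotype = c("lifespan", "healthspan"),
                                seed = config$seed) {
  phenotype <- match.arg(phenotype)
  stopifnot(length(burdens) == length(sexes))
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  if (phenotype == "lifespan") {
    lp <- config$beta_burden_lifespan * burdens +
      config$beta_sex_lifespan * sexes
    h0 <- config$h0_lifespan
  } else {
    lp <- config$beta_burden_healthspan * burdens +
      config$beta_sex_healthspan * sexes
    h0 <- config$h0_morbidity
  }
  gompertz_event_times(length(burdens), h0, config$gompertz_slope, lp)
}

#' Apply the enrollment and follow-up censoring scheme
#'
#' Assessment ages are uniform over the configured range. Enrollment
#' requires being alive at assessment: death ages at or before the drawn
#' assessment age are redrawn from the conditional event-time distribution
#' given survival to assessment (the exact limit of rejection resampling).
#' The event is observed iff it falls inside the follow-up window.
#'
#' @param config a [sim_config()].
#' @param event_ages numeric vector of simulated death ages.
#' @param linpred linear predictor used for the conditional redraw
#'   (burden/sex terms); scalar or per-individual vector.
#' @param seed optional seed (see [simulate_burdens()]).
#' @return data.frame with `age_at_assessment`, `event_age` (after any
#'   conditional redraw), `time` (years on the follow-up scale) and
#'   `event` (1 = died within follow-up).
#' @export
simulate_followup <- function(config, event_ages, linpred = 0,
                              seed = config$seed) {
  n <- length(event_ages)
  if (n == 0L) stop("empty cohort")
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  linpred <- rep_len(linpred, n)
  assess <- runif(n, config$assessment_age_range[1],
                  config$assessment_age_range[2])
  dead_before <- event_ages <= assess
  if (any(dead_before)) {
    event_ages[dead_before] <- gompertz_event_times(
      sum(dead_before), config$h0_lifespan, config$gompertz_slope,
      linpred[dead_before], min_age = assess[dead_before])
  }
  event <- as.integer(event_ages <= assess + config$followup_years)
  time <- pmin(event_ages - assess, config$followup_years)
  data.frame(age_at_assessment = assess, event_age = event_ages,
             time = time, event = event)
}

## MAF bin machinery shared with the variant_io module.
maf_bin_breaks <- function() c(0, 1e-4, 1e-3, 1e-2, 0.2)

#' Labels of the four MAF bins
#'
#' Half-open intervals partitioning `[0, 0.2)`; boundaries belong to the
#' upper bin.
#' @return character vector of length 4.
#' @export
maf_bin_labels <- function() {
  b <- maf_bin_breaks()
  sprintf("[%g,%g)", b[-5], b[-1])
}

## Sample a MAF log-uniformly within a bin.
rmaf_in_bin <- function(n, bin) {
  b <- maf_bin_breaks()
  lo <- pmax(b[bin], 1e-6)
  hi <- b[bin + 1]
  exp(runif(n, log(lo), log(hi)))
}

## Distinct carrier individuals for an allele count drawn at a given MAF:
## allele count ~ Binomial(2N, maf), alleles placed on random chromosomes.
sample_carriers <- function(maf, n_individuals, ids) {
  k <- rbinom(1, 2 * n_individuals, maf)
  if (k == 0) return(character(0))
  chrom <- sample.int(2 * n_individuals, k)
  sort(ids[unique((chrom + 1L) %/% 2L)])
}

simulate_transcripts <- function(config) {
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  n_exons <- sample(1:8, config$n_genes, replace = TRUE)
  lapply(seq_len(config$n_genes), function(i) {
    exon_lengths <- pmax(60L, as.integer(round(rnorm(n_exons[i], 180, 60))))
    total <- sum(exon_lengths)
    cds_start <- min(50L, max(1L, total %/% 10L))
    cds_end <- total - min(30L, total %/% 10L)
    transcript_model(gene = genes[i],
                     transcript = sprintf("T%04d.1", i),
                     chrom = as.character(sample(1:22, 1)),
                     strand = sample(c("+", "-"), 1),
                     tx_start = sample.int(1e6, 1),
                     exon_lengths = exon_lengths,
                     cds_start = cds_start, cds_end = cds_end)
  })
}

#' Simulate an annotated variant table with carriers and transcripts
#'
#' Variants are assigned to genes, effect categories (including a
#' synonymous background and non-coding classes), and MAFs spanning the
#' four frequency bins; carriers are drawn binomially at each site's MAF.
#' Genes reserved as PTV-free (`iptv_fraction`) receive no ultra-rare
#' PTVs, so they surface downstream as the iPTV set. Stop-gain variants
#' carry CDS positions on their transcript for NMD prediction.
#'
#' @param config a [sim_config()].
#' @param seed optional seed (see [simulate_burdens()]).
#' @return list with `variants` (data.frame; `carriers` is a list column
#'   of individual ids), `transcripts` (list of [transcript_model()]s) and
#'   `iptv_truth` (character vector of the PTV-free genes).
#' @export
simulate_variant_table <- function(config, seed = config$seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  if (config$n_variants < config$n_genes)
    stop("need at least one variant per gene")
  n <- config$n_variants
  transcripts <- simulate_transcripts(config)
  genes <- vapply(transcripts, function(t) t$gene, character(1))
  chroms <- vapply(transcripts, function(t) t$chrom, character(1))
  ids <- sprintf("I%05d", seq_len(config$n_individuals))

  effects <- sample(c("stop_gained", "frameshift_variant",
                      "splice_donor_variant", "splice_acceptor_variant",
                      "synonymous_variant", "missense_variant",
                      "3_prime_UTR_variant", "5_prime_UTR_variant"),
                    n, replace = TRUE,
                    prob = c(0.10, 0.14, 0.04, 0.03, 0.35, 0.24, 0.06, 0.04))
  bin <- sample.int(4, n, replace = TRUE, prob = config$maf_bin_probs)
  maf <- rmaf_in_bin(n, bin)
  gene_idx <- sample.int(config$n_genes, n, replace = TRUE)

  ## keep the reserved iPTV genes free of ultra-rare PTVs
  n_iptv <- round(config$iptv_fraction * config$n_genes)
  iptv_truth <- if (n_iptv > 0) genes[seq_len(n_iptv)] else character(0)
  ptv_terms <- c("stop_gained", "frameshift_variant",
                 "splice_donor_variant", "splice_acceptor_variant")
  clash <- effects %in% ptv_terms & bin == 1L & gene_idx <= n_iptv
  if (any(clash) && n_iptv < config$n_genes)
    gene_idx[clash] <- sample((n_iptv + 1L):config$n_genes,
                              sum(clash), replace = TRUE)

  carriers <- lapply(maf, sample_carriers,
                     n_individuals = config$n_individuals, ids = ids)
  cds_pos <- rep(NA_integer_, n)
  is_stop <- effects == "stop_gained"
  if (any(is_stop)) {
    cds_pos[is_stop] <- vapply(which(is_stop), function(i) {
      tm <- transcripts[[gene_idx[i]]]
      as.integer(sample(seq(tm$cds_start, tm$cds_end), 1))
    }, integer(1))
  }
  variants <- data.frame(
    chrom = chroms[gene_idx],
    pos = sample.int(1e6, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    gene = genes[gene_idx],
    transcript = vapply(transcripts[gene_idx], function(t) t$transcript,
                        character(1)),
    canonical = TRUE,
    effect = effects,
    maf = maf,
    missing_rate = runif(n, 0, 0.05),
    cds_pos = cds_pos,
    stringsAsFactors = FALSE
  )
  variants$carriers <- I(carriers)
  list(variants = variants, transcripts = transcripts,
       iptv_truth = iptv_truth)
}

#' Simulate a full synthetic cohort
#'
#' Orchestrates the generator: sexes and per-individual burdens, death
#' ages and follow-up censoring (lifespan), age at first chronic disease
#' (healthspan, age scale, events may precede assessment), parental ages
#' at death with a shared-burden transmission term, nuisance covariates
#' (two genetic PCs, assessment center), and a variant-level table whose
#' ultra-rare PTV carriers aggregate exactly to the burden matrix.
#'
#' @param config a [sim_config()].
#' @param variants logical; generate the variant-level table (set `FALSE`
#'   for survival-only simulations at large n).
#' @return list of class `synthetic_cohort`: `phenotypes` (data.frame),
#'   `burden` (matrix, individuals x MAF bin), `variants`, `transcripts`,
#'   `iptv_truth`, `config`.
#' @export
simulate_cohort <- function(config, variants = TRUE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_individuals
  ids <- sprintf("I%05d", seq_len(n))
  sex <- rbinom(n, 1, config$male_fraction)
  burden <- simulate_burdens(config, seed = NA)
  ur <- burden[, 1]

  lp_life <- config$beta_burden_lifespan * ur + config$beta_sex_lifespan * sex
  death_age <- simulate_event_ages(config, ur, sex, "lifespan", seed = NA)
  fu <- simulate_followup(config, death_age, lp_life, seed = NA)

  disease_age <- simulate_event_ages(config, ur, sex, "healthspan", seed = NA)
  hs_censor <- fu$age_at_assessment + config$followup_years
  disease <- as.integer(disease_age <= hs_censor)
  hs_age <- pmin(disease_age, hs_censor)

  parent_age <- function(parent_sex) {
    b <- config$parent_burden_weight * ur +
      (1 - config$parent_burden_weight) *
        rcount(n, config$burden_mean, config$burden_dispersion)
    lp <- config$beta_burden_lifespan * b +
      config$beta_sex_lifespan * parent_sex
    ev <- gompertz_event_times(n, config$parent_h0, config$gompertz_slope, lp)
    cens <- fu$age_at_assessment + config$parent_age_gap
    data.frame(age = pmin(ev, cens), dead = as.integer(ev <= cens))
  }
  mother <- parent_age(0)
  father <- parent_age(1)

  phenotypes <- data.frame(
    id = ids, sex = sex,
    age_at_assessment = fu$age_at_assessment,
    time = fu$time, death = fu$event,
    age_first_disease = hs_age, disease = disease,
    mother_age = mother$age, mother_dead = mother$dead,
    father_age = father$age, father_dead = father$dead,
    pc1 = rnorm(n), pc2 = rnorm(n),
    center = sample(c("C1", "C2", "C3"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  out <- list(phenotypes = phenotypes, burden = burden, config = config)
  if (variants) {
    vt <- simulate_variant_table(config, seed = NA)
    vt <- match_ultra_rare_carriers(vt, burden, ids)
    out$variants <- vt$variants
    out$transcripts <- vt$transcripts
    out$iptv_truth <- vt$iptv_truth
  }
  class(out) <- "synthetic_cohort"
  out
}

## Reassign ultra-rare PTV carriers so that per-individual site counts
## aggregate exactly to the burden matrix: each individual carries its
## burden-matrix count of distinct ultra-rare PTV sites, sites drawn with
## probability proportional to their nominal MAF.
match_ultra_rare_carriers <- function(vt, burden, ids) {
  v <- vt$variants
  ptv_terms <- c("stop_gained", "frameshift_variant",
                 "splice_donor_variant", "splice_acceptor_variant")
  pool <- which(v$effect %in% ptv_terms & v$canonical &
                  v$maf < 1e-4 & v$chrom %in% as.character(1:22))
  need <- max(burden[, 1])
  if (length(pool) < need)
    stop("ultra-rare PTV site pool smaller than the largest burden; ",
         "increase n_variants")
  w <- v$maf[pool]
  carr <- vector("list", nrow(v))
  carr[pool] <- list(character(0))
  for (i in seq_along(ids)) {
    k <- burden[i, 1]
    if (k == 0) next
    sites <- pool[sample.int(length(pool), k, prob = w)]
    for (s in sites) carr[[s]] <- c(carr[[s]], ids[i])
  }
  v$carriers[pool] <- lapply(carr[pool], sort)
  vt$variants <- v
  vt
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals", nrow(x$phenotypes)))
  if (!is.null(x$variants))
    cat(sprintf(", %d variants in %d genes", nrow(x$variants),
                length(x$transcripts)))
  cat(sprintf("\n  deaths in follow-up: %d (%.1f%%)\n",
              sum(x$phenotypes$death),
              100 * mean(x$phenotypes$death)))
  cat(sprintf("  first-disease events: %d (%.1f%%)\n",
              sum(x$phenotypes$disease), 100 * mean(x$phenotypes$disease)))
  invisible(x)
}
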