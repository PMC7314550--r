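#' Reported causes of death in the UK Biobank follow-up
#'
#' The published cause-of-death tally for the 1,122 participants of the
#' exome-sequenced UK Biobank cohort who died during the 11-year
#' follow-up, shipped as a plain-text table. Used to compute summary
#' shares (e.g. the fraction of deaths due to neoplasms).
#'
#' @return data.frame with `cause` and `deaths`.
#' @export
ukb_cause_of_death <- function() {
  read.delim(system.file("extdata", "ukb_cause_of_death.tsv",
                         package = "ptvburden"),
             stringsAsFactors = FALSE)
}

#' Share of deaths attributable to one cause
#'
#' @param table a cause-of-death data.frame (`cause`, `deaths`).
#' @param cause cause name (matched by prefix, case-insensitive).
#' @return percentage of all deaths, in `[0, 100]`.
#' @export
cause_share <- function(table = ukb_cause_of_death(), cause = "Neoplasm") {
  hit <- grepl(paste0("^", cause), table$cause, ignore.case = TRUE)
  if (!any(hit)) stop("cause not found: ", cause)
  100 * sum(table$deaths[hit]) / sum(table$deaths)
}
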