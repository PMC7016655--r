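# Population-frequency criteria: PM2 (rarity) and the benign counterparts
# BA1/BS1.  "No data" in a queried database is treated as absence: a severe
# recessive childhood-disease variant missing from all reference panels is
# exactly the situation PM2 describes.

#' Allele frequency from allele counts
#'
#' @param allele_count Number of alternate alleles observed (>= 0).
#' @param allele_number Total number of alleles genotyped (> 0).
#' @return `allele_count / allele_number`, a fraction in \[0, 1\].
#' @export
#' @examples
#' allele_frequency(8, 1026)   # 0.0078 at 4 decimals
allele_frequency <- function(allele_count, allele_number) {
  stopifnot(is.numeric(allele_count), is.numeric(allele_number))
  if (any(allele_count < 0)) stop("allele_count must be >= 0")
  if (any(allele_number <= 0))
    stop("undefined frequency: allele_number must be > 0")
  if (any(allele_count > allele_number))
    stop("allele_count must not exceed allele_number")
  allele_count / allele_number
}

per_database_frequencies <- function(records) {
  records <- frequency_records(records)
  if (!nrow(records)) return(numeric(0))
  present <- !is.na(records$allele_count)
  freqs <- rep(NA_real_, nrow(records))
  freqs[present] <- allele_frequency(records$allele_count[present],
                                     records$allele_number[present])
  stats::setNames(freqs, records$database)
}

#' Evaluate PM2: absent or extremely rare in population databases
#'
#' PM2 is met when, in every queried database, the variant is either absent
#' (no record) or both rarer than `af_max` and seen in at most `hom_max`
#' homozygotes.  An empty record set means the variant was absent from all
#' queried databases, which meets PM2 for any positive `af_max`.
#'
#' Defaults (`af_max = 1e-4`, `hom_max = 0`) encode common curation practice
#' for a severe recessive childhood disease; both are overridable through
#' the run configuration.
#'
#' @param records A `popfreq_records` table (see [frequency_records()]),
#'   possibly 0-row.
#' @param af_max Strict upper bound on the allele frequency in any database.
#' @param hom_max Maximum tolerated homozygote count (when reported).
#' @return An [evidence_item()] for PM2.
#' @export
#' @examples
#' recs <- frequency_records(data.frame(
#'   database = "gnomAD", allele_count = 2, allele_number = 251106,
#'   homozygote_count = 0))
#' evaluate_pm2(recs)
evaluate_pm2 <- function(records, af_max = 1e-4, hom_max = 0L) {
  stopifnot(af_max > 0, hom_max >= 0)
  records <- frequency_records(records)
  freqs <- per_database_frequencies(records)
  present <- !is.na(freqs)
  if (!any(present)) {
    return(evidence_item("PM2", met = TRUE,
                         rationale = "absent from all queried databases"))
  }
  rare <- freqs[present] < af_max
  hom_ok <- rep(TRUE, sum(present))
  hc <- records$homozygote_count[present]
  hom_ok[!is.na(hc)] <- hc[!is.na(hc)] <= hom_max
  met <- all(rare & hom_ok)
  detail <- paste(sprintf("%s=%.3g", names(freqs)[present], freqs[present]),
                  collapse = ", ")
  rationale <- if (met) {
    sprintf("all observed frequencies below %g (%s)", af_max, detail)
  } else {
    sprintf("frequency or homozygote count above threshold (%s)", detail)
  }
  evidence_item("PM2", met = met, rationale = rationale)
}

#' Evaluate BA1/BS1: benign frequency counterparts
#'
#' BA1 (stand-alone benign) is met when any database frequency reaches
#' `ba1_af`; BS1 (strong benign) when any frequency reaches `bs1_af` and BA1
#' is not met.  Both comparisons are inclusive (`>=`).
#'
#' @param records A `popfreq_records` table.
#' @param ba1_af Stand-alone threshold (default 0.05).
#' @param bs1_af Strong threshold (default 0.01); must be below `ba1_af`.
#' @return A list of two [evidence_item()]s (BA1, BS1).
#' @export
evaluate_ba1_bs1 <- function(records, ba1_af = 0.05, bs1_af = 0.01) {
  stopifnot(ba1_af > bs1_af, bs1_af > 0)
  freqs <- per_database_frequencies(frequency_records(records))
  fmax <- if (any(!is.na(freqs))) max(freqs, na.rm = TRUE) else 0
  ba1 <- fmax >= ba1_af
  bs1 <- !ba1 && fmax >= bs1_af
  list(
    evidence_item("BA1", met = ba1,
                  rationale = sprintf("maximum observed frequency %.3g vs stand-alone threshold %g",
                                      fmax, ba1_af)),
    evidence_item("BS1", met = bs1,
                  rationale = sprintf("maximum observed frequency %.3g vs strong threshold %g",
                                      fmax, bs1_af)))
}
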