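# PP2: missense variants are a common disease mechanism in the gene AND the
# gene carries little benign missense variation; BP1 is the truncating-
# mechanism counterpart.  Inputs are gene-level variant count summaries from
# curated databases (e.g. ClinVar-style or HGMD-style totals); when several
# sources are supplied the most favorable one may satisfy the missense-
# mechanism condition.

#' Evaluate PP2: missense as a common disease mechanism
#'
#' PP2 is met when the highest pathogenic-missense fraction across the
#' supplied summaries reaches `missense_fraction_min` and, wherever a benign
#' breakdown is reported, the benign fraction stays at or below
#' `benign_fraction_max`.  If no summary reports pathogenic variants the
#' criterion is uninformative and not met.
#'
#' @param summaries A `gene_summaries` table (see [gene_summaries()]).
#' @param missense_fraction_min Minimum pathogenic_missense/pathogenic_total
#'   fraction (default 0.5).
#' @param benign_fraction_max Maximum benign_count/total_classified fraction
#'   (default 0.10).
#' @return An [evidence_item()] for PP2.
#' @export
#' @examples
#' gs <- gene_summaries(data.frame(
#'   source = c("ClinVar", "HGMD"),
#'   pathogenic_total = c(69, 191), pathogenic_missense = c(52, 103),
#'   benign_count = c(8, NA), total_classified = c(93, NA)))
#' evaluate_pp2(gs)
evaluate_pp2 <- function(summaries, missense_fraction_min = 0.5,
                         benign_fraction_max = 0.10) {
  summaries <- gene_summaries(summaries)
  informative <- !is.na(summaries$pathogenic_total) &
    summaries$pathogenic_total > 0
  if (!any(informative))
    return(evidence_item("PP2", met = FALSE,
                         rationale = "no summary reports pathogenic variants (uninformative)"))
  fracs <- summaries$pathogenic_missense[informative] /
    summaries$pathogenic_total[informative]
  best <- max(fracs)
  missense_ok <- best >= missense_fraction_min
  has_benign <- !is.na(summaries$benign_count) &
    !is.na(summaries$total_classified) & summaries$total_classified > 0
  benign_fracs <- summaries$benign_count[has_benign] /
    summaries$total_classified[has_benign]
  benign_ok <- !any(has_benign) || all(benign_fracs <= benign_fraction_max)
  met <- missense_ok && benign_ok
  rationale <- sprintf(
    "max pathogenic-missense fraction %.3f (threshold %.2f); benign fraction %s",
    best, missense_fraction_min,
    if (any(has_benign)) sprintf("%.3f (threshold %.2f)",
                                 max(benign_fracs), benign_fraction_max)
    else "not reported")
  evidence_item("PP2", met = met, rationale = rationale)
}

#' Evaluate BP1: missense in a truncating-mechanism gene
#'
#' BP1 is met when the pathogenic-missense fraction is at or below
#' `missense_fraction_max` in every informative summary, indicating that
#' missense changes are not how this gene causes disease.
#'
#' @param summaries A `gene_summaries` table.
#' @param missense_fraction_max Maximum missense fraction (default 0.1).
#' @return An [evidence_item()] for BP1.
#' @export
evaluate_bp1 <- function(summaries, missense_fraction_max = 0.1) {
  summaries <- gene_summaries(summaries)
  informative <- !is.na(summaries$pathogenic_total) &
    summaries$pathogenic_total > 0
  if (!any(informative))
    return(evidence_item("BP1", met = FALSE,
                         rationale = "no summary reports pathogenic variants (uninformative)"))
  fracs <- summaries$pathogenic_missense[informative] /
    summaries$pathogenic_total[informative]
  met <- max(fracs) <= missense_fraction_max
  evidence_item("BP1", met = met,
                rationale = sprintf("max pathogenic-missense fraction %.3f (threshold %.2f)",
                                    max(fracs), missense_fraction_max))
}
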