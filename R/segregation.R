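# Autosomal-recessive co-segregation: within a family, disease status must
# track homozygosity for the candidate variant.  Full penetrance is assumed:
# any unaffected homozygote (or affected non-homozygote) breaks consistency.
# Members with unknown affection or missing genotype are excluded from all
# counts.

#' Check autosomal-recessive co-segregation in one family
#'
#' Counts are computed over genotyped members with known affection status
#' only.  A family is consistent when at least one affected member is
#' homozygous for the variant, no affected member carries another genotype,
#' and no unaffected member is homozygous.  Families with no informative
#' member return an uninformative verdict (`consistent = FALSE`,
#' `uninformative = TRUE`).
#'
#' @param ped A [pedigree()] object.
#' @return A one-row data frame (class `segregation_verdict`) with columns
#'   `family_id`, `consistent`, `uninformative`, `n_affected_homalt`,
#'   `n_affected_other_genotype`, `n_unaffected_homalt`,
#'   `n_informative_unaffected`.
#' @export
#' @examples
#' ped <- parse_ped(c("A F 0 0 1 1 0/1", "A M 0 0 2 1 0/1",
#'                    "A C1 F M 2 2 1/1", "A C2 F M 1 2 1/1"))[[1]]
#' check_ar_cosegregation(ped)
check_ar_cosegregation <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  df <- pedigree_to_df(ped)
  informative <- df$genotype != "missing" & df$affection != "unknown"
  d <- df[informative, , drop = FALSE]
  n_aff_hom   <- sum(d$affection == "affected"   & d$genotype == "hom_alt")
  n_aff_other <- sum(d$affection == "affected"   & d$genotype != "hom_alt")
  n_unaff_hom <- sum(d$affection == "unaffected" & d$genotype == "hom_alt")
  n_inf_unaff <- sum(d$affection == "unaffected" & d$genotype != "hom_alt")
  uninformative <- nrow(d) == 0L
  consistent <- !uninformative && n_aff_other == 0L && n_unaff_hom == 0L &&
    n_aff_hom >= 1L
  out <- data.frame(
    family_id = ped$family_id, consistent = consistent,
    uninformative = uninformative,
    n_affected_homalt = n_aff_hom,
    n_affected_other_genotype = n_aff_other,
    n_unaffected_homalt = n_unaff_hom,
    n_informative_unaffected = n_inf_unaff,
    stringsAsFactors = FALSE)
  class(out) <- c("segregation_verdict", class(out))
  out
}

#' Co-segregation verdicts for a list of pedigrees
#'
#' @param pedigrees List of [pedigree()] objects.
#' @return A `segregation_verdict` data frame, one row per family.
#' @export
segregation_verdicts <- function(pedigrees) {
  out <- do.call(rbind, lapply(pedigrees, check_ar_cosegregation))
  class(out) <- c("segregation_verdict", class(out))
  out
}

contradicted <- function(verdicts) {
  verdicts$n_affected_other_genotype > 0 | verdicts$n_unaffected_homalt > 0
}

#' Evaluate PP1: co-segregation with disease across families
#'
#' PP1 is met when at least one family shows consistent autosomal-recessive
#' co-segregation and no family contradicts it (an affected non-homozygote
#' or an unaffected homozygote anywhere suppresses the criterion).  PP1
#' enters at supporting strength; optional escalation to moderate or strong
#' is available when many independent families segregate, but is off by
#' default because a single-cohort run rarely justifies it.
#'
#' @param verdicts A `segregation_verdict` data frame from
#'   [segregation_verdicts()]; must contain at least one family.
#' @param escalate Logical: apply the escalation thresholds?
#' @param escalation List with `moderate_families`, `moderate_informative`
#'   (both required for moderate) and `strong_families`.
#' @return An [evidence_item()] for PP1.
#' @export
evaluate_pp1 <- function(verdicts, escalate = FALSE,
                         escalation = list(moderate_families = 3L,
                                           moderate_informative = 6L,
                                           strong_families = 5L)) {
  if (is.null(verdicts) || nrow(verdicts) == 0L)
    stop("evaluate_pp1 requires verdicts from at least one family")
  if (all(verdicts$uninformative))
    return(evidence_item("PP1", met = FALSE,
                         rationale = "no informative families"))
  any_contradiction <- any(contradicted(verdicts))
  n_consistent <- sum(verdicts$consistent)
  met <- n_consistent >= 1L && !any_contradiction
  strength <- "supporting"
  if (met && escalate) {
    n_inf <- sum(verdicts$n_informative_unaffected[verdicts$consistent])
    if (n_consistent >= escalation$strong_families) {
      strength <- "strong"
    } else if (n_consistent >= escalation$moderate_families &&
               n_inf >= escalation$moderate_informative) {
      strength <- "moderate"
    }
  }
  rationale <- if (met) {
    sprintf("%d of %d families show consistent AR co-segregation, none contradicts",
            n_consistent, nrow(verdicts))
  } else if (any_contradiction) {
    sprintf("contradictory segregation in family/families: %s",
            paste(verdicts$family_id[contradicted(verdicts)],
                  collapse = ", "))
  } else {
    "no family shows consistent co-segregation"
  }
  evidence_item("PP1", met = met, strength = strength,
                rationale = rationale)
}

#' Evaluate BS4: lack of segregation with disease
#'
#' BS4 is met when any family contradicts autosomal-recessive segregation:
#' an affected member who is not homozygous for the variant, or an
#' unaffected homozygote.
#'
#' @param verdicts A `segregation_verdict` data frame.
#' @return An [evidence_item()] for BS4.
#' @export
evaluate_bs4 <- function(verdicts) {
  if (is.null(verdicts) || nrow(verdicts) == 0L)
    stop("evaluate_bs4 requires verdicts from at least one family")
  bad <- contradicted(verdicts)
  evidence_item(
    "BS4", met = any(bad),
    rationale = if (any(bad))
      sprintf("segregation contradicted in: %s",
              paste(verdicts$family_id[bad], collapse = ", "))
    else "no family contradicts AR segregation")
}
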