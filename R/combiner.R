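# Combining met evidence items into the five-tier classification.  The rule
# set is the published ACMG/AMP combining table; evaluation order is fixed
# (Pathogenic, Likely pathogenic, Benign, Likely benign) and the first
# satisfied rule is reported.  The tier outcome is order-independent by
# construction; only the reported rule identifier depends on the order.

#' Tally met evidence items by direction and strength
#'
#' Counts only items with `met = TRUE`; each criterion code may appear at
#' most once among met items (duplicates are rejected).  Strength-modulated
#' items count in the bucket of their assigned strength, not the default for
#' their code.
#'
#' @param evidence List of [evidence_item()] objects.
#' @return An object of class `evidence_tally`: counts `n_stand_alone`,
#'   `n_very_strong`, `n_strong`, `n_moderate`, `n_supporting` (pathogenic
#'   side), `n_ba`, `n_bs`, `n_bp` (benign side), plus the list of met items
#'   as `met_items`.
#' @export
#' @examples
#' tally_evidence(list(evidence_item("PS4", TRUE), evidence_item("PM2", TRUE),
#'                     evidence_item("PP1", TRUE), evidence_item("PP2", TRUE),
#'                     evidence_item("PP3", TRUE)))
tally_evidence <- function(evidence) {
  stopifnot(is.list(evidence))
  met <- Filter(function(e) {
    stopifnot(inherits(e, "evidence_item"))
    e$met
  }, evidence)
  codes <- vapply(met, `[[`, character(1), "code")
  if (anyDuplicated(codes))
    stop("duplicate met criterion code(s): ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  count <- function(direction, strength) {
    sum(vapply(met, function(e)
      e$direction == direction && e$strength == strength, logical(1)))
  }
  structure(
    list(n_stand_alone = count("pathogenic", "stand_alone"),
         n_very_strong = count("pathogenic", "very_strong"),
         n_strong      = count("pathogenic", "strong"),
         n_moderate    = count("pathogenic", "moderate"),
         n_supporting  = count("pathogenic", "supporting"),
         n_ba = count("benign", "stand_alone"),
         n_bs = count("benign", "strong") + count("benign", "very_strong"),
         n_bp = count("benign", "supporting") +
                count("benign", "moderate"),
         met_items = met),
    class = "evidence_tally")
}

#' Construct an evidence tally from raw counts
#'
#' Convenience constructor for rule exploration without building evidence
#' items (e.g. what-if analyses and exhaustive rule audits).
#'
#' @param very_strong,strong,moderate,supporting Pathogenic-side counts.
#' @param stand_alone Pathogenic stand-alone count (unused by the guideline
#'   but kept for symmetry; default 0).
#' @param ba,bs,bp Benign-side counts (stand-alone, strong, supporting).
#' @return An `evidence_tally`.
#' @export
evidence_tally <- function(very_strong = 0L, strong = 0L, moderate = 0L,
                           supporting = 0L, stand_alone = 0L, ba = 0L,
                           bs = 0L, bp = 0L) {
  counts <- c(very_strong, strong, moderate, supporting, stand_alone,
              ba, bs, bp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("tally counts must be non-negative integers")
  structure(
    list(n_stand_alone = stand_alone, n_very_strong = very_strong,
         n_strong = strong, n_moderate = moderate,
         n_supporting = supporting, n_ba = ba, n_bs = bs, n_bp = bp,
         met_items = list()),
    class = "evidence_tally")
}

# Ordered rule table: id, tier, predicate over a tally.  Counts are read as
# "at least" the combination the guideline enumerates: the published table
# lists minimal qualifying combinations, and the at-least reading is what
# keeps the verdict monotone when evidence beyond a minimal combination is
# present (e.g. one strong plus three moderates still qualifies under the
# one-strong-plus-moderates pathogenic rule).
combining_rules <- function() {
  list(
    list(id = "P_vs_plus",  tier = "pathogenic",
         test = function(t) t$n_very_strong >= 1 &&
           (t$n_strong >= 1 || t$n_moderate >= 2 ||
            (t$n_moderate >= 1 && t$n_supporting >= 1) ||
            t$n_supporting >= 2)),
    list(id = "P_2_strong", tier = "pathogenic",
         test = function(t) t$n_strong >= 2),
    list(id = "P_1_strong_combo", tier = "pathogenic",
         test = function(t) t$n_strong >= 1 &&
           (t$n_moderate >= 3 ||
            (t$n_moderate >= 2 && t$n_supporting >= 2) ||
            (t$n_moderate >= 1 && t$n_supporting >= 4))),
    list(id = "LP_vs_1_moderate", tier = "likely_pathogenic",
         test = function(t) t$n_very_strong >= 1 && t$n_moderate >= 1),
    list(id = "LP_1_strong_1_2_moderate", tier = "likely_pathogenic",
         test = function(t) t$n_strong >= 1 && t$n_moderate >= 1),
    list(id = "LP_1_strong_2_supporting", tier = "likely_pathogenic",
         test = function(t) t$n_strong >= 1 && t$n_supporting >= 2),
    list(id = "LP_3_moderate", tier = "likely_pathogenic",
         test = function(t) t$n_moderate >= 3),
    list(id = "LP_2_moderate_2_supporting", tier = "likely_pathogenic",
         test = function(t) t$n_moderate >= 2 && t$n_supporting >= 2),
    list(id = "LP_1_moderate_4_supporting", tier = "likely_pathogenic",
         test = function(t) t$n_moderate >= 1 && t$n_supporting >= 4),
    list(id = "B_stand_alone", tier = "benign",
         test = function(t) t$n_ba >= 1),
    list(id = "B_2_strong", tier = "benign",
         test = function(t) t$n_bs >= 2),
    list(id = "LB_1_strong_1_supporting", tier = "likely_benign",
         test = function(t) t$n_bs >= 1 && t$n_bp >= 1),
    list(id = "LB_2_supporting", tier = "likely_benign",
         test = function(t) t$n_bp >= 2))
}

#' Combine an evidence tally into a five-tier classification
#'
#' Applies the ACMG/AMP combining rules.  If rules fire on both the
#' pathogenic and the benign side, the verdict is uncertain significance
#' with `rule_fired = "conflicting"`; if no rule fires at all it is
#' uncertain significance with `rule_fired = "default_vus"`.
#'
#' @param tally An `evidence_tally` from [tally_evidence()] or
#'   [evidence_tally()].
#' @return An object of class `acmg_classification` with fields `tier`,
#'   `rule_fired`, `evidence_trace` (the met items behind the tally).
#' @export
#' @examples
#' combine_evidence(evidence_tally(strong = 1, moderate = 1, supporting = 3))
combine_evidence <- function(tally) {
  stopifnot(inherits(tally, "evidence_tally"))
  fired <- Filter(function(r) r$test(tally), combining_rules())
  tiers <- vapply(fired, `[[`, character(1), "tier")
  path_side <- any(tiers %in% c("pathogenic", "likely_pathogenic"))
  benign_side <- any(tiers %in% c("benign", "likely_benign"))
  if (path_side && benign_side) {
    tier <- "uncertain_significance"
    rule <- "conflicting"
  } else if (length(fired)) {
    tier <- fired[[1]]$tier
    rule <- fired[[1]]$id
  } else {
    tier <- "uncertain_significance"
    rule <- "default_vus"
  }
  structure(list(tier = tier, rule_fired = rule,
                 evidence_trace = tally$met_items),
            class = "acmg_classification")
}

#' @export
print.acmg_classification <- function(x, ...) {
  cat(sprintf("<acmg_classification> %s (rule: %s)\n", x$tier,
              x$rule_fired))
  if (length(x$evidence_trace)) {
    cat("  evidence:",
        paste(vapply(x$evidence_trace, function(e)
          sprintf("%s[%s]", e$code, e$strength), character(1)),
          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reclassification under one additional (or escalated) criterion
#'
#' Answers "what would the tier become if this criterion were also met?".
#' The additional code must not already be among the met items; to model a
#' strength escalation of an already-met criterion, drop it from the
#' evidence first and re-add it at the new strength.
#'
#' @param tally An `evidence_tally`.
#' @param code Criterion code to add.
#' @param strength Strength at which to count it (default: the code's
#'   guideline strength).
#' @return The `acmg_classification` of the augmented tally.
#' @export
#' @examples
#' base <- tally_evidence(list(
#'   evidence_item("PS4", TRUE), evidence_item("PM2", TRUE),
#'   evidence_item("PP1", TRUE), evidence_item("PP2", TRUE),
#'   evidence_item("PP3", TRUE)))
#' what_if(base, "PM3")$tier  # pathogenic
what_if <- function(tally, code, strength = acmg_default_strength(code)) {
  stopifnot(inherits(tally, "evidence_tally"))
  code <- match.arg(code, acmg_codes())
  existing <- vapply(tally$met_items, `[[`, character(1), "code")
  if (code %in% existing)
    stop("criterion ", code, " is already met in this tally")
  extra <- evidence_item(code, met = TRUE, strength = strength,
                         rationale = "hypothetical (what-if analysis)")
  augmented <- tally
  slot <- if (extra$direction == "pathogenic") {
    switch(extra$strength, stand_alone = "n_stand_alone",
           very_strong = "n_very_strong", strong = "n_strong",
           moderate = "n_moderate", supporting = "n_supporting")
  } else {
    switch(extra$strength, stand_alone = "n_ba",
           very_strong = "n_bs", strong = "n_bs",
           moderate = "n_bp", supporting = "n_bp")
  }
  augmented[[slot]] <- augmented[[slot]] + 1L
  augmented$met_items <- c(tally$met_items, list(extra))
  combine_evidence(augmented)
}
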