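# Per-tool mapping of 16 predictor outputs (numeric scores or categorical
# labels) to deleterious/benign/ambiguous calls, aggregated into PP3 (or BP4)
# by consensus fraction.

PREDICTOR_TOOLS <- c("PolyPhen2", "SIFT", "DANN", "PROVEAN", "LRT",
                     "MutationTaster", "MutationAssessor", "FATHMM",
                     "FATHMM-MKL", "M-CAP", "CADD", "MetaSVM", "MetaLR",
                     "PhyloP20way", "PhyloP100way", "GERP_RS")

categorical_entry <- function(mapping) {
  list(kind = "categorical", mapping = mapping)
}
numeric_entry <- function(cutoff, direction = "higher_is_damaging") {
  stopifnot(direction %in% c("higher_is_damaging", "lower_is_damaging"))
  list(kind = "numeric", cutoff = cutoff, direction = direction)
}

damaging_labels <- c("damaging", "deleterious", "disease-causing",
                     "disease causing")
tolerated_labels <- c("tolerated", "benign", "neutral", "polymorphism")

#' Default per-tool threshold table for the 16-predictor panel
#'
#' Categorical tools map their published labels (e.g. PolyPhen2 "Probably
#' damaging"/"Possibly damaging", SIFT "Damaging", MutationTaster
#' "Disease-causing", MutationAssessor "high"/"medium" impact) onto
#' deleterious/benign calls; numeric tools compare against the cutoffs in
#' conventional use: DANN > 0.9, CADD > 20 (a scaled C-score of 20 marks the
#' top 1% of substitutions), PhyloP 20way > 0.5, PhyloP 100way > 2,
#' GERP RS > 4, all with higher scores more damaging.  Conservation-only
#' tools (PhyloP, GERP) count in the same consensus pool as the functional
#' predictors.
#'
#' @return A named list, one entry per tool, each either
#'   `list(kind = "categorical", mapping = ...)` or
#'   `list(kind = "numeric", cutoff = ..., direction = ...)`.
#' @export
default_threshold_table <- function() {
  cat_damaging <- categorical_entry(c(
    stats::setNames(rep("deleterious", length(damaging_labels)),
                    damaging_labels),
    stats::setNames(rep("benign", length(tolerated_labels)),
                    tolerated_labels)))
  list(
    PolyPhen2 = categorical_entry(c("probably damaging" = "deleterious",
                                    "possibly damaging" = "deleterious",
                                    "benign" = "benign")),
    SIFT = cat_damaging,
    DANN = numeric_entry(0.9),
    PROVEAN = cat_damaging,
    LRT = cat_damaging,
    MutationTaster = cat_damaging,
    MutationAssessor = categorical_entry(c("high" = "deleterious",
                                           "high impact" = "deleterious",
                                           "medium" = "deleterious",
                                           "medium impact" = "deleterious",
                                           "low" = "benign",
                                           "low impact" = "benign",
                                           "neutral" = "benign")),
    FATHMM = cat_damaging,
    `FATHMM-MKL` = cat_damaging,
    `M-CAP` = cat_damaging,
    CADD = numeric_entry(20),
    MetaSVM = cat_damaging,
    MetaLR = cat_damaging,
    PhyloP20way = numeric_entry(0.5),
    PhyloP100way = numeric_entry(2),
    GERP_RS = numeric_entry(4))
}

#' Map one predictor output to a deleterious/benign/ambiguous call
#'
#' Categorical labels are matched case-insensitively against the tool's
#' mapping; numeric values are compared against the tool's cutoff in the
#' stated direction (strictly beyond the cutoff is deleterious, otherwise
#' benign).  A categorical label missing from the mapping yields
#' `"ambiguous"`.
#'
#' @param tool Tool name registered in `thresholds`.
#' @param value Raw value: a number for numeric tools, a label string for
#'   categorical tools.
#' @param thresholds Threshold table, see [default_threshold_table()].
#' @return `"deleterious"`, `"benign"` or `"ambiguous"`.
#' @export
#' @examples
#' classify_tool_call("CADD", 24.9)
#' classify_tool_call("PolyPhen2", "Possibly damaging")
classify_tool_call <- function(tool, value,
                               thresholds = default_threshold_table()) {
  entry <- thresholds[[tool]]
  if (is.null(entry))
    stop("tool '", tool, "' is not registered in the threshold table")
  if (entry$kind == "numeric") {
    num <- suppressWarnings(as.numeric(value))
    if (is.na(num))
      stop("non-numeric value '", value, "' for numeric tool '", tool, "'")
    if (!is.finite(num)) stop("non-finite value for tool '", tool, "'")
    hit <- if (entry$direction == "higher_is_damaging") num > entry$cutoff
           else num < entry$cutoff
    return(if (hit) "deleterious" else "benign")
  }
  label <- tolower(trimws(as.character(value)))
  call <- unname(entry$mapping[label])
  if (length(call) != 1L || is.na(call)) "ambiguous" else call
}

profile_calls <- function(profile, thresholds) {
  stopifnot(is.list(profile))
  vapply(names(profile), function(tool) {
    classify_tool_call(tool, profile[[tool]], thresholds)
  }, character(1))
}

#' Evaluate PP3: computational consensus of deleteriousness
#'
#' PP3 is met when the fraction of deleterious calls among all mapped
#' (non-ambiguous) calls reaches `tau`.  The default `tau = 0.75` demands a
#' clear majority while tolerating a dissenting tool or two in a 16-tool
#' panel.  The rationale records the per-tool calls and the count.
#'
#' @param profile Named list mapping tool name to raw value.
#' @param thresholds Threshold table, see [default_threshold_table()].
#' @param tau Required deleterious fraction among mapped calls.
#' @return An [evidence_item()] for PP3 with attribute `calls` (the per-tool
#'   call vector) and `n_deleterious`.
#' @export
evaluate_pp3 <- function(profile, thresholds = default_threshold_table(),
                         tau = 0.75) {
  stopifnot(tau > 0, tau <= 1)
  if (!length(profile)) {
    ev <- evidence_item("PP3", met = FALSE, rationale = "no predictions")
    attr(ev, "calls") <- character(0)
    attr(ev, "n_deleterious") <- 0L
    return(ev)
  }
  calls <- profile_calls(profile, thresholds)
  mapped <- calls[calls != "ambiguous"]
  n_del <- sum(mapped == "deleterious")
  frac <- if (length(mapped)) n_del / length(mapped) else 0
  met <- length(mapped) > 0 && frac >= tau
  ev <- evidence_item(
    "PP3", met = met,
    rationale = sprintf("%d of %d mapped tools deleterious (%s)",
                        n_del, length(mapped),
                        paste(names(calls), calls, sep = "=",
                              collapse = ", ")))
  attr(ev, "calls") <- calls
  attr(ev, "n_deleterious") <- n_del
  ev
}

#' Evaluate BP4: computational consensus of benign impact
#'
#' BP4 is met when the benign fraction among mapped calls reaches
#' `tau_benign` and PP3 is not met for the same profile; the two criteria
#' are therefore never simultaneously met.
#'
#' @inheritParams evaluate_pp3
#' @param tau_benign Required benign fraction among mapped calls.
#' @param tau Deleterious fraction used for the internal PP3 check.
#' @return An [evidence_item()] for BP4.
#' @export
evaluate_bp4 <- function(profile, thresholds = default_threshold_table(),
                         tau_benign = 0.75, tau = 0.75) {
  stopifnot(tau_benign > 0, tau_benign <= 1)
  if (!length(profile))
    return(evidence_item("BP4", met = FALSE, rationale = "no predictions"))
  calls <- profile_calls(profile, thresholds)
  mapped <- calls[calls != "ambiguous"]
  n_ben <- sum(mapped == "benign")
  frac <- if (length(mapped)) n_ben / length(mapped) else 0
  pp3_met <- evaluate_pp3(profile, thresholds, tau)$met
  met <- length(mapped) > 0 && frac >= tau_benign && !pp3_met
  evidence_item(
    "BP4", met = met,
    rationale = sprintf("%d of %d mapped tools benign", n_ben,
                        length(mapped)))
}
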