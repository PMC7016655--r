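# Full-run orchestration: inputs -> evidence -> association ->
# classification, driven by a single configuration (an R list or a YAML
# file).  Reports are emitted as JSON (machine-readable, schema-stable) and
# TSV (evidence table).

#' Default thresholds for a classification run
#'
#' All tunables referenced by the evidence modules, overridable per run:
#' `af_max`/`hom_max` (PM2), `ba1_af`/`bs1_af` (BA1/BS1), `tau`/`tau_benign`
#' (PP3/BP4), `missense_fraction_min`/`benign_fraction_max` (PP2),
#' `bp1_missense_fraction_max` (BP1), `or_min`/`exclude_value` (PS4),
#' `base_confidence`/`n_tests` (Wald interval with Bonferroni adjustment),
#' `escalate`/`escalation` (PP1 strength escalation).
#'
#' @return A named list of threshold values.
#' @export
default_run_thresholds <- function() {
  list(af_max = 1e-4, hom_max = 0L, ba1_af = 0.05, bs1_af = 0.01,
       tau = 0.75, tau_benign = 0.75,
       missense_fraction_min = 0.5, benign_fraction_max = 0.10,
       bp1_missense_fraction_max = 0.1,
       or_min = 3, exclude_value = 1,
       base_confidence = 0.95, n_tests = 1L,
       escalate = FALSE,
       escalation = list(moderate_families = 3L, moderate_informative = 6L,
                         strong_families = 5L))
}

#' Classify one variant from its evidence inputs
#'
#' Evaluates every criterion for which an input is supplied (inputs left
#' `NULL` simply contribute no evidence), tallies the met items, combines
#' them into a five-tier verdict and reports the standard what-if
#' escalations: adding PM3 (a known-pathogenic variant in trans) and
#' applying PP1 at moderate or strong strength.
#'
#' @param variant A [variant_record()].
#' @param frequency Population-frequency records ([frequency_records()]), or
#'   `NULL`.
#' @param profile Predictor profile (named list), or `NULL`.
#' @param gene_summary Gene-level summaries ([gene_summaries()]), or `NULL`.
#' @param pedigrees List of [pedigree()]s, or `NULL`.
#' @param cohort_df A [cohort()] data frame, or `NULL`.
#' @param thresholds Threshold list, see [default_run_thresholds()].
#' @param extra_evidence Additional manually asserted [evidence_item()]s
#'   (e.g. PP4 from clinical review); appended as-is.
#' @return A list of class `variant_report`: `variant`, `evidence` (all
#'   evaluated items), `association` (or `NULL`), `classification`,
#'   `escalations` (data frame scenario/tier).
#' @export
classify_variant <- function(variant, frequency = NULL, profile = NULL,
                             gene_summary = NULL, pedigrees = NULL,
                             cohort_df = NULL,
                             thresholds = default_run_thresholds(),
                             extra_evidence = list()) {
  stopifnot(inherits(variant, "variant_record"))
  th <- utils::modifyList(default_run_thresholds(), thresholds)
  evidence <- list()
  assoc <- NULL
  if (!is.null(frequency)) {
    evidence <- c(evidence,
                  list(evaluate_pm2(frequency, th$af_max, th$hom_max)),
                  evaluate_ba1_bs1(frequency, th$ba1_af, th$bs1_af))
  }
  if (!is.null(profile)) {
    evidence <- c(evidence,
                  list(evaluate_pp3(profile, tau = th$tau),
                       evaluate_bp4(profile, tau_benign = th$tau_benign,
                                    tau = th$tau)))
  }
  if (!is.null(gene_summary)) {
    evidence <- c(evidence,
                  list(evaluate_pp2(gene_summary, th$missense_fraction_min,
                                    th$benign_fraction_max),
                       evaluate_bp1(gene_summary,
                                    th$bp1_missense_fraction_max)))
  }
  if (!is.null(pedigrees) && length(pedigrees)) {
    verdicts <- segregation_verdicts(pedigrees)
    evidence <- c(evidence,
                  list(evaluate_pp1(verdicts, escalate = th$escalate,
                                    escalation = th$escalation),
                       evaluate_bs4(verdicts)))
  }
  if (!is.null(cohort_df)) {
    assoc <- case_control_association(build_table(cohort_df),
                                      th$base_confidence, th$n_tests)
    evidence <- c(evidence,
                  list(evaluate_ps4(assoc, th$or_min, th$exclude_value)))
  }
  evidence <- c(evidence, extra_evidence)
  tally <- tally_evidence(evidence)
  classification <- combine_evidence(tally)
  escalations <- escalation_table(tally)
  structure(
    list(variant = variant, evidence = evidence, association = assoc,
         classification = classification, escalations = escalations),
    class = "variant_report")
}

escalation_table <- function(tally) {
  met_codes <- vapply(tally$met_items, `[[`, character(1), "code")
  rows <- list()
  if (!"PM3" %in% met_codes)
    rows <- c(rows, list(data.frame(
      scenario = "add PM3 (pathogenic variant in trans)",
      tier = what_if(tally, "PM3")$tier, stringsAsFactors = FALSE)))
  if ("PP1" %in% met_codes) {
    pp1 <- tally$met_items[[match("PP1", met_codes)]]
    for (s in setdiff(c("moderate", "strong"), pp1$strength)) {
      without <- tally_evidence(
        tally$met_items[met_codes != "PP1"])
      rows <- c(rows, list(data.frame(
        scenario = sprintf("escalate PP1 to %s", s),
        tier = what_if(without, "PP1", strength = s)$tier,
        stringsAsFactors = FALSE)))
    }
  }
  if (!length(rows))
    return(data.frame(scenario = character(0), tier = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' @export
print.variant_report <- function(x, ...) {
  cat(sprintf("== %s %s (%s) ==\n", x$variant$gene, x$variant$cdna_change,
              x$variant$protein_change))
  for (e in x$evidence) if (e$met) print(e)
  if (!is.null(x$association)) print(x$association)
  print(x$classification)
  if (nrow(x$escalations)) {
    cat("what-if escalations:\n")
    for (i in seq_len(nrow(x$escalations)))
      cat(sprintf("  %s -> %s\n", x$escalations$scenario[i],
                  x$escalations$tier[i]))
  }
  invisible(x)
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file with the structure accepted by
#'   [run_classification()].
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  yaml::read_yaml(path)
}

resolve_input <- function(path, reader, stage, base_dir = NULL) {
  if (is.null(path)) return(NULL)
  if (!is.null(base_dir) && !file.exists(path))
    path <- file.path(base_dir, path)
  if (!file.exists(path))
    stop("[", stage, "] input file not found: ", path)
  tryCatch(reader(path),
           error = function(e)
             stop("[", stage, "] failed reading '", path, "': ",
                  conditionMessage(e), call. = FALSE))
}

#' Run the full classification pipeline from a configuration
#'
#' The configuration is a list (or YAML file read with
#' [read_run_config()]) with entries:
#' \describe{
#'   \item{preset}{optional; `"rpe65_replica"` runs the bundled worked
#'     example end to end, ignoring per-variant paths.}
#'   \item{variants}{a list; each element has `gene`, `transcript`,
#'     `cdna_change`, `protein_change`, `consequence`, and optional input
#'     paths `frequency_path`, `cohort_path`, `ped_path`, plus
#'     `predictor_id` selecting its column in the shared predictor table.}
#'   \item{predictors_path, gene_summaries_path}{shared input tables.}
#'   \item{thresholds}{overrides merged onto [default_run_thresholds()];
#'     `n_tests` defaults to the number of variants.}
#'   \item{out_dir}{optional; when set, JSON and TSV reports are written.}
#' }
#'
#' @param config Configuration list or path to a YAML file.
#' @return A named list of `variant_report`s (one per variant), invisibly
#'   when `out_dir` is set.
#' @export
#' @examples
#' reports <- run_classification(list(preset = "rpe65_replica"))
#' reports[["p.Phe83Leu"]]$classification$tier
run_classification <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  stopifnot(is.list(config))
  th <- utils::modifyList(default_run_thresholds(),
                          config$thresholds %||% list())
  if (identical(config$preset, "rpe65_replica")) {
    th$n_tests <- config$thresholds$n_tests %||% 2L
    reports <- lapply(REPLICA_VARIANTS, function(v) {
      classify_variant(
        rpe65_variants()[[v]],
        frequency = rpe65_frequency_records(v),
        profile = rpe65_predictor_profile(v),
        gene_summary = rpe65_gene_summaries(),
        pedigrees = replica_pedigrees(v),
        cohort_df = replica_cohort(v),
        thresholds = th)
    })
    names(reports) <- REPLICA_VARIANTS
  } else {
    if (is.null(config$variants) || !length(config$variants))
      stop("[config] no variants declared and no preset selected")
    th$n_tests <- config$thresholds$n_tests %||% length(config$variants)
    base_dir <- config$base_dir
    profiles <- resolve_input(config$predictors_path,
                              read_predictor_profiles, "predictors",
                              base_dir)
    gene_summary <- resolve_input(config$gene_summaries_path,
                                  read_gene_summaries, "gene_context",
                                  base_dir)
    reports <- lapply(config$variants, function(vc) {
      variant <- variant_record(vc$gene, vc$transcript, vc$cdna_change,
                                vc$protein_change, vc$consequence,
                                vc$inheritance_mode %||%
                                  "autosomal_recessive")
      classify_variant(
        variant,
        frequency = resolve_input(vc$frequency_path,
                                  read_frequency_records, "frequency",
                                  base_dir),
        profile = if (!is.null(profiles) && !is.null(vc$predictor_id))
          profiles[[vc$predictor_id]],
        gene_summary = gene_summary,
        pedigrees = resolve_input(vc$ped_path, parse_ped, "segregation",
                                  base_dir),
        cohort_df = resolve_input(vc$cohort_path, read_cohort,
                                  "enrichment", base_dir),
        thresholds = th)
    })
    names(reports) <- vapply(config$variants, function(vc)
      vc$id %||% vc$protein_change, character(1))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(reports,
                      file.path(config$out_dir, "classification.json"))
    write_report_tsv(reports,
                     file.path(config$out_dir, "evidence.tsv"))
    return(invisible(reports))
  }
  reports
}

`%||%` <- function(x, y) if (is.null(x)) y else x

report_to_list <- function(report) {
  list(
    variant = unclass(report$variant),
    tier = report$classification$tier,
    rule_fired = report$classification$rule_fired,
    evidence = lapply(report$evidence, function(e)
      list(code = e$code, direction = e$direction, strength = e$strength,
           met = e$met, rationale = e$rationale)),
    association = if (!is.null(report$association))
      list(table = unclass(report$association$table),
           or = report$association$or_point,
           ci_lower = report$association$ci_lower,
           ci_upper = report$association$ci_upper,
           confidence_level = report$association$confidence_level,
           correction_applied = report$association$correction_applied),
    escalations = report$escalations)
}

#' Write classification reports
#'
#' `write_report_json()` emits the full per-variant report (evidence trace,
#' association, tier, escalations); `write_report_tsv()` emits a flat
#' evidence table (variant, code, strength, met, rationale).
#'
#' @param reports Named list of `variant_report`s from
#'   [run_classification()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(reports, path) {
  jsonlite::write_json(lapply(reports, report_to_list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_report_tsv <- function(reports, path) {
  rows <- do.call(rbind, lapply(names(reports), function(v) {
    do.call(rbind, lapply(reports[[v]]$evidence, function(e)
      data.frame(variant = v, code = e$code, direction = e$direction,
                 strength = e$strength, met = e$met,
                 rationale = e$rationale, stringsAsFactors = FALSE)))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
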