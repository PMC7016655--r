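#' @keywords internal
"_PACKAGE"

# ---- controlled vocabularies -------------------------------------------------

CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice",
                  "synonymous", "other")
INHERITANCE_MODES <- c("autosomal_recessive", "autosomal_dominant", "x_linked")
GENOTYPES   <- c("hom_ref", "het", "hom_alt", "missing")
SEXES       <- c("male", "female", "unknown")
AFFECTIONS  <- c("affected", "unaffected", "unknown")
DIAGNOSIS_GROUPS <- c("lca_eord", "other_ird")
STRENGTHS   <- c("stand_alone", "very_strong", "strong", "moderate",
                 "supporting")
TIERS <- c("pathogenic", "likely_pathogenic", "uncertain_significance",
           "likely_benign", "benign")

#' ACMG/AMP criterion codes recognised by the package
#'
#' The full coded vocabulary of the ACMG/AMP framework: PVS1, PS1-PS4,
#' PM1-PM6, PP1-PP5 on the pathogenic side and BA1, BS1-BS4, BP1-BP7 on the
#' benign side.
#'
#' @return Character vector of criterion codes.
#' @export
#' @examples
#' acmg_codes()
acmg_codes <- function() {
  c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
    "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
}

#' Direction and default strength of an ACMG/AMP criterion code
#'
#' Direction follows the code prefix (`P*` pathogenic, `B*` benign).  Default
#' strengths follow the guideline: PVS1 very strong; PS* strong; PM* moderate;
#' PP* supporting; BA1 stand-alone; BS* strong; BP* supporting.
#'
#' @param code A single criterion code, e.g. `"PM2"`.
#' @return For [acmg_direction()], `"pathogenic"` or `"benign"`; for
#'   [acmg_default_strength()], one of `"stand_alone"`, `"very_strong"`,
#'   `"strong"`, `"moderate"`, `"supporting"`.
#' @export
#' @examples
#' acmg_direction("PS4")
#' acmg_default_strength("PM2")
acmg_direction <- function(code) {
  code <- match.arg(code, acmg_codes())
  if (startsWith(code, "B")) "benign" else "pathogenic"
}

#' @rdname acmg_direction
#' @export
acmg_default_strength <- function(code) {
  code <- match.arg(code, acmg_codes())
  prefix <- substr(code, 1, 2)
  switch(prefix,
         PV = "very_strong",
         PS = "strong",
         PM = "moderate",
         PP = "supporting",
         BA = "stand_alone",
         BS = "strong",
         BP = "supporting",
         stop("unrecognised code prefix: ", code))
}

# ---- VariantRecord -----------------------------------------------------------

#' Create a variant record
#'
#' A minimal description of one candidate variant: gene symbol, transcript,
#' HGVS c. and p. notation, consequence class and the inheritance mode of the
#' associated disease.  The classification machinery in this package exercises
#' the autosomal-recessive path.
#'
#' @param gene Gene symbol, e.g. `"RPE65"`.
#' @param transcript Transcript identifier, e.g. `"NM_000329.3"`.
#' @param cdna_change HGVS cDNA notation; must start with `"c."`.
#' @param protein_change HGVS protein notation; must start with `"p."`.
#' @param consequence One of `r paste0('"', CONSEQUENCES, '"', collapse = ", ")`.
#' @param inheritance_mode One of `"autosomal_recessive"`,
#'   `"autosomal_dominant"`, `"x_linked"`.
#' @return An object of class `variant_record`.
#' @export
#' @examples
#' variant_record("RPE65", "NM_000329.3", "c.247T>C", "p.Phe83Leu", "missense")
variant_record <- function(gene, transcript, cdna_change, protein_change,
                           consequence,
                           inheritance_mode = "autosomal_recessive") {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene),
            is.character(transcript), length(transcript) == 1L)
  if (!startsWith(cdna_change, "c."))
    stop("cdna_change must start with 'c.': got '", cdna_change, "'")
  if (!startsWith(protein_change, "p."))
    stop("protein_change must start with 'p.': got '", protein_change, "'")
  consequence <- match.arg(consequence, CONSEQUENCES)
  inheritance_mode <- match.arg(inheritance_mode, INHERITANCE_MODES)
  structure(
    list(gene = gene, transcript = transcript, cdna_change = cdna_change,
         protein_change = protein_change, consequence = consequence,
         inheritance_mode = inheritance_mode),
    class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant_record> %s %s:%s (%s), %s, %s\n",
              x$gene, x$transcript, x$cdna_change, x$protein_change,
              x$consequence, x$inheritance_mode))
  invisible(x)
}

# ---- EvidenceItem ------------------------------------------------------------

#' Create an ACMG/AMP evidence item
#'
#' One criterion with its direction, strength, met flag and a free-text
#' rationale.  Direction is always derived from the code; the strength
#' defaults to the guideline strength for the code but may be overridden
#' (strength modulation, e.g. PP1 applied at moderate when many families
#' segregate).
#'
#' @param code Criterion code from [acmg_codes()].
#' @param met Logical: is the criterion satisfied?
#' @param rationale Free-text justification recorded in reports.
#' @param strength Strength bucket; defaults to the code's guideline strength.
#' @return An object of class `evidence_item`.
#' @export
#' @examples
#' evidence_item("PM2", met = TRUE, rationale = "absent from all databases")
#' evidence_item("PP1", met = TRUE, strength = "moderate",
#'               rationale = "co-segregation in many families")
evidence_item <- function(code, met, rationale = "",
                          strength = acmg_default_strength(code)) {
  code <- match.arg(code, acmg_codes())
  strength <- match.arg(strength, STRENGTHS)
  stopifnot(is.logical(met), length(met) == 1L, !is.na(met),
            is.character(rationale), length(rationale) == 1L)
  structure(
    list(code = code, direction = acmg_direction(code), strength = strength,
         met = met, rationale = rationale),
    class = "evidence_item")
}

#' @export
print.evidence_item <- function(x, ...) {
  cat(sprintf("<evidence_item> %s [%s/%s] %s%s\n",
              x$code, x$direction, x$strength,
              if (x$met) "MET" else "not met",
              if (nzchar(x$rationale)) paste0(" - ", x$rationale) else ""))
  invisible(x)
}

#' @export
format.evidence_item <- function(x, ...) {
  sprintf("%s(%s,%s,%s)", x$code, x$direction, x$strength, x$met)
}

# ---- Individual & Pedigree ---------------------------------------------------

#' Create a pedigree member
#'
#' @param individual_id,family_id Case-sensitive identifier strings.
#' @param father_id,mother_id Parent identifiers or `NULL` for founders.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param affection `"affected"`, `"unaffected"` or `"unknown"`.
#' @param genotype Genotype at the declared candidate variant: `"hom_ref"`,
#'   `"het"`, `"hom_alt"` or `"missing"`.
#' @return An object of class `ped_individual`.
#' @export
individual <- function(individual_id, family_id, father_id = NULL,
                       mother_id = NULL, sex = "unknown",
                       affection = "unknown", genotype = "missing") {
  stopifnot(is.character(individual_id), nzchar(individual_id),
            is.character(family_id), nzchar(family_id))
  sex <- match.arg(sex, SEXES)
  affection <- match.arg(affection, AFFECTIONS)
  genotype <- match.arg(genotype, GENOTYPES)
  structure(
    list(individual_id = individual_id, family_id = family_id,
         father_id = father_id, mother_id = mother_id, sex = sex,
         affection = affection, genotype = genotype),
    class = "ped_individual")
}

#' Create a pedigree
#'
#' Validates that every member carries the family id, that member ids are
#' unique, that parent ids resolve within the family (or are `NULL`), and
#' that the parent graph is acyclic (no individual is its own ancestor).
#'
#' @param family_id Family identifier.
#' @param members List of [individual()] objects.
#' @return An object of class `pedigree`.
#' @export
pedigree <- function(family_id, members) {
  stopifnot(is.character(family_id), nzchar(family_id), is.list(members),
            length(members) >= 1L)
  ids <- vapply(members, function(m) m$individual_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicated individual id within family '", family_id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (m in members) {
    if (m$family_id != family_id)
      stop("member '", m$individual_id, "' carries family id '", m$family_id,
           "', expected '", family_id, "'")
    for (pid in c(m$father_id, m$mother_id)) {
      if (!is.null(pid) && !pid %in% ids)
        stop("parent id '", pid, "' of '", m$individual_id,
             "' not found in family '", family_id, "'")
    }
  }
  # cycle check: walk ancestors of each member
  parent_of <- stats::setNames(
    lapply(members, function(m) c(m$father_id, m$mother_id)), ids)
  for (id in ids) {
    seen <- character()
    frontier <- parent_of[[id]]
    while (length(frontier)) {
      if (id %in% frontier)
        stop("parental cycle detected at individual '", id,
             "' in family '", family_id, "'")
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(parent_of[frontier])), seen)
    }
  }
  structure(list(family_id = family_id, members = members),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> family %s, %d members\n",
              x$family_id, length(x$members)))
  df <- pedigree_to_df(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Flatten a pedigree into a data frame
#'
#' @param ped A [pedigree()] object.
#' @return A data frame with one row per member.
#' @export
pedigree_to_df <- function(ped) {
  do.call(rbind, lapply(ped$members, function(m) {
    data.frame(family_id = m$family_id, individual_id = m$individual_id,
               father_id = if (is.null(m$father_id)) NA_character_ else m$father_id,
               mother_id = if (is.null(m$mother_id)) NA_character_ else m$mother_id,
               sex = m$sex, affection = m$affection, genotype = m$genotype,
               stringsAsFactors = FALSE)
  }))
}

# ---- CohortProband -----------------------------------------------------------

#' Build a cohort proband table
#'
#' The case-control analysis unit is one proband per family.  This
#' constructor validates the column set, the controlled vocabularies and the
#' one-proband-per-family invariant.
#'
#' @param df Data frame with columns `proband_id`, `family_id`,
#'   `diagnosis_group` (`"lca_eord"` or `"other_ird"`) and `genotype`.
#' @return The validated data frame with class `cohort` prepended.
#' @export
cohort <- function(df) {
  required <- c("proband_id", "family_id", "diagnosis_group", "genotype")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df)) {
    bad_group <- setdiff(unique(df$diagnosis_group), DIAGNOSIS_GROUPS)
    if (length(bad_group))
      stop("unknown diagnosis_group label(s): ",
           paste(bad_group, collapse = ", "),
           "; allowed: ", paste(DIAGNOSIS_GROUPS, collapse = ", "))
    bad_gt <- setdiff(unique(df$genotype), GENOTYPES)
    if (length(bad_gt))
      stop("unknown genotype label(s): ", paste(bad_gt, collapse = ", "),
           "; allowed: ", paste(GENOTYPES, collapse = ", "))
    if (anyDuplicated(df$family_id))
      stop("duplicated family_id in cohort (one proband per family): ",
           paste(unique(df$family_id[duplicated(df$family_id)]),
                 collapse = ", "))
  }
  class(df) <- c("cohort", class(df))
  df
}
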