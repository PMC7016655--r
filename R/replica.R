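# Worked example: two RPE65 missense variants (NM_000329.3 c.247T>C
# p.Phe83Leu and c.560G>A p.Gly187Glu) in a Brazilian inherited-retinal-
# dystrophy cohort of 513 families (93 LCA/EORD, 420 other IRD).  The
# population-frequency, predictor and gene-summary tables ship as TSV files
# under extdata; the cohort and pedigrees are rebuilt in code from the
# published per-family counts.

REPLICA_VARIANTS <- c("p.Phe83Leu", "p.Gly187Glu")

replica_path <- function(file) {
  path <- system.file("extdata", file, package = "acmgrare")
  if (!nzchar(path)) stop("bundled table not found: ", file)
  path
}

#' The two RPE65 variants of the worked example
#'
#' @return A named list of two [variant_record()]s.
#' @export
rpe65_variants <- function() {
  list(
    "p.Phe83Leu" = variant_record("RPE65", "NM_000329.3", "c.247T>C",
                                  "p.Phe83Leu", "missense"),
    "p.Gly187Glu" = variant_record("RPE65", "NM_000329.3", "c.560G>A",
                                   "p.Gly187Glu", "missense"))
}

#' Bundled population-frequency records for the worked example
#'
#' Queried databases: gnomAD, ExAC, ESP, 1000 Genomes and ABraOM.
#' p.Phe83Leu is absent from all five; p.Gly187Glu was seen in two gnomAD
#' heterozygotes (2 of 251,106 alleles) and one ExAC heterozygote.
#'
#' @param variant `"p.Phe83Leu"` or `"p.Gly187Glu"`.
#' @return A `popfreq_records` data frame.
#' @export
rpe65_frequency_records <- function(variant = REPLICA_VARIANTS) {
  variant <- match.arg(variant)
  file <- if (variant == "p.Phe83Leu") "rpe65_popfreq_phe83leu.tsv"
          else "rpe65_popfreq_gly187glu.tsv"
  read_frequency_records(replica_path(file))
}

#' Bundled 16-tool predictor profiles for the worked example
#'
#' @param variant `"p.Phe83Leu"` or `"p.Gly187Glu"`.
#' @return A named list (tool -> raw value) usable with [evaluate_pp3()].
#' @export
rpe65_predictor_profile <- function(variant = REPLICA_VARIANTS) {
  variant <- match.arg(variant)
  read_predictor_profiles(replica_path("rpe65_predictors.tsv"))[[variant]]
}

#' Bundled gene-level variant summaries for RPE65
#'
#' ClinVar/UniProt report 69 pathogenic RPE65 variants of which 52 are
#' missense; HGMD lists 191 disease-causing variants of which 103 are
#' missense; Varsome classifies 8 of 93 catalogued variants as benign.
#'
#' @return A `gene_summaries` data frame.
#' @export
rpe65_gene_summaries <- function() {
  read_gene_summaries(replica_path("rpe65_gene_summaries.tsv"))
}

#' Replica pedigrees of the segregating families
#'
#' Seven nuclear families: A-D carry p.Phe83Leu (five affected homozygotes
#' in total), E-G carry p.Gly187Glu (seven affected homozygotes).  Genotyped
#' affected members per family follow the published clinical table (A and F
#' two each, G three); parents are heterozygous unaffected, and each family
#' includes at least one unaffected carrier or non-carrier relative.  The
#' full published pedigrees are only partially recoverable, so these
#' structures are representative synthetic reconstructions at the level the
#' study reports, not exact copies.
#'
#' @param variant `"p.Phe83Leu"` (families A-D), `"p.Gly187Glu"` (families
#'   E-G) or `"all"`.
#' @return A list of [pedigree()] objects.
#' @export
replica_pedigrees <- function(variant = c(REPLICA_VARIANTS, "all")) {
  variant <- match.arg(variant)
  fam <- function(id, affected_ids, unaffected) {
    members <- list(
      individual("I:1", id, sex = "male", affection = "unaffected",
                 genotype = "het"),
      individual("I:2", id, sex = "female", affection = "unaffected",
                 genotype = "het"))
    for (aid in affected_ids)
      members <- c(members, list(individual(
        aid, id, father_id = "I:1", mother_id = "I:2",
        affection = "affected", genotype = "hom_alt")))
    for (u in names(unaffected))
      members <- c(members, list(individual(
        u, id, father_id = "I:1", mother_id = "I:2",
        affection = "unaffected", genotype = unaffected[[u]])))
    pedigree(id, members)
  }
  phe <- list(
    fam("A", c("II:1", "II:4"), c("II:2" = "het", "II:3" = "hom_ref")),
    fam("B", "II:1", c("II:2" = "het")),
    fam("C", "II:1", c("II:2" = "het")),
    fam("D", "II:1", c("II:2" = "het")))
  gly <- list(
    fam("E", c("II:2", "II:4"), c("II:1" = "hom_ref")),
    fam("F", c("II:1", "II:8"), c("II:3" = "het")),
    fam("G", c("II:7", "II:8", "II:23"), c("II:1" = "het")))
  switch(variant, "p.Phe83Leu" = phe, "p.Gly187Glu" = gly,
         all = c(phe, gly))
}

#' Replica case-control cohort
#'
#' 513 probands (one per family): 93 LCA/EORD and 420 other-IRD families.
#' For the chosen variant, the homozygous case probands are the segregating
#' families (A-D for p.Phe83Leu, E-G for p.Gly187Glu); every other proband
#' is homozygous reference, since neither variant was observed, even
#' heterozygously, in any other proband of the cohort.  Deterministic: no
#' randomness is involved.
#'
#' @param variant `"p.Phe83Leu"` or `"p.Gly187Glu"`.
#' @return A [cohort()] data frame of 513 rows.
#' @export
#' @examples
#' build_table(replica_cohort("p.Phe83Leu"))  # a=4, b=89, c=0, d=420
replica_cohort <- function(variant = REPLICA_VARIANTS) {
  variant <- match.arg(variant)
  exposed_fams <- if (variant == "p.Phe83Leu") c("A", "B", "C", "D")
                  else c("E", "F", "G")
  n_other_cases <- 93L - length(exposed_fams)
  case_fams <- c(exposed_fams, sprintf("CASE%03d", seq_len(n_other_cases)))
  ctrl_fams <- sprintf("CTRL%03d", seq_len(420L))
  cohort(data.frame(
    proband_id = paste0(c(case_fams, ctrl_fams), "-II:1"),
    family_id = c(case_fams, ctrl_fams),
    diagnosis_group = rep(c("lca_eord", "other_ird"), c(93L, 420L)),
    genotype = c(rep("hom_alt", length(exposed_fams)),
                 rep("hom_ref", 513L - length(exposed_fams))),
    stringsAsFactors = FALSE))
}

#' Cohort specification matching the replica marginals
#'
#' Convenience preset for [generate_cohort()]: 93 case and 420 control
#' families with the variant's homozygote count planted in the case group
#' and none in the controls.
#'
#' @param variant `"p.Phe83Leu"` or `"p.Gly187Glu"`.
#' @param seed Seed passed through to [cohort_spec()].
#' @return A [cohort_spec()].
#' @export
replica_cohort_spec <- function(variant = REPLICA_VARIANTS, seed = 1L) {
  variant <- match.arg(variant)
  cohort_spec(n_case_families = 93L, n_control_families = 420L,
              n_exposed_cases = if (variant == "p.Phe83Leu") 4L else 3L,
              n_exposed_controls = 0L, carrier_frequency = 0,
              penetrance = 1, seed = seed)
}
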