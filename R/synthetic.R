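# Synthetic cohorts, pedigrees and predictor profiles with the statistical
# structure the analysis assumes: one proband per family, planted homozygous
# carriers in a recessive-disease case group, nuclear families with
# carrier-by-carrier matings and Mendelian transmission.  Planted counts are
# exact (not probabilistic), so 2x2 table cells are recoverable from the
# specification; all randomness is seeded.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Specification of a synthetic case-control cohort
#'
#' @param n_case_families,n_control_families Family (= proband) counts for
#'   the two diagnosis groups.  Defaults follow the worked
#'   inherited-retinal-dystrophy cohort: 93 LCA/EORD and 420 other-IRD
#'   families.
#' @param n_exposed_cases,n_exposed_controls Exact numbers of probands per
#'   group planted as homozygous for the candidate variant.
#' @param family_structure Named probability vector over sibship sizes used
#'   when generating pedigrees for exposed families.
#' @param carrier_frequency Probability that an unexposed proband is a
#'   heterozygous carrier (0 reproduces a cohort in which the variant is
#'   seen only in the planted homozygotes).
#' @param penetrance Probability that a homozygote is affected (default 1:
#'   full penetrance).
#' @param seed Integer seed for all randomness in [generate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_case_families = 93L, n_control_families = 420L,
                        n_exposed_cases = 0L, n_exposed_controls = 0L,
                        family_structure = c("2" = 0.5, "3" = 0.3,
                                             "4" = 0.2),
                        carrier_frequency = 0, penetrance = 1,
                        seed = 1L) {
  stopifnot(n_case_families >= 0, n_control_families >= 0,
            carrier_frequency >= 0, carrier_frequency <= 1,
            penetrance >= 0, penetrance <= 1,
            abs(sum(family_structure) - 1) < 1e-8)
  if (n_exposed_cases > n_case_families)
    stop("infeasible spec: n_exposed_cases exceeds n_case_families")
  if (n_exposed_controls > n_control_families)
    stop("infeasible spec: n_exposed_controls exceeds n_control_families")
  structure(
    list(n_case_families = as.integer(n_case_families),
         n_control_families = as.integer(n_control_families),
         n_exposed_cases = as.integer(n_exposed_cases),
         n_exposed_controls = as.integer(n_exposed_controls),
         family_structure = family_structure,
         carrier_frequency = carrier_frequency,
         penetrance = penetrance, seed = as.integer(seed)),
    class = "cohort_spec")
}

simulate_nuclear_family <- function(family_id, proband_id, n_children,
                                    penetrance) {
  # carrier-by-carrier mating; proband forced hom_alt/affected, remaining
  # children drawn by Mendelian transmission from het x het
  members <- list(
    individual("I:1", family_id, sex = "male", affection = "unaffected",
               genotype = "het"),
    individual("I:2", family_id, sex = "female", affection = "unaffected",
               genotype = "het"))
  child_gts <- c("hom_alt",
                 if (n_children > 1)
                   sample(c("hom_ref", "het", "hom_alt"), n_children - 1,
                          replace = TRUE, prob = c(0.25, 0.5, 0.25)))
  for (i in seq_len(n_children)) {
    gt <- child_gts[[i]]
    affected <- gt == "hom_alt" &&
      (penetrance >= 1 || stats::runif(1) < penetrance)
    members <- c(members, list(individual(
      if (i == 1L) proband_id else sprintf("II:%d", i),
      family_id, father_id = "I:1", mother_id = "I:2",
      sex = sample(c("male", "female"), 1),
      affection = if (affected) "affected" else "unaffected",
      genotype = gt)))
  }
  pedigree(family_id, members)
}

#' Generate a synthetic cohort (and pedigrees for exposed families)
#'
#' Exactly `n_exposed_cases` case probands and `n_exposed_controls` control
#' probands are planted as homozygotes; every exposed family also receives a
#' nuclear pedigree (heterozygous parents, proband homozygous affected,
#' siblings by Mendelian transmission).  Unexposed probands are heterozygous
#' carriers with probability `carrier_frequency`, otherwise homozygous
#' reference.  Output is deterministic for a fixed spec (including its
#' seed).
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `cohort` (a [cohort()] data frame) and
#'   `pedigrees` (list of [pedigree()] objects for exposed families).
#' @export
#' @examples
#' out <- generate_cohort(cohort_spec(n_exposed_cases = 4, seed = 7))
#' build_table(out$cohort)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    make_group <- function(prefix, n, n_exposed, group) {
      if (n == 0L) return(NULL)
      fam_ids <- sprintf("%s%03d", prefix, seq_len(n))
      exposed_idx <- if (n_exposed > 0) sort(sample.int(n, n_exposed))
                     else integer(0)
      genotype <- ifelse(
        seq_len(n) %in% exposed_idx, "hom_alt",
        ifelse(stats::runif(n) < spec$carrier_frequency, "het", "hom_ref"))
      data.frame(proband_id = paste0(fam_ids, "-II:1"),
                 family_id = fam_ids, diagnosis_group = group,
                 genotype = genotype, stringsAsFactors = FALSE)
    }
    cases <- make_group("CASE", spec$n_case_families,
                        spec$n_exposed_cases, "lca_eord")
    controls <- make_group("CTRL", spec$n_control_families,
                           spec$n_exposed_controls, "other_ird")
    cohort_df <- cohort(rbind(cases, controls))
    exposed <- cohort_df[cohort_df$genotype == "hom_alt", , drop = FALSE]
    sizes <- as.integer(names(spec$family_structure))
    pedigrees <- lapply(seq_len(nrow(exposed)), function(i) {
      n_children <- if (length(sizes) == 1L) sizes
                    else sample(sizes, 1, prob = spec$family_structure)
      simulate_nuclear_family(exposed$family_id[[i]],
                              exposed$proband_id[[i]],
                              n_children, spec$penetrance)
    })
    list(cohort = cohort_df, pedigrees = pedigrees)
  })
}

#' Generate null cohorts for calibration studies
#'
#' Exposure (homozygosity) is drawn independently of diagnosis group with
#' probability `exposure_prob`, so any association found downstream is a
#' false positive.  Per-replicate seeds are derived reproducibly from the
#' master seed.
#'
#' @param n_reps Number of replicate cohorts.
#' @param n_families Probands per cohort.
#' @param case_fraction Fraction of probands in the case group.
#' @param exposure_prob Per-proband probability of homozygosity.
#' @param seed Master seed.
#' @return A list of `n_reps` [cohort()] data frames.
#' @export
generate_null_cohorts <- function(n_reps, n_families, case_fraction,
                                  exposure_prob, seed = 1L) {
  stopifnot(n_reps >= 1, n_families >= 1,
            case_fraction >= 0, case_fraction <= 1,
            exposure_prob >= 0, exposure_prob <= 1)
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_reps))
  n_cases <- round(case_fraction * n_families)
  lapply(seq_len(n_reps), function(r) {
    with_seed(rep_seeds[[r]], {
      fam_ids <- sprintf("NULL%05d", seq_len(n_families))
      genotype <- ifelse(stats::runif(n_families) < exposure_prob,
                         "hom_alt", "hom_ref")
      cohort(data.frame(
        proband_id = paste0(fam_ids, "-P"), family_id = fam_ids,
        diagnosis_group = rep(c("lca_eord", "other_ird"),
                              c(n_cases, n_families - n_cases)),
        genotype = genotype, stringsAsFactors = FALSE))
    })
  })
}

#' Generate a synthetic 16-tool predictor profile
#'
#' Each tool in the canonical panel emits a value on the ground-truth side
#' with probability `1 - noise`: categorical tools emit a label on that
#' side, numeric tools draw a score uniformly from the side of their cutoff.
#'
#' @param ground_truth `"deleterious_like"` or `"benign_like"`.
#' @param noise Per-tool probability of emitting the opposite-side value
#'   (in \[0, 0.5\]).
#' @param seed Integer seed.
#' @return A named list usable with [evaluate_pp3()] / [evaluate_bp4()].
#' @export
#' @examples
#' evaluate_pp3(generate_predictor_profile("deleterious_like", 0, seed = 1))
generate_predictor_profile <- function(ground_truth = c("deleterious_like",
                                                        "benign_like"),
                                       noise = 0, seed = 1L) {
  ground_truth <- match.arg(ground_truth)
  stopifnot(noise >= 0, noise <= 0.5)
  thresholds <- default_threshold_table()
  del_label <- list(
    PolyPhen2 = "Probably damaging", SIFT = "Damaging",
    PROVEAN = "Damaging", LRT = "Deleterious",
    MutationTaster = "Disease-causing", MutationAssessor = "Medium impact",
    FATHMM = "Damaging", `FATHMM-MKL` = "Damaging", `M-CAP` = "Damaging",
    MetaSVM = "Damaging", MetaLR = "Damaging")
  ben_label <- list(
    PolyPhen2 = "Benign", SIFT = "Tolerated", PROVEAN = "Neutral",
    LRT = "Neutral", MutationTaster = "Polymorphism",
    MutationAssessor = "Neutral", FATHMM = "Tolerated",
    `FATHMM-MKL` = "Tolerated", `M-CAP` = "Tolerated",
    MetaSVM = "Tolerated", MetaLR = "Tolerated")
  numeric_hi <- list(DANN = c(0.9, 1), CADD = c(20, 40),
                     PhyloP20way = c(0.5, 1.199), PhyloP100way = c(2, 10),
                     GERP_RS = c(4, 6.17))
  numeric_lo <- list(DANN = c(0, 0.9), CADD = c(0, 20),
                     PhyloP20way = c(-3, 0.5), PhyloP100way = c(-5, 2),
                     GERP_RS = c(-5, 4))
  with_seed(seed, {
    profile <- lapply(PREDICTOR_TOOLS, function(tool) {
      damaging_side <- (ground_truth == "deleterious_like")
      if (noise > 0 && stats::runif(1) < noise)
        damaging_side <- !damaging_side
      if (thresholds[[tool]]$kind == "categorical") {
        if (damaging_side) del_label[[tool]] else ben_label[[tool]]
      } else {
        rng <- if (damaging_side) numeric_hi[[tool]] else numeric_lo[[tool]]
        # keep strictly inside the open side of the cutoff
        stats::runif(1, rng[[1]] + 1e-6, rng[[2]] - 1e-6)
      }
    })
    stats::setNames(profile, PREDICTOR_TOOLS)
  })
}
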