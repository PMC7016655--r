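# Independent oracles, coded directly from the defining formulas and kept
# separate from the package implementation paths they check.

# Odds ratio and Wald interval by direct transcription: correction applied
# cell-wise, OR as a ratio of odds, bounds as OR * exp(+-z*SE).
oracle_or_ci <- function(a, b, c, d, level) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  odds_case <- a / b
  odds_ctrl <- c / d
  or <- odds_case / odds_ctrl
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm((1 + level) / 2)
  list(or = or, lower = or * exp(-z * se), upper = or * exp(z * se))
}

# Five-tier verdict as one flat boolean expression per side.
oracle_tier <- function(vs, s, m, p, ba, bs, bp) {
  pathogenic <-
    (vs >= 1 && (s >= 1 || m >= 2 || (m >= 1 && p >= 1) || p >= 2)) ||
    s >= 2 ||
    (s >= 1 && (m >= 3 || (m >= 2 && p >= 2) || (m >= 1 && p >= 4)))
  likely_path <-
    (vs >= 1 && m >= 1) || (s >= 1 && m >= 1) || (s >= 1 && p >= 2) ||
    m >= 3 || (m >= 2 && p >= 2) || (m >= 1 && p >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs >= 1 && bp >= 1) || bp >= 2
  path_side <- pathogenic || likely_path
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return("uncertain_significance")
  if (pathogenic) return("pathogenic")
  if (likely_path) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_benign) return("likely_benign")
  "uncertain_significance"
}

# Severity scale used by monotonicity checks (higher = more pathogenic).
tier_rank <- function(tier) {
  match(tier, c("benign", "likely_benign", "uncertain_significance",
                "likely_pathogenic", "pathogenic"))
}

# Shared tiny fixtures ---------------------------------------------------

nuclear_ped_lines <- function(fid = "FAM1") {
  c(paste(fid, "F", "0", "0", "1", "1", "0/1"),
    paste(fid, "M", "0", "0", "2", "1", "0/1"),
    paste(fid, "C1", "F", "M", "2", "2", "1/1"),
    paste(fid, "C2", "F", "M", "1", "2", "1/1"))
}

make_cohort_df <- function(n_cases, n_controls, exposed_cases = 0,
                           exposed_controls = 0) {
  n <- n_cases + n_controls
  ids <- sprintf("F%04d", seq_len(n))
  genotype <- rep("hom_ref", n)
  if (exposed_cases > 0) genotype[seq_len(exposed_cases)] <- "hom_alt"
  if (exposed_controls > 0)
    genotype[n_cases + seq_len(exposed_controls)] <- "hom_alt"
  cohort(data.frame(
    proband_id = sprintf("%s-P", ids), family_id = ids,
    diagnosis_group = rep(c("lca_eord", "other_ird"),
                          c(n_cases, n_controls)),
    genotype = genotype, stringsAsFactors = FALSE))
}
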