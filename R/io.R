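# Readers/writers for the tabular and pedigree formats the pipeline touches.
# PED dialect: whitespace (tab or space) delimited, PLINK affection coding
# (1 = unaffected, 2 = affected, 0 or -9 = unknown), founders coded "0".

GT_STRINGS <- c("0/0" = "hom_ref", "0/1" = "het", "1/0" = "het",
                "1/1" = "hom_alt", "./." = "missing")
GT_DOSAGES <- c("0" = "hom_ref", "1" = "het", "2" = "hom_alt",
                "NA" = "missing", "." = "missing")

decode_genotype <- function(token) {
  if (token %in% names(GT_STRINGS)) return(unname(GT_STRINGS[[token]]))
  if (token %in% names(GT_DOSAGES)) return(unname(GT_DOSAGES[[token]]))
  stop("unrecognised genotype encoding '", token,
       "' (expected 0/0, 0/1, 1/1, ./. or dosage 0, 1, 2, NA)")
}

encode_genotype <- function(genotype) {
  switch(genotype,
         hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.",
         stop("unknown genotype '", genotype, "'"))
}

decode_affection <- function(token, line = NA) {
  switch(token,
         "1" = "unaffected",
         "2" = "affected",
         "0" = "unknown",
         "-9" = "unknown",
         stop("invalid affection code '", token, "'",
              if (!is.na(line)) paste0(" at line ", line) else "",
              " (allowed: 1, 2, 0, -9)"))
}

decode_sex <- function(token) {
  switch(token, "1" = "male", "2" = "female", "unknown")
}

#' Parse pedigrees from PED-format text
#'
#' Reads the standard 6-column PED layout (family id, individual id, father
#' id, mother id, sex, affection) plus one genotype column for the declared
#' candidate variant.  Tab and space delimiters are both accepted; unknown
#' parents (`"0"`) become `NULL`; genotypes may be encoded as `0/0`, `0/1`,
#' `1/1`, `./.` or as dosages `0`, `1`, `2`, `NA`.
#'
#' @param text PED content as a single string, a character vector of lines,
#'   or a file path (detected by existence on disk).
#' @param genotype_column 1-based column index holding the genotype
#'   (default 7, immediately after the six pedigree columns).
#' @return A list of [pedigree()] objects, one per family id, in order of
#'   first appearance.
#' @export
#' @examples
#' ped <- parse_ped(c("FAM1 F 0 0 1 1 0/1",
#'                    "FAM1 M 0 0 2 1 0/1",
#'                    "FAM1 C F M 2 2 1/1"))
#' ped[[1]]
parse_ped <- function(text, genotype_column = 7L) {
  lines <- if (length(text) == 1L && file.exists(text)) readLines(text)
           else unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(fields) < max(6L, genotype_column))
      stop("malformed PED line ", i, ": expected at least ",
           max(6L, genotype_column), " columns, found ", length(fields))
    rows[[i]] <- list(
      family_id = fields[[1]], individual_id = fields[[2]],
      father_id = if (fields[[3]] == "0") NULL else fields[[3]],
      mother_id = if (fields[[4]] == "0") NULL else fields[[4]],
      sex = decode_sex(fields[[5]]),
      affection = decode_affection(fields[[6]], line = i),
      genotype = decode_genotype(fields[[genotype_column]]))
  }
  fam_ids <- vapply(rows, `[[`, character(1), "family_id")
  lapply(unique(fam_ids), function(fid) {
    members <- lapply(rows[fam_ids == fid], function(r) {
      individual(r$individual_id, r$family_id, r$father_id, r$mother_id,
                 r$sex, r$affection, r$genotype)
    })
    pedigree(fid, members)
  })
}

#' Write pedigrees as PED-format text
#'
#' Inverse of [parse_ped()]: emits 6 pedigree columns plus a `0/0`-style
#' genotype column.
#'
#' @param pedigrees A list of [pedigree()] objects.
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`), the character
#'   vector of PED lines.
#' @export
write_ped <- function(pedigrees, path = NULL) {
  lines <- unlist(lapply(pedigrees, function(ped) {
    vapply(ped$members, function(m) {
      paste(m$family_id, m$individual_id,
            if (is.null(m$father_id)) "0" else m$father_id,
            if (is.null(m$mother_id)) "0" else m$mother_id,
            switch(m$sex, male = "1", female = "2", "0"),
            switch(m$affection, unaffected = "1", affected = "2", "0"),
            encode_genotype(m$genotype),
            sep = "\t")
    }, character(1))
  }))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a cohort proband table
#'
#' Expects a TSV with columns `proband_id`, `family_id`, `diagnosis_group`
#' and `genotype`; enforces one proband per family and the controlled
#' vocabularies for group and genotype labels.
#'
#' @param table TSV content (single string or lines) or a file path.
#' @return A validated [cohort()] data frame (possibly 0-row).
#' @export
read_cohort <- function(table) {
  txt <- if (length(table) == 1L && file.exists(table)) readLines(table)
         else unlist(strsplit(table, "\n", fixed = TRUE))
  df <- utils::read.delim(text = paste(txt, collapse = "\n"), sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  cohort(df)
}

#' @rdname read_cohort
#' @param cohort_df A [cohort()] data frame.
#' @param path Optional output path; when `NULL` the TSV lines are returned.
#' @export
write_cohort <- function(cohort_df, path = NULL) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(as.data.frame(cohort_df), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read population frequency records
#'
#' Expects a TSV with columns `database`, `allele_count`, `allele_number`,
#' `homozygote_count`; the literal `NA` marks "no data" for a database that
#' was queried but holds no record of the variant.
#'
#' @param table TSV content or a file path.
#' @return A data frame of class `popfreq_records`.
#' @export
read_frequency_records <- function(table) {
  txt <- if (length(table) == 1L && file.exists(table)) readLines(table)
         else unlist(strsplit(table, "\n", fixed = TRUE))
  df <- utils::read.delim(text = paste(txt, collapse = "\n"), sep = "\t",
                          stringsAsFactors = FALSE)
  frequency_records(df)
}

#' Validate a population frequency record table
#'
#' @param df Data frame with columns `database`, `allele_count`,
#'   `allele_number`, `homozygote_count` (`NA` = no data).
#' @return The validated data frame with class `popfreq_records`.
#' @export
frequency_records <- function(df) {
  required <- c("database", "allele_count", "allele_number",
                "homozygote_count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("frequency table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("allele_count", "allele_number", "homozygote_count")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("negative ", col, " in frequency table")
  }
  present <- !is.na(df$allele_count)
  if (any(present & (is.na(df$allele_number) | df$allele_number <= 0)))
    stop("allele_number must be > 0 wherever allele_count is present")
  if (any(df$allele_count[present] > df$allele_number[present]))
    stop("allele_count exceeds allele_number")
  both <- present & !is.na(df$homozygote_count)
  if (any(2 * df$homozygote_count[both] > df$allele_count[both]))
    stop("homozygote_count * 2 exceeds allele_count")
  class(df) <- c("popfreq_records", class(df))
  df
}

#' Read predictor score/label profiles
#'
#' Expects a long-format TSV with columns `variant_id`, `tool`, `value`;
#' returns one named list per variant mapping tool name to its raw value
#' (numeric where the string parses as a number, otherwise the label).
#'
#' @param table TSV content or a file path.
#' @return A named list of prediction profiles (named lists keyed by tool).
#' @export
read_predictor_profiles <- function(table) {
  txt <- if (length(table) == 1L && file.exists(table)) readLines(table)
         else unlist(strsplit(table, "\n", fixed = TRUE))
  df <- utils::read.delim(text = paste(txt, collapse = "\n"), sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("variant_id", "tool", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("predictor table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- lapply(split(df, factor(df$variant_id, unique(df$variant_id))),
                function(chunk) {
    vals <- lapply(chunk$value, function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
    stats::setNames(vals, chunk$tool)
  })
  out
}

#' Read gene-level variant count summaries
#'
#' Expects a TSV with columns `source`, `pathogenic_total`,
#' `pathogenic_missense`, `benign_count`, `total_classified` (the last two
#' may be `NA` when the source reports no benign breakdown).
#'
#' @param table TSV content or a file path.
#' @return A data frame of class `gene_summaries`.
#' @export
read_gene_summaries <- function(table) {
  txt <- if (length(table) == 1L && file.exists(table)) readLines(table)
         else unlist(strsplit(table, "\n", fixed = TRUE))
  df <- utils::read.delim(text = paste(txt, collapse = "\n"), sep = "\t",
                          stringsAsFactors = FALSE)
  gene_summaries(df)
}

#' Validate a gene-level variant count summary table
#'
#' @param df Data frame with columns `source`, `pathogenic_total`,
#'   `pathogenic_missense`, `benign_count`, `total_classified`.
#' @return The validated data frame with class `gene_summaries`.
#' @export
gene_summaries <- function(df) {
  required <- c("source", "pathogenic_total", "pathogenic_missense")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("gene summary table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"benign_count" %in% names(df)) df$benign_count <- NA_real_
  if (!"total_classified" %in% names(df)) df$total_classified <- NA_real_
  for (col in c("pathogenic_total", "pathogenic_missense", "benign_count",
                "total_classified")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    if (any(df[[col]] < 0, na.rm = TRUE)) stop("negative ", col)
  }
  if (any(df$pathogenic_missense > df$pathogenic_total, na.rm = TRUE))
    stop("pathogenic_missense exceeds pathogenic_total")
  class(df) <- c("gene_summaries", class(df))
  df
}

#' Read per-sample genotypes for one variant from a minimal VCF
#'
#' Optional genotype source.  Matches a single site by CHROM/POS/REF/ALT and
#' maps each sample's GT field to the package genotype vocabulary.  Requires
#' the `vcfR` package.  Full VCF semantics (INFO parsing, multi-allelic
#' decomposition) are out of scope.
#'
#' @param path Path to an uncompressed VCF file.
#' @param chrom,pos,ref,alt Coordinates and alleles of the candidate variant.
#' @return A data frame with columns `sample_id`, `genotype`.
#' @export
read_genotypes_vcf <- function(path, chrom, pos, ref, alt) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotypes_vcf requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix   # character matrix, one row per site even for single-site files
  hit <- which(fix[, "CHROM"] == chrom &
               as.integer(fix[, "POS"]) == as.integer(pos) &
               fix[, "REF"] == ref & fix[, "ALT"] == alt)
  if (length(hit) != 1L)
    stop("expected exactly one matching site for ", chrom, ":", pos, " ",
         ref, ">", alt, ", found ", length(hit))
  gt <- vcfR::extract.gt(v, element = "GT")[hit, , drop = TRUE]
  genotype <- vapply(gt, function(g) {
    if (is.na(g)) return("missing")
    g <- gsub("|", "/", g, fixed = TRUE)
    decode_genotype(g)
  }, character(1))
  data.frame(sample_id = names(genotype), genotype = unname(genotype),
             stringsAsFactors = FALSE)
}
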