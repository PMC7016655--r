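test_that("PED parsing resolves a nuclear family with founder convention", {
  peds <- parse_ped(nuclear_ped_lines())
  expect_length(peds, 1L)
  ped <- peds[[1]]
  expect_s3_class(ped, "pedigree")
  expect_length(ped$members, 4L)
  df <- pedigree_to_df(ped)
  expect_true(is.na(df$father_id[df$individual_id == "F"]))
  children <- df[df$individual_id %in% c("C1", "C2"), ]
  expect_equal(children$father_id, c("F", "F"))
  expect_equal(children$mother_id, c("M", "M"))
  expect_equal(children$affection, c("affected", "affected"))
  expect_equal(children$genotype, c("hom_alt", "hom_alt"))
  parents <- df[df$individual_id %in% c("F", "M"), ]
  expect_equal(parents$genotype, c("het", "het"))
  expect_equal(parents$affection, c("unaffected", "unaffected"))
})

test_that("PED parsing rejects malformed input with a line reference", {
  expect_error(parse_ped("FAM1 A 0 0 1"), "line 1")
  expect_error(parse_ped("FAM1 A 0 0 1 5 0/1"), "affection")
  expect_error(parse_ped(c("FAM1 A 0 0 1 1 0/1",
                           "FAM1 A 0 0 2 1 0/1")), "duplicated")
  expect_error(parse_ped("FAM1 A 0 0 1 1 0/3"), "genotype")
})

test_that("genotype dosage and allele-pair encodings are equivalent", {
  pair <- parse_ped(c("X A 0 0 1 1 0/0", "X B 0 0 1 1 0/1",
                      "X C 0 0 1 1 1/1", "X D 0 0 1 1 ./."))
  dose <- parse_ped(c("X A 0 0 1 1 0", "X B 0 0 1 1 1",
                      "X C 0 0 1 1 2", "X D 0 0 1 1 NA"))
  expect_identical(pedigree_to_df(pair[[1]])$genotype,
                   pedigree_to_df(dose[[1]])$genotype)
  # tab-delimited input is accepted too
  tabbed <- parse_ped("X\tA\t0\t0\t1\t1\t0/1")
  expect_equal(pedigree_to_df(tabbed[[1]])$genotype, "het")
})

test_that("pedigrees round-trip through PED text", {
  peds <- parse_ped(c(nuclear_ped_lines("FAM1"), nuclear_ped_lines("FAM2")))
  reparsed <- parse_ped(write_ped(peds))
  expect_equal(lapply(reparsed, pedigree_to_df),
               lapply(peds, pedigree_to_df))
})

test_that("pedigree construction rejects inconsistent structures", {
  expect_error(
    pedigree("F1", list(individual("A", "F1", father_id = "GHOST"))),
    "not found")
  expect_error(
    pedigree("F1", list(individual("A", "F2"))), "family id")
  # a parental cycle: A's father is B, B's father is A
  expect_error(
    pedigree("F1", list(individual("A", "F1", father_id = "B"),
                        individual("B", "F1", father_id = "A"))),
    "cycle")
})

test_that("cohort reading enforces the one-proband-per-family unit", {
  tsv <- c("proband_id\tfamily_id\tdiagnosis_group\tgenotype",
           "P1\tF1\tlca_eord\thom_alt",
           "P2\tF2\tother_ird\thom_ref")
  df <- read_cohort(paste(tsv, collapse = "\n"))
  expect_equal(nrow(df), 2L)
  expect_equal(df$diagnosis_group, c("lca_eord", "other_ird"))

  dup <- c(tsv, "P3\tF1\tother_ird\thet")
  expect_error(read_cohort(paste(dup, collapse = "\n")), "family")
  bad <- c(tsv[1], "P1\tF1\tsome_group\thom_alt")
  expect_error(read_cohort(paste(bad, collapse = "\n")),
               "lca_eord, other_ird")
})

test_that("an empty cohort table reads as an empty record list", {
  df <- read_cohort("proband_id\tfamily_id\tdiagnosis_group\tgenotype")
  expect_equal(nrow(df), 0L)
})

test_that("cohort tables round-trip through TSV", {
  df <- make_cohort_df(5, 7, exposed_cases = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(df, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(df))
})

test_that("replica cohort reproduces the published group sizes", {
  df <- replica_cohort("p.Phe83Leu")
  expect_equal(nrow(df), 513L)
  expect_equal(as.vector(table(df$diagnosis_group)[c("lca_eord",
                                                     "other_ird")]),
               c(93L, 420L))
  expect_equal(sum(df$genotype == "hom_alt"), 4L)
})

test_that("variant records validate HGVS prefixes and vocabularies", {
  v <- variant_record("RPE65", "NM_000329.3", "c.247T>C", "p.Phe83Leu",
                      "missense")
  expect_equal(v$inheritance_mode, "autosomal_recessive")
  expect_error(variant_record("G", "T", "247T>C", "p.X", "missense"),
               "c\\.")
  expect_error(variant_record("G", "T", "c.1A>G", "Phe83Leu", "missense"),
               "p\\.")
  expect_error(variant_record("G", "T", "c.1A>G", "p.X", "weird"))
})

test_that("genotypes for one site can be pulled from a minimal VCF", {
  skip_if_not_installed("vcfR")
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##contig=<ID=1>",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "S1", "S2", "S3", sep = "\t"),
           paste("1", "68896028", ".", "T", "C", ".", "PASS", ".", "GT",
                 "1/1", "0/1", "0|0", sep = "\t"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  gt <- read_genotypes_vcf(path, "1", 68896028, "T", "C")
  expect_equal(gt$genotype[match(c("S1", "S2", "S3"), gt$sample_id)],
               c("hom_alt", "het", "hom_ref"))
  expect_error(read_genotypes_vcf(path, "1", 1, "T", "C"),
               "exactly one")
})
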