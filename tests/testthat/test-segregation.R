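test_that("a consistent nuclear family yields the expected counts", {
  ped <- parse_ped(nuclear_ped_lines())[[1]]
  v <- check_ar_cosegregation(ped)
  expect_true(v$consistent)
  expect_false(v$uninformative)
  expect_equal(v$n_affected_homalt, 2L)
  expect_equal(v$n_affected_other_genotype, 0L)
  expect_equal(v$n_unaffected_homalt, 0L)
  expect_equal(v$n_informative_unaffected, 2L)
})

test_that("an unaffected homozygote or affected carrier breaks consistency", {
  unaff_hom <- parse_ped(c("F A 0 0 1 1 0/1", "F B 0 0 2 1 0/1",
                           "F C A B 1 2 1/1", "F D A B 2 1 1/1"))[[1]]
  v1 <- check_ar_cosegregation(unaff_hom)
  expect_false(v1$consistent)
  expect_equal(v1$n_unaffected_homalt, 1L)

  aff_het <- parse_ped(c("F A 0 0 1 1 0/1", "F B 0 0 2 1 0/1",
                         "F C A B 1 2 0/1"))[[1]]
  v2 <- check_ar_cosegregation(aff_het)
  expect_false(v2$consistent)
  expect_equal(v2$n_affected_other_genotype, 1L)
})

test_that("singletons are weakly informative, ungenotyped families not at all", {
  singleton <- parse_ped("F P 0 0 1 2 1/1")[[1]]
  v <- check_ar_cosegregation(singleton)
  expect_true(v$consistent)
  expect_equal(v$n_informative_unaffected, 0L)

  blank <- parse_ped(c("F A 0 0 1 2 ./.", "F B 0 0 1 0 1/1"))[[1]]
  vb <- check_ar_cosegregation(blank)  # missing genotype / unknown affection
  expect_true(vb$uninformative)
  expect_false(vb$consistent)
  expect_equal(vb$n_affected_homalt, 0L)
})

test_that("verdict counts never exceed the informative member count", {
  set.seed(5)
  for (i in 1:25) {
    sim <- generate_cohort(cohort_spec(n_case_families = 3,
                                       n_control_families = 0,
                                       n_exposed_cases = 3, seed = i))
    for (ped in sim$pedigrees) {
      v <- check_ar_cosegregation(ped)
      df <- pedigree_to_df(ped)
      n_informative <- sum(df$genotype != "missing" &
                             df$affection != "unknown")
      expect_lte(v$n_affected_homalt + v$n_affected_other_genotype +
                   v$n_unaffected_homalt + v$n_informative_unaffected,
                 n_informative)
    }
  }
})

test_that("adding an unaffected het relative never flips a consistent family", {
  base <- nuclear_ped_lines()
  v0 <- check_ar_cosegregation(parse_ped(base)[[1]])
  v1 <- check_ar_cosegregation(
    parse_ped(c(base, "FAM1 C3 F M 2 1 0/1"))[[1]])
  expect_true(v0$consistent)
  expect_true(v1$consistent)
  expect_equal(v1$n_informative_unaffected,
               v0$n_informative_unaffected + 1L)
})

test_that("all seven replica families co-segregate and support PP1", {
  verdicts <- segregation_verdicts(replica_pedigrees("all"))
  expect_equal(nrow(verdicts), 7L)
  expect_true(all(verdicts$consistent))
  # affected homozygote counts per family follow the published table
  expect_equal(verdicts$n_affected_homalt[match(LETTERS[1:7],
                                                verdicts$family_id)],
               c(2L, 1L, 1L, 1L, 2L, 2L, 3L))
  pp1 <- evaluate_pp1(verdicts)
  expect_true(pp1$met)
  expect_equal(pp1$strength, "supporting")
  expect_false(evaluate_bs4(verdicts)$met)
})

test_that("one contradictory family suppresses PP1 and raises BS4", {
  peds <- replica_pedigrees("p.Phe83Leu")
  # mutate an unaffected member of family A to homozygous
  df <- pedigree_to_df(peds[[1]])
  idx <- which(df$affection == "unaffected")[1]
  members <- lapply(seq_len(nrow(df)), function(i)
    individual(df$individual_id[i], df$family_id[i],
               if (is.na(df$father_id[i])) NULL else df$father_id[i],
               if (is.na(df$mother_id[i])) NULL else df$mother_id[i],
               df$sex[i], df$affection[i],
               if (i == idx) "hom_alt" else df$genotype[i]))
  peds[[1]] <- pedigree(df$family_id[1], members)
  verdicts <- segregation_verdicts(peds)
  expect_false(verdicts$consistent[1])
  expect_false(evaluate_pp1(verdicts)$met)
  expect_true(evaluate_bs4(verdicts)$met)
})

test_that("PP1 escalation engages only when asked and thresholds are met", {
  verdicts <- segregation_verdicts(replica_pedigrees("all"))
  expect_equal(evaluate_pp1(verdicts)$strength, "supporting")
  escalated <- evaluate_pp1(verdicts, escalate = TRUE)
  expect_equal(escalated$strength, "strong")   # 7 consistent families
  two <- verdicts[1:2, ]
  expect_equal(evaluate_pp1(two, escalate = TRUE)$strength, "supporting")
  expect_error(evaluate_pp1(verdicts[0, ]), "at least one family")
})

test_that("uninformative-only verdicts yield PP1 unmet without BS4", {
  blank <- segregation_verdicts(list(
    parse_ped("F A 0 0 1 2 ./.")[[1]]))
  ev <- evaluate_pp1(blank)
  expect_false(ev$met)
  expect_match(ev$rationale, "no informative families")
  expect_false(evaluate_bs4(blank)$met)
})
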