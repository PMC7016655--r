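five_criterion_evidence <- function() list(
  evidence_item("PS4", TRUE, "enrichment"),
  evidence_item("PM2", TRUE, "rarity"),
  evidence_item("PP1", TRUE, "segregation"),
  evidence_item("PP2", TRUE, "gene context"),
  evidence_item("PP3", TRUE, "in silico"))

test_that("tallying counts met items by direction and strength", {
  t5 <- tally_evidence(five_criterion_evidence())
  expect_equal(t5$n_strong, 1L)
  expect_equal(t5$n_moderate, 1L)
  expect_equal(t5$n_supporting, 3L)
  expect_equal(t5$n_bs + t5$n_bp + t5$n_ba, 0L)

  t3 <- tally_evidence(list(evidence_item("PM2", TRUE),
                            evidence_item("PP2", TRUE),
                            evidence_item("PP3", TRUE),
                            evidence_item("PS4", FALSE)))
  expect_equal(t3$n_moderate, 1L)
  expect_equal(t3$n_supporting, 2L)
  expect_equal(t3$n_strong, 0L)

  expect_equal(tally_evidence(list())$n_supporting, 0L)
  expect_error(tally_evidence(list(evidence_item("PM2", TRUE),
                                   evidence_item("PM2", TRUE))),
               "duplicate")
})

test_that("strength-modulated items count in their assigned bucket", {
  t <- tally_evidence(list(
    evidence_item("PP1", TRUE, strength = "moderate")))
  expect_equal(t$n_moderate, 1L)
  expect_equal(t$n_supporting, 0L)
})

test_that("the worked five-criterion combination is likely pathogenic", {
  cls <- combine_evidence(tally_evidence(five_criterion_evidence()))
  expect_equal(cls$tier, "likely_pathogenic")
  expect_equal(cls$rule_fired, "LP_1_strong_1_2_moderate")
  # before segregation and enrichment: one moderate + two supporting = VUS
  vus <- combine_evidence(evidence_tally(moderate = 1, supporting = 2))
  expect_equal(vus$tier, "uncertain_significance")
  expect_equal(vus$rule_fired, "default_vus")
  # direct likely-pathogenic rule: very strong + moderate
  expect_equal(combine_evidence(evidence_tally(very_strong = 1,
                                               moderate = 1))$tier,
               "likely_pathogenic")
})

test_that("benign combinations and conflicts resolve as specified", {
  expect_equal(combine_evidence(evidence_tally(ba = 1))$tier, "benign")
  expect_equal(combine_evidence(evidence_tally(bs = 2))$tier, "benign")
  expect_equal(combine_evidence(evidence_tally(bs = 1, bp = 1))$tier,
               "likely_benign")
  expect_equal(combine_evidence(evidence_tally(bp = 2))$tier,
               "likely_benign")
  conflicted <- combine_evidence(evidence_tally(strong = 1, moderate = 2,
                                                bs = 2))
  expect_equal(conflicted$tier, "uncertain_significance")
  expect_equal(conflicted$rule_fired, "conflicting")
})

test_that("what-if escalations lift the worked example to pathogenic", {
  base <- tally_evidence(five_criterion_evidence())
  expect_equal(what_if(base, "PM3")$tier, "pathogenic")
  no_pp1 <- tally_evidence(Filter(function(e) e$code != "PP1",
                                  five_criterion_evidence()))
  expect_equal(what_if(no_pp1, "PP1", strength = "strong")$tier,
               "pathogenic")
  expect_equal(what_if(no_pp1, "PP1", strength = "moderate")$tier,
               "pathogenic")
  # a single supporting criterion on its own stays VUS
  expect_equal(what_if(evidence_tally(), "PP3")$tier,
               "uncertain_significance")
  expect_error(what_if(base, "PM2"), "already met")
})

all_tallies <- function(max_count = 3L) {
  grid <- expand.grid(vs = 0:max_count, s = 0:max_count, m = 0:max_count,
                      p = 0:max_count, ba = 0:1, bs = 0:max_count,
                      bp = 0:max_count)
  grid
}

test_that("the combiner matches the flat-rule oracle exhaustively", {
  grid <- all_tallies()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- combine_evidence(evidence_tally(
      very_strong = g$vs, strong = g$s, moderate = g$m, supporting = g$p,
      ba = g$ba, bs = g$bs, bp = g$bp))$tier
    want <- oracle_tier(g$vs, g$s, g$m, g$p, g$ba, g$bs, g$bp)
    expect_identical(got, want)
  }
})

test_that("added evidence never moves the verdict the wrong way", {
  grid <- all_tallies(2L)
  bump <- function(g, slot) { g[[slot]] <- g[[slot]] + 1L; g }
  tier_of <- function(g) combine_evidence(evidence_tally(
    very_strong = g$vs, strong = g$s, moderate = g$m, supporting = g$p,
    ba = g$ba, bs = g$bs, bp = g$bp))$tier
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    base_rank <- tier_rank(tier_of(g))
    # pathogenic-side additions never move the tier toward benign ...
    for (slot in c("vs", "s", "m", "p"))
      expect_gte(tier_rank(tier_of(bump(g, slot))), base_rank)
    # ... and benign-side additions never move it toward pathogenic
    for (slot in c("ba", "bs", "bp"))
      expect_lte(tier_rank(tier_of(bump(g, slot))), base_rank)
  }
})

test_that("identical tallies always classify identically", {
  t1 <- evidence_tally(strong = 1, moderate = 2, supporting = 1)
  t2 <- evidence_tally(strong = 1, moderate = 2, supporting = 1)
  expect_identical(combine_evidence(t1)$tier, combine_evidence(t2)$tier)
  expect_identical(combine_evidence(t1)$rule_fired,
                   combine_evidence(t2)$rule_fired)
})
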