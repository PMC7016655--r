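test_that("2x2 tables are built from diagnosis group and exposure", {
  tab <- build_table(make_cohort_df(93, 420, exposed_cases = 4))
  expect_equal(unclass(tab)[c("a", "b", "c", "d")],
               list(a = 4L, b = 89L, c = 0L, d = 420L))
  tab2 <- build_table(make_cohort_df(93, 420, exposed_cases = 3))
  expect_equal(tab2$a, 3L)
  expect_equal(tab2$b, 90L)
  none <- build_table(make_cohort_df(10, 10))
  expect_equal(c(none$a, none$c), c(0L, 0L))
  expect_error(build_table(make_cohort_df(0, 0)), "empty cohort")
})

test_that("missing genotypes count as unexposed with a warning", {
  df <- make_cohort_df(5, 5, exposed_cases = 1)
  df$genotype[2] <- "missing"
  expect_warning(tab <- build_table(df), "missing")
  expect_equal(tab$b, 4L)
})

test_that("zero cells trigger the all-cell +0.5 correction, others do not", {
  or1 <- haldane_anscombe_or(contingency_2x2(4, 89, 0, 420))
  expect_equal(round(as.numeric(or1), 3), 42.285)
  expect_true(attr(or1, "correction_applied"))
  expect_equal(as.numeric(or1), (4.5 * 420.5) / (89.5 * 0.5))

  or2 <- haldane_anscombe_or(contingency_2x2(3, 90, 0, 420))
  expect_equal(round(as.numeric(or2), 3), 32.525)

  balanced <- haldane_anscombe_or(contingency_2x2(10, 10, 10, 10))
  expect_equal(as.numeric(balanced), 1)
  expect_false(attr(balanced, "correction_applied"))

  expect_error(haldane_anscombe_or(contingency_2x2(0, 0, 3, 4)), "margin")
  expect_error(contingency_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("Wald intervals use corrected cells and the exact normal quantile", {
  ci <- wald_log_ci(contingency_2x2(4, 89, 0, 420), 0.975)
  oracle <- oracle_or_ci(4, 89, 0, 420, 0.975)
  expect_equal(unname(ci), c(oracle$lower, oracle$upper), tolerance = 1e-12)
  ci2 <- wald_log_ci(contingency_2x2(3, 90, 0, 420), 0.975)
  oracle2 <- oracle_or_ci(3, 90, 0, 420, 0.975)
  expect_equal(unname(ci2), c(oracle2$lower, oracle2$upper),
               tolerance = 1e-12)
  # log-symmetry about 1 for a balanced table
  sym <- wald_log_ci(contingency_2x2(10, 10, 10, 10), 0.9)
  expect_equal(unname(sym[1] * sym[2]), 1, tolerance = 1e-12)
  expect_error(wald_log_ci(contingency_2x2(1, 1, 1, 1), 1.2), "between")
})

test_that("corrected OR and CI match the direct-formula oracle on a grid", {
  for (a in 0:6) for (b in 0:6) for (c in 0:6) for (d in 0:6) {
    if (a + b == 0 || c + d == 0) next
    tab <- contingency_2x2(a, b, c, d)
    oracle <- oracle_or_ci(a, b, c, d, 0.95)
    expect_equal(as.numeric(haldane_anscombe_or(tab)), oracle$or,
                 tolerance = 1e-12)
    ci <- wald_log_ci(tab, 0.95)
    expect_equal(unname(ci), c(oracle$lower, oracle$upper),
                 tolerance = 1e-12)
  }
})

test_that("transposing case and control rows inverts the OR and CI", {
  set.seed(3)
  for (i in 1:30) {
    cells <- sample(0:8, 4, replace = TRUE)
    if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0) next
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    swapped <- contingency_2x2(cells[3], cells[4], cells[1], cells[2])
    expect_equal(as.numeric(haldane_anscombe_or(swapped)),
                 1 / as.numeric(haldane_anscombe_or(tab)),
                 tolerance = 1e-12)
    ci <- wald_log_ci(tab, 0.975)
    ci_swapped <- wald_log_ci(swapped, 0.975)
    expect_equal(unname(ci_swapped),
                 unname(c(1 / ci[2], 1 / ci[1])), tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment spreads the error rate over comparisons", {
  expect_equal(bonferroni_confidence(0.95, 2), 0.975)
  expect_equal(bonferroni_confidence(0.95, 1), 0.95)
  expect_equal(bonferroni_confidence(0.99, 4), 0.9975)
  expect_error(bonferroni_confidence(1.5, 2), "between")
  expect_error(bonferroni_confidence(0.95, 0), "positive integer")
})

test_that("PS4 requires both a large OR and an interval excluding one", {
  assoc <- case_control_association(contingency_2x2(4, 89, 0, 420),
                                    base_level = 0.95, n_tests = 2)
  expect_equal(assoc$confidence_level, 0.975)
  ev <- evaluate_ps4(assoc)
  expect_true(ev$met)
  expect_equal(ev$strength, "strong")

  fake <- function(or, lo, hi) structure(
    list(or_point = or, ci_lower = lo, ci_upper = hi,
         confidence_level = 0.975, z_quantile = qnorm(0.9875),
         correction_applied = FALSE, table = NULL),
    class = "association_result")
  expect_false(evaluate_ps4(fake(2.5, 1.2, 5.0))$met)  # below or_min
  expect_false(evaluate_ps4(fake(5.0, 0.8, 30.0))$met) # CI includes 1
})
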