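test_that("clinical CAG bands partition all positive integers", {
  expect_equal(as.character(classify_allele(c(1, 26))),
               c("normal", "normal"))
  expect_equal(as.character(classify_allele(c(27, 35))),
               c("intermediate", "intermediate"))
  expect_equal(as.character(classify_allele(36)), "incomplete_penetrance")
  expect_equal(as.character(classify_allele(c(39, 40, 80))),
               c("incomplete_penetrance", "full_penetrance",
                 "full_penetrance"))
  cls <- classify_allele(1:100)
  expect_false(anyNA(cls))                       # no gaps
  expect_equal(sum(cls == "normal"), 26)
  expect_equal(sum(cls == "intermediate"), 9)
  expect_equal(sum(cls == "incomplete_penetrance"), 4)
  expect_equal(sum(cls == "full_penetrance"), 61)
  expect_error(classify_allele(0), "positive")
})

test_that("sum of repeats counts both alleles, order-free", {
  expect_equal(sum_of_repeats(17, 18), 35L)
  expect_equal(sum_of_repeats(17, 17), 34L)
  g <- data.frame(allele_a = c(17, 20), allele_b = c(18, 25))
  expect_equal(sum_of_repeats(g), c(35L, 45L))
  expect_equal(sum_of_repeats(g$allele_b, g$allele_a), sum_of_repeats(g))
})

test_that("group summaries use the sample SD and need n >= 2", {
  s <- summarize_group(c(34, 36), "g")
  expect_equal(s$mean, 35)
  expect_equal(s$sd, sqrt(2))
  expect_equal(summarize_group(rep(40, 5))$sd, 0)
  expect_error(summarize_group(34), "at least 2")
})

test_that("bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(round(bonferroni_threshold(0.05, 3), 3), 0.017)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(1.2, 3))
})

test_that("pooled t test matches stats::t.test on raw data to 1e-10", {
  set.seed(13)
  for (i in 1:25) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    m1 <- runif(1, 20, 50); m2 <- runif(1, 20, 50)
    s1 <- runif(1, 0.5, 8); s2 <- runif(1, 0.5, 8)
    x <- vector_with_summary(n1, m1, s1)
    y <- vector_with_summary(n2, m2, s2)
    ours <- pooled_t_test(summarize_group(x, "x"), summarize_group(y, "y"))
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    expect_equal(c(ours$ci_low, ours$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter))
  }
})

test_that("pooled t test is antisymmetric and handles degeneracy", {
  a <- summarize_group_values(10, 35, 3, "a")
  b <- summarize_group_values(20, 37, 4, "b")
  ab <- pooled_t_test(a, b)
  ba <- pooled_t_test(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  expect_equal(c(ab$ci_low, ab$ci_high), -c(ba$ci_high, ba$ci_low))

  same <- pooled_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  z1 <- summarize_group_values(5, 35, 0, "z1")
  expect_equal(pooled_t_test(z1, z1)$note,
               "zero pooled variance, equal means")
  z2 <- summarize_group_values(5, 36, 0, "z2")
  deg <- pooled_t_test(z1, z2)
  expect_true(grepl("degenerate", deg$note))
  expect_true(is.na(deg$p))
})

test_that("carrier tallies and the exclusion filter are consistent", {
  g <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    group = c("a", "a", "a", "b", "b", "b"),
    allele_a = c(17, 17, 28, 17, 17, 17),
    allele_b = c(18, 30, 35, 20, 21, 22))
  tal <- intermediate_carrier_tally(g)
  expect_equal(tal$carriers, c(2L, 0L))
  expect_equal(tal$percent, c(66.7, 0.0))
  left <- exclude_intermediate_carriers(g)
  expect_equal(nrow(left), 4L)
  expect_false(any(is.na(left)))
  # no carriers: unchanged
  expect_equal(exclude_intermediate_carriers(left), left)
})

test_that("compare_groups runs each group against the reference", {
  set.seed(5)
  g <- data.frame(
    sample_id = sprintf("s%d", 1:60),
    group = rep(c("controls", "g1", "g2"), each = 20),
    allele_a = sample(15:20, 60, replace = TRUE),
    allele_b = sample(17:25, 60, replace = TRUE))
  comps <- compare_groups(g, reference = "controls")
  expect_equal(comps$group_a, c("g1", "g2"))
  expect_equal(unique(comps$group_b), "controls")
  expect_equal(unique(comps$alpha_adjusted), 0.025)  # alpha/2 by default
  expect_error(compare_groups(g, reference = "nope"), "not present")
})

test_that("summary table mirrors the report layout", {
  ch <- generate_cohort(lund_spec(seed = 2))
  tab <- cohort_summary_table(ch$genotypes)
  expect_equal(tab$group, c("controls", "MLH1", "MSH2", "MSH6"))
  expect_equal(tab$n, c(19L, 12L, 15L, 21L))
  expect_equal(tab$carrier_pct, c(5.3, 8.3, 6.7, 0.0))
  expect_true(all(is.na(tab$mean_ei)))
  fmt <- format_summary_table(tab)
  expect_match(fmt$sum_of_repeats[1], "^\\d+\\.\\d{2} ± \\d+\\.\\d$")
  expect_equal(fmt$intermediate_carriers[4], "0/21")
  expect_equal(fmt$mean_ei[1], "NA")
})
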