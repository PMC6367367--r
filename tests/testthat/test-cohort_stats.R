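test_that("report percentages reproduce both rounding conventions", {
  p1 <- percent_both(2780, 3000)
  expect_equal(p1$pct_half_away, 92.7)
  expect_equal(p1$pct_half_toward, 92.7)
  p2 <- percent_both(199, 3000)
  expect_equal(p2$pct_half_away, 6.6)
  p3 <- percent_both(21, 48)    # 43.75: the conventions disagree
  expect_equal(p3$pct_half_away, 43.8)
  expect_equal(p3$pct_half_toward, 43.7)
  expect_true(p3$convention_differs)
  expect_equal(percent_both(0, 50)$pct_half_away, 0.0)
})

test_that("exact rank-sum mode agrees with enumeration oracles", {
  r <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 0.1)
  # identical groups give p = 1
  expect_equal(rank_sum_test(c(5, 6, 7), c(5, 6, 7))$p_value, 1)
  # tie-free cases against wilcox.test's exact distribution
  set.seed(81)
  for (i in 1:12) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(100, n1) + runif(n1)        # continuous: no ties
    y <- sample(50:150, n2) + runif(n2)
    ours <- rank_sum_test(x, y)$p_value
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  # tied data against the independent brute-force enumerator
  for (i in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(2:6, n2, replace = TRUE)
    expect_equal(rank_sum_test(x, y)$p_value, brute_rank_sum_p(x, y))
  }
  # large-sample normal mode tracks the reference implementation
  set.seed(82)
  x <- rpois(30, 8); y <- rpois(25, 12)
  ours <- rank_sum_test(x, y)
  expect_equal(ours$method, "normal")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(ours$p_value, ref, tolerance = 1e-9)
})

test_that("the stow association test separates shifted cohorts", {
  s <- data.frame(stow_status = rep(c("ping16A_stow", "none"), each = 3),
                  mping = c(10, 11, 12, 1, 2, 3))
  r <- test_stow_association(s)
  expect_equal(r$p_value, 0.1)
  expect_error(test_stow_association(
    data.frame(stow_status = "none", mping = 1)), "non-empty")
})

test_that("one-way ANOVA and Tukey HSD follow closed forms", {
  r <- anova_tukey(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(r$F, 13.5)
  expect_equal(r$df, 1L)
  expect_equal(r$df_resid, 4L)
  # two-group ANOVA satisfies F = t^2
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2)
  # shift invariance
  r2 <- anova_tukey(list(a = c(1, 2, 3) + 17, b = c(4, 5, 6) + 17))
  expect_equal(r2$F, r$F)
  # degenerate identical constants
  r0 <- anova_tukey(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(r0$F, 0)
  expect_equal(r0$p_value, 1)
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "observations")
  # with two groups the Tukey adjusted p equals the ANOVA p
  expect_equal(r$tukey$p_adj, r$p_value, tolerance = 1e-4)
})

test_that("transposition-rate arithmetic follows the dilution model", {
  # 10 colonies over 2e6 plated cells is 5 per million
  r <- transposition_frequency(10, 200, dilution = 1e-4)
  expect_equal(r$total_cells, 2e6)
  expect_equal(r$per_million, 5)
  # rate equal to control normalizes to 1
  rn <- transposition_frequency(10, 200, dilution = 1e-4,
                                control_per_million = 5)
  expect_equal(rn$normalized, 1.0)
  expect_error(transposition_frequency(10, 200, control_per_million = 0),
               "zero")
  expect_error(transposition_frequency(10, 0), "> 0")
  expect_error(transposition_frequency(10, 200, dilution = 2), "dilution")
})

test_that("method correlation behaves under identity and affine maps", {
  s <- data.frame(mPing_count = c(1, 5, 9, 13), mPing_estimate = c(1, 5, 9,
                                                                   13))
  r <- correlate_methods(s, "mPing")
  expect_equal(r$r, 1)
  # affine invariance (positive slope)
  r2 <- correlate_methods(counts = c(1, 5, 9, 13),
                          estimates = 3 * c(1, 5, 9, 13) + 7)
  expect_equal(r2$r, 1)
  rc <- correlate_methods(counts = c(2, 2, 2), estimates = c(1, 2, 3))
  expect_equal(rc$status, "not-applicable")
  expect_error(correlate_methods(counts = c(1, 2), estimates = c(1, 2)),
               ">= 3")
})

test_that("report tables summarize presence and variant tallies", {
  s <- data.frame(accession = paste0("a", 1:10),
                  subgroup = rep(c("g1", "g2"), 5),
                  mping = c(rep(3, 9), 0), ping = c(rep(0, 9), 1),
                  pong = rep(1, 10),
                  ping_variant = c(rep("undetermined", 9), "Ping16A"),
                  stow_status = c(rep("none", 8), "stowaway_only",
                                  "ping16A_stow"))
  rt <- report_tables(s)
  expect_equal(rt$presence$pct_half_away[rt$presence$element == "mping"],
               90.0)
  expect_equal(rt$variants$Freq[rt$variants$variant == "Ping16A"], 1)
  expect_equal(sum(rt$stow$Freq), 10)
  expect_equal(nrow(rt$subgroup_means), 2)
  # copy-number summary helper
  cs <- summarize_copy_numbers(c(1, 2, 3, 4))
  expect_equal(cs$mean, 2.5)
  expect_equal(cs$sd, 1.29)
})
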