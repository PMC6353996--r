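test_that("group summaries compute mean and SE over cells", {
  rec <- data.frame(group = c("a", "a"), value = c(0.2, 0.3))
  s <- summarize_cells(rec)
  expect_equal(s$mean, 0.25)
  # SE of the mean with the sample (n - 1) standard deviation:
  # sd(0.2, 0.3) = 0.1/sqrt(2), se = sd/sqrt(2) = 0.05
  expect_equal(s$se, sd(c(0.2, 0.3)) / sqrt(2))
  expect_equal(s$se, 0.05, tolerance = 1e-12)
  # order invariance
  rec2 <- data.frame(group = c("b", "a", "b", "a"),
                     value = c(5, 1, 6, 2))
  expect_equal(summarize_cells(rec2), summarize_cells(rec2[c(3, 1, 4, 2), ]))
  # degenerate and undersized groups
  expect_warning(summarize_cells(data.frame(group = "a", value = c(1, 1))),
                 "degenerate")
  expect_error(summarize_cells(data.frame(group = "a", value = 1)),
               "< 2 records")
})

test_that("a large synthetic group mean lands near its truth", {
  set.seed(10)
  rec <- data.frame(group = "g", value = rnorm(100, 0.22, 0.015))
  s <- summarize_cells(rec)
  expect_lt(abs(s$mean - 0.22), 3 * s$se)
})

test_that("percent differences follow the normal-denominator convention", {
  # identical groups differ by 0%
  expect_equal(percent_difference(10, 10)$percent, 0)
  # antisymmetry of sign
  expect_equal(sign(percent_difference(9, 10)$percent), -1)
  expect_equal(sign(percent_difference(11, 10)$percent), 1)
  expect_error(percent_difference(5, 0), "> 0")
  # half-up display rounding
  expect_equal(round_half_up(12.5), 13)
  expect_equal(round_half_up(-12.5), -13)
  expect_equal(round_half_up(20.498), 20)
})

test_that("published group means reproduce the quoted percent differences", {
  # whole cell at 0.05 mg/ml: cancer-vs-normal spread runs from 12% (smallest,
  # MDA-MB-231 vs MCF-12A) to 20% (largest, MDA-MB-157 vs MCF-10A)
  w <- reference_percent_differences("whole_cell")
  expect_equal(
    w$percent_display[w$cancer == "MDA-MB-231" & w$normal == "MCF-12A"], 12)
  expect_equal(
    w$percent_display[w$cancer == "MDA-MB-157" & w$normal == "MCF-10A"], 20)
  expect_equal(min(w$percent_display), 12)
  expect_equal(max(w$percent_display), 20)
  # nucleus-excluded: smallest difference 13%
  e <- reference_percent_differences("excl_nucleus")
  expect_equal(min(e$percent_display), 13)
  # nuclei: differences span 8% to 14%
  n <- reference_percent_differences("nucleus")
  expect_equal(min(n$percent_display), 8)
  expect_equal(max(n$percent_display), 14)
})

sim_grouped <- function(n_exp = 5, n_per = 20, effect = 0, sd_exp = 0.005,
                        sd_cell = 0.015, mu = 0.22) {
  exp_eff <- rnorm(n_exp, 0, sd_exp)
  df <- do.call(rbind, lapply(seq_len(n_exp), function(e) {
    data.frame(
      experiment = sprintf("e%d", e),
      value_a = mu + effect + exp_eff[e] + rnorm(n_per, 0, sd_cell),
      value_b = mu + exp_eff[e] + rnorm(n_per, 0, sd_cell)
    )
  }))
  df
}

test_that("permutation p-values are valid and self-comparison is null", {
  set.seed(3)
  df <- sim_grouped()
  cmp <- compare_groups(df$value_a, df$value_b, df$experiment, df$experiment,
                        n_perm = 200, seed = 1)
  expect_gte(cmp$p_value, 1 / 201)
  expect_lte(cmp$p_value, 1)
  expect_equal(cmp$method, "within_experiment_permutation")
  # a group against itself: statistic 0, p = 1 up to permutation resolution
  self <- compare_groups(df$value_a, df$value_a, df$experiment, df$experiment,
                         n_perm = 200, seed = 2)
  expect_equal(self$p_value, 1)
})

test_that("disjoint experiments trigger experiment-level permutation", {
  set.seed(4)
  va <- rnorm(50, 0.24, 0.015)
  vb <- rnorm(50, 0.21, 0.015)
  ea <- rep(sprintf("a%d", 1:5), each = 10)
  eb <- rep(sprintf("b%d", 1:5), each = 10)
  cmp <- compare_groups(va, vb, ea, eb, n_perm = 500, seed = 1)
  expect_equal(cmp$method, "experiment_permutation")
  # single experiment per group falls back with a warning
  expect_warning(
    cmp2 <- compare_groups(va, vb, rep("a1", 50), rep("b1", 50),
                           n_perm = 200, seed = 1),
    "pseudo-replication"
  )
  expect_equal(cmp2$method, "cell_permutation")
})

test_that("the permutation test keeps its nominal type-I error", {
  set.seed(7)
  rejections <- vapply(1:200, function(i) {
    df <- sim_grouped(effect = 0)
    cmp <- compare_groups(df$value_a, df$value_b, df$experiment,
                          df$experiment, n_perm = 199)
    cmp$p_value <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("the permutation test detects the cancer-scale Fpol shift", {
  set.seed(8)
  hits <- vapply(1:40, function(i) {
    df <- sim_grouped(effect = 0.03)
    cmp <- compare_groups(df$value_a, df$value_b, df$experiment,
                          df$experiment, n_perm = 1999)
    cmp$p_value < 0.001
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("the optional mixed-model cross-check agrees in direction", {
  skip_if_not_installed("lme4")
  set.seed(9)
  df <- sim_grouped(effect = 0.03)
  out <- compare_groups_lmm(df$value_a, df$value_b, df$experiment,
                            df$experiment)
  expect_gt(out$difference, 0)
  expect_gt(out$t_value, 3)
})
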