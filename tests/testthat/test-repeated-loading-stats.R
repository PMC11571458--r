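test_that("force increases reproduce the reference table's printed columns", {
  ref <- ref_force_table()
  printed <- list(`1` = c(28, 36, 39, 42), `2` = c(17, 21, 24, 25),
                  `3` = c(9, 11, 11, 12))
  for (nl in 1:3) {
    means <- ref$force_n[ref$n_layers == nl]
    expect_equal(force_increase_table(means)[-1], printed[[as.character(nl)]])
  }
  expect_equal(force_increase_table(c(10017, 12867))[2], 28)
  expect_equal(force_increase_table(c(3858, 4525))[2], 17)
  expect_equal(force_increase_table(c(5, 5, 5)), c(0, 0, 0))
  expect_error(force_increase_table(c(0, 5)), "positive")
})

test_that("Shapiro-Wilk wrapper behaves under null and alternative", {
  set.seed(21)
  p_norm <- replicate(100, shapiro_wilk(rnorm(20))$p_value)
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- replicate(100, shapiro_wilk(rexp(30))$p_value)
  expect_gt(mean(p_exp < 0.05), 0.60)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("repeated-measures ANOVA matches a manual SS decomposition", {
  fm <- rbind(c(10, 12, 13), c(11, 13.2, 14), c(9, 11, 11.5))
  res <- rm_anova(fm)
  # manual sums of squares, subject effect removed
  grand <- mean(fm)
  ss_treat <- nrow(fm) * sum((colMeans(fm) - grand)^2)
  ss_subj <- ncol(fm) * sum((rowMeans(fm) - grand)^2)
  ss_tot <- sum((fm - grand)^2)
  ss_err <- ss_tot - ss_treat - ss_subj
  df1 <- ncol(fm) - 1
  df2 <- (nrow(fm) - 1) * (ncol(fm) - 1)
  f_manual <- (ss_treat / df1) / (ss_err / df2)
  expect_equal(res$F, f_manual, tolerance = 1e-9)
  expect_equal(res$eta_squared, ss_treat / (ss_treat + ss_err),
               tolerance = 1e-9)
  expect_equal(res$df1, df1)
  expect_equal(res$df2, df2)
  expect_equal(res$p_value, stats::pf(f_manual, df1, df2, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("no repetition effect yields a small F and large p", {
  set.seed(8)
  base <- c(100, 200, 300, 400)
  fm <- base + matrix(rnorm(20, 0, 1), 4, 5)
  res <- rm_anova(fm)
  expect_gt(res$p_value, 0.2)
  expect_true(res$eta_squared >= 0 && res$eta_squared <= 1)
  expect_error(rm_anova(fm[1, , drop = FALSE]), ">= 2 specimens")
  fm[2, 3] <- NA
  expect_error(rm_anova(fm), "missing")
})

test_that("consecutive one-sided paired t tests match the hand formula", {
  fm <- cbind(c(10, 11, 9), c(12, 13.1, 10.9))
  res <- posthoc_consecutive_t(fm)
  d <- fm[, 2] - fm[, 1] # (2, 2.1, 1.9)
  t_hand <- mean(d) / (stats::sd(d) / sqrt(3))
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$t, 34.64, tolerance = 1e-3)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$p_value, stats::pt(t_hand, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("degenerate paired differences are flagged, not silently tested", {
  fm <- cbind(c(10, 11, 9), c(12, 13, 11)) # d constant = 2
  expect_warning(res <- posthoc_consecutive_t(fm), "constant")
  expect_true(is.na(res$t))
  expect_equal(res$mean_diff_n, 2)
  fm2 <- cbind(c(10, 11, 9), c(10, 11, 9)) # identical samples
  expect_warning(res2 <- posthoc_consecutive_t(fm2), "constant")
  expect_true(is.na(res2$p_value))
})

test_that("build_table1 reproduces a hand-built metrics fixture exactly", {
  vals <- matrix(c(100, 110, 120,
                   102, 112, 123,
                   98, 109, 119), nrow = 3, byrow = TRUE) # specimen x rep
  metrics <- tidyr::expand_grid(specimen_id = c("a", "b", "c"),
                                repetition = 1:3)
  metrics$force_at_eref_n <- as.vector(t(vals))
  metrics$n_layers <- 1L
  metrics$drop_height <- 0.5
  metrics$block <- "extra"
  res <- build_table1(metrics, e_ref = 30,
                      config = study_config())[["1"]]
  expect_equal(res$summary$mean_n, colMeans(vals))
  expect_equal(res$summary$sd_n, apply(vals, 2, sd))
  expect_equal(res$summary$increase_pct,
               100 * (colMeans(vals) / mean(vals[, 1]) - 1))
  expect_equal(dim(res$force_matrix), c(3, 3))
  expect_equal(res$anova$F, rm_anova(vals)$F)
  expect_equal(res$summary$p_value[-1], posthoc_consecutive_t(vals)$p_value)
})

test_that("missing reference-energy cells are reported with identifiers", {
  metrics <- tibble::tibble(
    specimen_id = c("a", "a"), repetition = 1:2,
    force_at_eref_n = c(100, NA), n_layers = 1L,
    drop_height = 0.5, block = "extra"
  )
  expect_error(build_table1(metrics, 30), "a R2")
  expect_error(build_table1(metrics[0, ], 30), "five-repetition")
})
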