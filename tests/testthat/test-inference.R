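balanced_toy <- function() {
  # 2 lines x 2 times x 2 replicates with known effects
  tidyr::expand_grid(line = c("WT", "mut"), time_point = c("t0", "t1"),
                     replicate = 1:2) %>%
    dplyr::mutate(value = c(10, 12, 14, 16, 20, 22, 30, 32))
}

test_that("two-way ANOVA matches the hand-computed decomposition", {
  tab <- balanced_toy()
  res <- two_way_anova(tab)
  # brute-force sums of squares from the definitions
  grand <- mean(tab$value)
  cell <- tapply(tab$value, list(tab$line, tab$time_point), mean)
  line_m <- tapply(tab$value, tab$line, mean)
  time_m <- tapply(tab$value, tab$time_point, mean)
  r <- 2
  ss_line <- r * 2 * sum((line_m - grand)^2)
  ss_time <- r * 2 * sum((time_m - grand)^2)
  ss_int <- r * sum((sweep(sweep(cell, 1, line_m), 2, time_m) + grand)^2)
  ss_err <- sum((tab$value - cell[cbind(tab$line, tab$time_point)])^2)
  an <- res$anova
  expect_equal(an$sum_sq[an$factor == "line"], ss_line)
  expect_equal(an$sum_sq[an$factor == "time_point"], ss_time)
  expect_equal(an$sum_sq[an$factor == "line:time_point"], ss_int)
  expect_equal(an$sum_sq[an$factor == "residuals"], ss_err)
  # partition adds to the total sum of squares
  expect_equal(sum(an$sum_sq), sum((tab$value - grand)^2), tolerance = 1e-9)
  expect_true(res$balanced)
  expect_equal(res$residual_df, 4)
})

test_that("degenerate and malformed designs are handled", {
  tab <- balanced_toy()
  const <- dplyr::mutate(tab, value = 5)
  res <- suppressWarnings(two_way_anova(const))  # aov warns on zero variance
  expect_equal(res$anova$p[1:3], rep(1, 3))
  expect_equal(res$anova$statistic[1:3], rep(0, 3))
  expect_error(two_way_anova(tab[tab$line != "mut" | tab$time_point != "t1", ]),
               "cell")
  expect_warning(two_way_anova(tab[-1, ]), "Unbalanced")
})

test_that("two-way ANOVA null rejection rate is calibrated", {
  set.seed(101)
  hits <- replicate(1000, {
    tab <- tidyr::expand_grid(line = c("a", "b", "c"), time_point = c("x", "y"),
                              replicate = 1:3) %>%
      dplyr::mutate(value = rnorm(18))
    two_way_anova(tab)$anova$p[1] < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.015)
})

test_that("Dunnett with one treatment reduces to the two-sided t-test", {
  cm <- tibble::tibble(line = c("WT", "T1"), time_point = "t0",
                       mean = c(10, 11.2), n = c(4, 4))
  res <- dunnett_vs_control(cm, residual_ms = 1.1, residual_df = 6,
                            mc_draws = 4e5, seed = 2)
  t_obs <- (11.2 - 10) / sqrt(1.1 * (1 / 4 + 1 / 4))
  p_t <- 2 * pt(-abs(t_obs), 6)
  expect_equal(res$p_adj, p_t, tolerance = 0.002)
  expect_gte(res$p_adj, res$p_raw)
})

test_that("Dunnett adjustment is monotone, ordered and label-invariant", {
  cm <- tibble::tibble(line = c("WT", "T1", "T2", "T3"), time_point = "t0",
                       mean = c(10, 10.5, 11.5, 13), n = 3)
  res <- dunnett_vs_control(cm, residual_ms = 1, residual_df = 8, seed = 3)
  expect_true(all(res$p_adj >= res$p_raw))
  # larger |t| gets smaller adjusted p
  ord <- order(abs(res$t), decreasing = TRUE)
  expect_true(all(diff(res$p_adj[ord]) >= 0))
  relabeled <- dplyr::mutate(cm, line = c("WT", "T3", "T2", "T1"))
  res2 <- dunnett_vs_control(relabeled, residual_ms = 1, residual_df = 8, seed = 3)
  expect_equal(sort(res2$p_adj), sort(res$p_adj), tolerance = 1e-12)
  expect_error(dunnett_vs_control(cm[-1, ], 1, 8), "Control")
})

test_that("Dunnett Monte Carlo agrees with the reference implementation", {
  skip_if_not_installed("multcomp")
  set.seed(42)
  df <- tidyr::expand_grid(line = c("WT", "T1", "T2", "T3"), replicate = 1:5) %>%
    dplyr::mutate(value = rnorm(20) + ifelse(line == "T2", 1.2, 0),
                  line = factor(line, levels = c("WT", "T1", "T2", "T3")))
  fit <- stats::aov(value ~ line, data = df)
  glht_res <- summary(multcomp::glht(fit, linfct = multcomp::mcp(line = "Dunnett")))
  p_ref <- as.numeric(glht_res$test$pvalues)
  cm <- df %>%
    dplyr::group_by(line) %>%
    dplyr::summarise(mean = mean(value), n = dplyr::n()) %>%
    dplyr::mutate(time_point = "t0")
  ms <- sum(stats::residuals(fit)^2) / fit$df.residual
  res <- dunnett_vs_control(cm, residual_ms = ms, residual_df = fit$df.residual,
                            mc_draws = 2e5, seed = 1)
  res <- res[match(c("T1", "T2", "T3"), res$line), ]
  expect_equal(res$p_adj, p_ref, tolerance = 0.01)
})

test_that("family-wise error of the Dunnett procedure is controlled", {
  set.seed(77)
  hits <- replicate(400, {
    df <- tidyr::expand_grid(line = c("WT", "T1", "T2", "T3"), replicate = 1:3) %>%
      dplyr::mutate(value = rnorm(12))
    fit <- stats::aov(value ~ line, data = df)
    cm <- df %>%
      dplyr::group_by(line) %>%
      dplyr::summarise(mean = mean(value), n = dplyr::n()) %>%
      dplyr::mutate(time_point = "t0")
    ms <- sum(stats::residuals(fit)^2) / fit$df.residual
    res <- dunnett_vs_control(cm, ms, fit$df.residual, mc_draws = 2e4,
                              seed = sample.int(1e6, 1))
    any(res$p_adj < 0.05)
  })
  expect_lte(mean(hits), 0.06)
})
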