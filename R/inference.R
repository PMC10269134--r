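# Group-comparison statistics for pigment and photophysiology tables:
# two-way fixed-effects ANOVA (line x time) and Dunnett many-to-one
# comparisons against the wild-type control within each time point.

#' Two-way fixed-effects ANOVA (line x time)
#'
#' Standard crossed fixed-effects decomposition with interaction, computed
#' by sequential sums of squares via [stats::lm()]/[stats::anova()]. For
#' balanced designs sequential and partial sums of squares coincide; an
#' unbalanced design is accepted with a warning (sums of squares are then
#' order-dependent). A constant response yields `F` reported as 0 with
#' p = 1.
#'
#' @param table Long tibble with columns `line`, `time_point`, `replicate`,
#'   `value`.
#' @return List with `anova` (tibble: factor, df, sum_sq, mean_sq, statistic,
#'   p), `residual_ms`, `residual_df`, `balanced`, `cell_means` (per
#'   line x time mean and n).
#' @export
two_way_anova <- function(table) {
  req <- c("line", "time_point", "value")
  if (!all(req %in% names(table))) {
    abort("`table` needs columns line, time_point, value.")
  }
  table <- dplyr::mutate(table, line = factor(.data$line),
                         time_point = factor(.data$time_point))
  counts <- table(table$line, table$time_point)
  if (any(counts < 1)) abort("Every line x time cell needs at least one observation.")
  balanced <- length(unique(as.vector(counts))) == 1
  if (!balanced) {
    warn("Unbalanced design: sequential (type I) sums of squares are order-dependent.")
  }
  fit <- lm(value ~ line * time_point, data = table)
  an <- anova(fit)
  tb <- tibble::tibble(
    factor = c("line", "time_point", "line:time_point", "residuals"),
    df = an$Df, sum_sq = an$`Sum Sq`, mean_sq = an$`Mean Sq`,
    statistic = an$`F value`, p = an$`Pr(>F)`
  )
  if (all(abs(stats::residuals(fit)) < 1e-12) && all(tb$sum_sq < 1e-20)) {
    tb$statistic[1:3] <- 0
    tb$p[1:3] <- 1
  }
  cell_means <- table %>%
    dplyr::group_by(.data$line, .data$time_point) %>%
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop")
  list(
    anova = tb,
    residual_ms = tb$mean_sq[tb$factor == "residuals"],
    residual_df = tb$df[tb$factor == "residuals"],
    balanced = balanced,
    cell_means = cell_means
  )
}

# Monte-Carlo sample of the Dunnett max-|T| null: T_i compares treatment i
# (n_i) against a shared control (n0) using a common variance estimate with
# `df` degrees of freedom. The shared control induces the equicorrelation
# (rho = 0.5 when balanced).
dunnett_maxt_sample <- function(n_treat, n0, df, draws) {
  k <- length(n_treat)
  z0 <- rnorm(draws)
  s <- sqrt(rchisq(draws, df) / df)
  tmat <- vapply(seq_len(k), function(i) {
    zi <- rnorm(draws)
    u <- (zi / sqrt(n_treat[i]) - z0 / sqrt(n0)) /
      sqrt(1 / n_treat[i] + 1 / n0)
    u / s
  }, numeric(draws))
  if (k == 1) tmat <- matrix(tmat, ncol = 1)
  do.call(pmax, as.data.frame(abs(tmat)))
}

#' Dunnett many-to-one comparisons against a control
#'
#' Within each time point, computes
#' `t_i = (mean_i - mean_ctrl) / sqrt(MSE (1/n_i + 1/n_ctrl))` against the
#' shared control and adjusts two-sidedly for the family of comparisons:
#' `p_adj = P(max_j |T_j| >= |t_i|)` under the equicorrelated multivariate-t
#' null induced by the shared control (correlation 0.5 for balanced
#' designs), estimated by seeded Monte Carlo.
#'
#' @param cell_means Tibble with `line`, `time_point`, `mean`, `n` (e.g. the
#'   `cell_means` component of [two_way_anova()]).
#' @param residual_ms,residual_df Pooled residual mean square and df.
#' @param control Name of the control line.
#' @param alpha Significance threshold used for the `significant` flag.
#' @param mc_draws Monte-Carlo draws (default 1e5; standard error on an
#'   adjusted p is below 0.002).
#' @param seed Seed for the Monte-Carlo draws.
#' @return Tibble: one row per (treatment line, time point) with the
#'   difference, t statistic, raw two-sided p, adjusted p and significance
#'   flag.
#' @export
dunnett_vs_control <- function(cell_means, residual_ms, residual_df,
                               control = "WT", alpha = 0.05,
                               mc_draws = 1e5, seed = 1L) {
  req <- c("line", "time_point", "mean", "n")
  if (!all(req %in% names(cell_means))) {
    abort("`cell_means` needs columns line, time_point, mean, n.")
  }
  cell_means <- dplyr::mutate(cell_means, line = as.character(.data$line))
  if (!control %in% cell_means$line) {
    abort(sprintf("Control line '%s' absent from `cell_means`.", control))
  }
  with_seed(seed, {
    out <- cell_means %>%
      dplyr::group_by(.data$time_point) %>%
      dplyr::group_modify(function(df, key) {
        ctrl <- dplyr::filter(df, .data$line == control)
        if (nrow(ctrl) != 1) {
          abort(sprintf("Control cell missing at time point %s.", as.character(key[[1]])))
        }
        trt <- dplyr::filter(df, .data$line != control) %>%
          dplyr::arrange(.data$line)
        tstat <- (trt$mean - ctrl$mean) /
          sqrt(residual_ms * (1 / trt$n + 1 / ctrl$n))
        maxt <- dunnett_maxt_sample(trt$n, ctrl$n, residual_df, mc_draws)
        p_adj <- vapply(abs(tstat), function(tt) mean(maxt >= tt), numeric(1))
        p_raw <- 2 * pt(-abs(tstat), residual_df)
        tibble::tibble(
          line = trt$line, diff = trt$mean - ctrl$mean,
          t = tstat, p_raw = p_raw, p_adj = pmax(p_adj, p_raw),
          significant = pmax(p_adj, p_raw) < alpha
        )
      }) %>%
      dplyr::ungroup()
    out
  })
}
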