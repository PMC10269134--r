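# High-light +/- lincomycin Fv/Fm analysis: normalization, photodamage rate
# from the translation-blocked arm, and repair/recovery decomposition.

#' Normalize Fv/Fm time courses to their initial value
#'
#' Per replicate: `100 * fv_fm(t) / fv_fm(0)`, the percent-of-initial scale
#' on which endpoint declines and recoveries are reported.
#'
#' @param tc Tibble with columns `time_min`, `fv_fm`, `replicate` and
#'   optional `line`, `arm` keys (see [gen_hl_linc_timecourse()]).
#' @return Input with an added `rel_pct` column.
#' @export
normalize_to_initial <- function(tc) {
  req <- c("time_min", "fv_fm", "replicate")
  if (!all(req %in% names(tc))) {
    abort("`tc` needs columns time_min, fv_fm, replicate.")
  }
  keys <- intersect(c("line", "arm"), names(tc))
  out <- tc %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "replicate")))) %>%
    dplyr::mutate(rel_pct = {
      i0 <- which(.data$time_min == 0)
      if (length(i0) != 1) abort("Each replicate needs exactly one t = 0 measurement.")
      if (.data$fv_fm[i0] <= 0) abort("Initial Fv/Fm must be positive.")
      100 * .data$fv_fm / .data$fv_fm[i0]
    }) %>%
    dplyr::ungroup()
  out
}

#' Photodamage rate constant from the translation-blocked arm
#'
#' With repair blocked by lincomycin the decline is first order, so
#' `ln(rel(t))` is linear in time through the origin. The rate is the
#' through-origin least-squares slope over the high-light phase; with a
#' single usable time point this reduces to `k = -ln(rel(t_end)) / t_end`.
#'
#' @param normalized Normalized series (see [normalize_to_initial()]),
#'   +LINC arm only; columns `time_min`, `rel_pct`, `replicate`.
#' @param t_end End of the high-light phase (min).
#' @return One-row tibble: `k_damage` (min^-1), per-replicate SD and n.
#' @export
photodamage_rate <- function(normalized, t_end = 60) {
  req <- c("time_min", "rel_pct", "replicate")
  if (!all(req %in% names(normalized))) {
    abort("`normalized` needs columns time_min, rel_pct, replicate.")
  }
  hl <- dplyr::filter(normalized, .data$time_min > 0, .data$time_min <= t_end)
  if (nrow(hl) == 0) abort("No time points in (0, t_end].")
  if (any(hl$rel_pct <= 0)) abort("Relative Fv/Fm must be positive to take logs.")
  per_rep <- hl %>%
    dplyr::group_by(.data$replicate) %>%
    dplyr::summarise(
      k = -sum(log(.data$rel_pct / 100) * .data$time_min) / sum(.data$time_min^2),
      .groups = "drop"
    )
  tibble::tibble(
    k_damage = mean(per_rep$k),
    sd = if (nrow(per_rep) > 1) sd(per_rep$k) else NA_real_,
    n_rep = nrow(per_rep)
  )
}

endpoint_mean <- function(normalized, t, label) {
  at <- dplyr::filter(normalized, .data$time_min == t)
  if (nrow(at) == 0) {
    abort(sprintf("Missing the %g-min time point required for %s.", t, label))
  }
  c(mean = mean(at$rel_pct), sd = sd(at$rel_pct), n = nrow(at))
}

#' Repair and recovery metrics from paired HL arms
#'
#' Endpoint percentages separating photodamage from repair: the 60-min
#' decline in each arm, their difference (`repair_protection`, the
#' percentage points of Fv/Fm preserved by active repair), the
#' percent-of-initial recovered at the end of the dim-light recovery in the
#' repair-competent arm, and the recovery deficit `100 - recovery_pct`.
#'
#' @param hl_arm Normalized series for the no-inhibitor arm.
#' @param linc_arm Normalized series for the lincomycin arm.
#' @param t_hl_end End of high light (min, default 60).
#' @param t_rec_end End of recovery (min, default 90).
#' @return One-row tibble with the metrics and their replicate SDs.
#' @export
repair_recovery_metrics <- function(hl_arm, linc_arm, t_hl_end = 60,
                                    t_rec_end = 90) {
  hl60 <- endpoint_mean(hl_arm, t_hl_end, "the HL-arm decline")
  linc60 <- endpoint_mean(linc_arm, t_hl_end, "the +LINC-arm decline")
  rec90 <- endpoint_mean(hl_arm, t_rec_end, "the recovery endpoint")
  tibble::tibble(
    decline_hl_pct = hl60[["mean"]], decline_hl_sd = hl60[["sd"]],
    decline_linc_pct = linc60[["mean"]], decline_linc_sd = linc60[["sd"]],
    repair_protection = hl60[["mean"]] - linc60[["mean"]],
    recovery_pct = rec90[["mean"]], recovery_sd = rec90[["sd"]],
    recovery_deficit = 100 - rec90[["mean"]],
    n_hl = hl60[["n"]], n_linc = linc60[["n"]]
  )
}

#' Photoinhibition summary per line
#'
#' Runs normalization, the +LINC photodamage rate and the repair/recovery
#' metrics for every line in a generated or measured HL ± LINC experiment.
#'
#' @param tc Raw Fv/Fm time courses with `line`, `arm`, `replicate`,
#'   `time_min`, `fv_fm`.
#' @return Tibble, one row per line.
#' @export
analyze_photoinhibition <- function(tc) {
  norm <- normalize_to_initial(tc)
  norm %>%
    dplyr::group_by(.data$line) %>%
    dplyr::group_modify(function(df, key) {
      hl <- dplyr::filter(df, .data$arm == "HL")
      linc <- dplyr::filter(df, .data$arm == "HL_LINC")
      metrics <- repair_recovery_metrics(hl, linc)
      rate <- photodamage_rate(linc)
      dplyr::bind_cols(metrics, k_damage = rate$k_damage)
    }) %>%
    dplyr::ungroup()
}

#' Plot normalized HL ± LINC time courses
#' @param normalized Output of [normalize_to_initial()].
#' @return A ggplot object.
#' @export
plot_photoinhibition <- function(normalized) {
  summ <- normalized %>%
    dplyr::group_by(dplyr::across(dplyr::any_of(c("line", "arm", "time_min")))) %>%
    dplyr::summarise(rel_pct = mean(.data$rel_pct), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$time_min, y = .data$rel_pct,
                                     colour = .data$line, linetype = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 60, linetype = "dotted") +
    ggplot2::labs(x = "Time (min)", y = "Fv/Fm (% of initial)")
}
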