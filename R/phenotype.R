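# Pigment-derived metrics and growth-rate estimation.

#' Per-cell pigment amount
#' @param pigment_amount_fmol Total pigment (fmol) in the counted aliquot.
#' @param cell_count Number of cells in the same aliquot, `> 0`.
#' @return fmol per cell.
#' @export
pigment_per_cell <- function(pigment_amount_fmol, cell_count) {
  if (any(cell_count <= 0)) abort("`cell_count` must be positive.")
  pigment_amount_fmol / cell_count
}

#' Xanthophyll-cycle de-epoxidation state index
#'
#' `DES = Dtx / (Dtx + Ddx)`, the fraction of the diadinoxanthin pool
#' converted to the photoprotective diatoxanthin. Scale-invariant and
#' bounded in `[0, 1]`; when both pigments are zero the index is undefined
#' and returned as `NA` with a warning.
#'
#' @param ddx Diadinoxanthin (any common unit), `>= 0`.
#' @param dtx Diatoxanthin (same unit), `>= 0`.
#' @return DES index values.
#' @examples
#' des_index(ddx = 3, dtx = 1)  # 0.25
#' @export
des_index <- function(ddx, dtx) {
  if (any(ddx < 0) || any(dtx < 0)) abort("Pigment amounts must be >= 0.")
  both_zero <- (ddx + dtx) == 0
  if (any(both_zero)) {
    warn("DES undefined where Ddx + Dtx = 0; returning NA.")
  }
  ifelse(both_zero, NA_real_, dtx / (dtx + ddx))
}

#' Pigment ratios per chlorophyll a
#'
#' @param record Tibble with columns `chla`, `fx`, `ddx`, `dtx` (and any
#'   identifier columns, which are preserved).
#' @return Input identifiers plus `fx_chla`, `ddx_chla`, `dtx_chla`.
#' @export
pigment_ratio_per_chla <- function(record) {
  req <- c("chla", "fx", "ddx", "dtx")
  if (!all(req %in% names(record))) {
    abort("`record` needs columns chla, fx, ddx, dtx.")
  }
  if (any(record$chla <= 0)) abort("`chla` must be positive to form ratios.")
  record %>%
    dplyr::mutate(
      fx_chla = .data$fx / .data$chla,
      ddx_chla = .data$ddx / .data$chla,
      dtx_chla = .data$dtx / .data$chla
    ) %>%
    dplyr::select(-dplyr::all_of(req))
}

#' Pigment summary table per line and time
#'
#' Replicate means of per-cell pigments, the DES index computed per replicate
#' then averaged, and ratios per Chl a.
#'
#' @param pigments Tibble as from [gen_pigment_timecourse()].
#' @return Tidy tibble, one row per line x time.
#' @export
summarise_pigments <- function(pigments) {
  pigments %>%
    dplyr::mutate(des = des_index(.data$ddx, .data$dtx)) %>%
    dplyr::group_by(.data$line, .data$time_h) %>%
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("chla", "fx", "ddx", "dtx", "des")), mean),
      n_rep = dplyr::n(), .groups = "drop"
    )
}

# Sliding-window log-linear fit on one replicate's counts.
division_rate_one <- function(time_d, cells, window_min_points, r2_min) {
  l2 <- log2(cells)
  n <- length(time_d)
  best <- list(slope = -Inf, r2 = NA_real_, window = c(NA_real_, NA_real_))
  best_r2 <- list(slope = NA_real_, r2 = -Inf, window = c(NA_real_, NA_real_))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i + 1 < window_min_points) next
      tt <- time_d[i:j]; yy <- l2[i:j]
      fit <- lm(yy ~ tt)
      slope <- unname(coef(fit)[2])
      r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits warn
      if (is.na(r2)) next
      if (r2 > best_r2$r2) best_r2 <- list(slope = slope, r2 = r2, window = range(tt))
      if (r2 >= r2_min && slope > best$slope) {
        best <- list(slope = slope, r2 = r2, window = range(tt))
      }
    }
  }
  if (!is.finite(best$slope)) {
    list(mu = best_r2$slope, r2 = best_r2$r2, window = best_r2$window, flagged = TRUE)
  } else {
    list(mu = best$slope, r2 = best$r2, window = best$window, flagged = FALSE)
  }
}

#' Maximum division rates from cell-count series
#'
#' For each replicate, the exponential phase is detected as the sliding
#' window (at least `window_min_points` samples) maximizing the slope of
#' `log2(counts)` versus time among windows whose linear fit reaches
#' `R^2 >= r2_min`; the slope of that window is the replicate's maximum
#' division rate (divisions per day, log2 units). The line-level rate is the
#' mean over replicates. Successive-interval rates
#' `log2(N[i+1]/N[i]) / dt[i]` are returned alongside. If no window meets
#' the R^2 threshold the best-R^2 window is used and the result flagged.
#'
#' @param series Tibble with columns `time_d`, `cells_per_ml`, `replicate`
#'   and optional grouping columns `line`, `light`.
#' @param window_min_points Minimum samples per window (default 3).
#' @param r2_min Minimum R^2 for an acceptable exponential window.
#' @return List with `per_replicate` (one row per replicate: `mu_max`, `r2`,
#'   window bounds, flag), `per_interval` (successive-interval rates) and
#'   `summary` (line-level mean and SD of `mu_max`).
#' @export
division_rates <- function(series, window_min_points = 3, r2_min = 0.99) {
  req <- c("time_d", "cells_per_ml", "replicate")
  if (!all(req %in% names(series))) {
    abort("`series` needs columns time_d, cells_per_ml, replicate.")
  }
  if (any(series$cells_per_ml <= 0)) abort("Counts must be positive.")
  keys <- intersect(c("line", "light"), names(series))
  grouped <- series %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "replicate", "time_d")))) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "replicate"))))
  if (any(dplyr::summarise(grouped, n = dplyr::n())$n < window_min_points)) {
    abort(sprintf("Each replicate needs at least %d samples.", window_min_points))
  }
  per_replicate <- grouped %>%
    dplyr::summarise(
      {
        res <- division_rate_one(.data$time_d, .data$cells_per_ml,
                                 window_min_points, r2_min)
        tibble::tibble(mu_max = res$mu, r2 = res$r2,
                       window_start = res$window[1], window_end = res$window[2],
                       flagged = res$flagged)
      },
      .groups = "drop"
    )
  per_interval <- grouped %>%
    dplyr::reframe(
      t_mid = (.data$time_d[-1] + .data$time_d[-dplyr::n()]) / 2,
      rate = diff(log2(.data$cells_per_ml)) / diff(.data$time_d)
    )
  summary <- per_replicate %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(sd = sd(.data$mu_max), n_rep = dplyr::n(),
                     any_flagged = any(.data$flagged),
                     mu_max = mean(.data$mu_max), .groups = "drop") %>%
    dplyr::select(dplyr::all_of(keys), "mu_max", "sd", "n_rep", "any_flagged")
  list(per_replicate = per_replicate, per_interval = per_interval,
       summary = summary)
}
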